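test_that("calibrated defaults hit the measured assay efficiencies", {
  expect_equal(conversion_fraction(simulate_in_vitro(at_model())), 0.95,
               tolerance = 1e-6)
  expect_equal(conversion_fraction(simulate_in_vitro(cv_model())), 0.77,
               tolerance = 1e-6)
})

test_that("violaxanthin consumption follows the closed-form exponential", {
  # dVio/dt = -k a Vio is autonomous: Vio(t) = vio0 exp(-k a t) regardless
  # of the second step; with k a = ln(20)/60 the 60-min conversion is 0.95
  k <- log(20) / 60
  m <- kinetic_model(k_de1 = k, k_de2 = 1e3,
                     ph_profile = vde_ph_profile("a_thaliana"))
  s <- simulate_in_vitro(m, ph = 5.1, vio0 = 0.33, t_end = 60)
  tr <- s$trajectory
  expect_equal(conversion_fraction(s), 0.95, tolerance = 1e-6)
  analytic <- 0.33 * exp(-k * tr$time)
  expect_lt(max(abs(tr$vio - analytic) / 0.33), 1e-3)
  # with a near-instant second step nearly all consumed violaxanthin is
  # already zeaxanthin
  expect_equal(conversion_fraction(s, "produced"), 0.95, tolerance = 1e-3)
})

test_that("complete DTT inhibition freezes the pigment pools", {
  m <- cv_model()  # dtt_inhibition = 0
  s <- simulate_in_vitro(m, dtt = TRUE)
  expect_equal(conversion_fraction(s), 0, tolerance = 1e-12)
  expect_true(all(s$trajectory$di == 0))
})

test_that("dtt_inhibition = 1 reproduces the uninhibited run bit-for-bit", {
  m <- cv_model()
  m$dtt_inhibition <- 1
  s0 <- simulate_in_vitro(m, dtt = FALSE)
  s1 <- simulate_in_vitro(m, dtt = TRUE)
  expect_identical(s0$trajectory, s1$trajectory)
})

test_that("mass is conserved and DI is monotone in vitro", {
  for (m in list(at_model(), cv_model())) {
    tr <- simulate_in_vitro(m)$trajectory
    tot <- tr$vio + tr$ant + tr$zea
    expect_lt(max(abs(tot - tot[1])), 1e-6 * tot[1])
    expect_true(all(diff(tr$di) >= -1e-10))
    expect_true(all(tr$di >= 0 & tr$di <= 1))
  }
})

test_that("conversion is non-decreasing in time and in k_de1", {
  m <- cv_model()
  convs_t <- sapply(c(10, 30, 60, 120), function(tt)
    conversion_fraction(simulate_in_vitro(m, t_end = tt)))
  expect_true(all(diff(convs_t) > 0))
  convs_k <- sapply(c(0.01, 0.025, 0.05, 0.1), function(k) {
    mk <- kinetic_model(k_de1 = k, ph_profile = m$ph_profile)
    conversion_fraction(simulate_in_vitro(mk))
  })
  expect_true(all(diff(convs_k) > 0))
})

test_that("in vivo: dark schedule with a zeaxanthin-free start is inert", {
  sched <- light_schedule(600, 0)
  tr <- simulate_in_vivo(cv_model(), sched,
                         pigment_profile(40, 0, 0))$trajectory
  # the neutral-pH tail of the activity curve leaves a negligible residual
  expect_true(all(tr$di < 1e-3))
  expect_true(all(tr$npq_total < 1e-3))
})

test_that("in vivo trajectories conserve mass and decompose NPQ exactly", {
  tr <- simulate_in_vivo(cv_model(), short_protocol())$trajectory
  tot <- tr$vio + tr$ant + tr$zea
  expect_lt(max(abs(tot - tot[1])), 1e-6 * tot[1])
  expect_equal(tr$npq_total, tr$q_e + tr$q_z + tr$q_i)
  expect_true(all(tr$q_e >= -1e-10 & tr$q_z >= -1e-10 & tr$q_i >= -1e-10))
  expect_true(all(tr$di >= 0 & tr$di <= 1))
})

test_that("in vivo DTT blocks zeaxanthin accumulation and qZ", {
  tr <- simulate_in_vivo(cv_model(), short_protocol(inhibitor = TRUE),
                         pigment_profile(40, 0, 0))$trajectory
  expect_lt(max(tr$zea), 1e-6)
  expect_lt(max(tr$q_z), 1e-6)
})

test_that("zeaxanthin persists through a dark interval between light cycles", {
  sched <- npq_protocol(irradiance = 2000, light_s = 300, dark_s = 300,
                        cycles = 2)
  tr <- simulate_in_vivo(cv_model(), sched)$trajectory
  di_cycle1 <- tr$di[which.min(abs(tr$time - 120))]
  di_cycle2 <- tr$di[which.min(abs(tr$time - 720))]
  expect_gt(di_cycle2, di_cycle1)
  # less than 15% of accumulated zeaxanthin is reconverted over 5 min dark
  zea_light_end <- tr$zea[which.min(abs(tr$time - 420))]
  zea_dark_end <- tr$zea[which.min(abs(tr$time - 720))]
  expect_gt(zea_dark_end, 0.85 * zea_light_end)
})

test_that("schedule and model constructors validate inputs", {
  expect_error(light_schedule(numeric(), numeric()), class = "xq_data_error")
  expect_error(light_schedule(10, -5), class = "xq_data_error")
  expect_error(kinetic_model(k_de1 = -1), class = "xq_data_error")
  expect_error(kinetic_model(k_de1 = 0.1, dtt_inhibition = 2),
               class = "xq_data_error")
  expect_error(simulate_in_vitro(cv_model(), vio0 = 0), class = "xq_data_error")
})

test_that("kinetic models survive the flat config round trip", {
  m <- cv_model()
  path <- withr::local_tempfile(fileext = ".cfg")
  write_kinetic_config(m, path)
  m2 <- read_kinetic_config(path)
  s1 <- simulate_in_vitro(m, t_end = 20)
  s2 <- simulate_in_vitro(m2, t_end = 20)
  expect_equal(s1$trajectory, s2$trajectory, tolerance = 1e-16)
  writeLines(c(readLines(path), "mystery_key = 3"), path)
  expect_error(read_kinetic_config(path), class = "xq_data_error")
})

test_that("shipped default config files match the runtime calibration", {
  for (sp in c("a_thaliana", "c_vulgaris")) {
    cfg <- system.file("extdata", paste0("kinetic_model_", sp, ".cfg"),
                       package = "xanthoq")
    expect_true(nzchar(cfg))
    m <- read_kinetic_config(cfg)
    expect_equal(m$k_de1, default_kinetic_model(sp)$k_de1, tolerance = 1e-9)
  }
})
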