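test_that("internal-standard normalization scales the whole spectrum", {
  sp <- gen_spectrum77k(default_77k_areas * 2,
                        noise = noise_spec(spectrum_sigma = 0))
  spn <- normalize_to_standard(sp)
  sel <- spn$wavelength >= 500 & spn$wavelength <= 540
  gfp_area <- pracma::trapz(spn$wavelength[sel], spn$intensity[sel])
  expect_equal(gfp_area, 1, tolerance = 0.01)
  expect_equal(attr(spn, "standard_area"), 2, tolerance = 0.01)

  # two spectra differing by a global factor become identical
  spn2 <- normalize_to_standard(
    gen_spectrum77k(default_77k_areas * 7,
                    noise = noise_spec(spectrum_sigma = 0)))
  expect_equal(spn$intensity, spn2$intensity, tolerance = 1e-9)
})

test_that("normalization without a standard band is an error", {
  flat <- spectrum77k(seq(500, 780, 1), rep(0, 281))
  expect_error(normalize_to_standard(flat), class = "xq_data_error")
})

test_that("a noiseless band sum is deconvolved to its true areas", {
  sp <- gen_spectrum77k(default_77k_areas,
                        noise = noise_spec(spectrum_sigma = 0))
  fit <- fit_gaussians(sp)
  co <- fit$components
  expect_equal(co$area[co$center < 690][1], 2.0, tolerance = 0.01)
  expect_equal(sum(co$area[co$role == "PSII"]), 3.2, tolerance = 0.01)
  expect_equal(co$area[co$role == "PSI"], 2.5, tolerance = 0.01)
  expect_lt(fit$residual_rms, 1e-6)
  expect_lt(max(abs(co$center - c(686, 698, 720, 745))), 0.1)
})

test_that("fitting extra components to a single band leaves them empty", {
  sp <- gen_spectrum77k(c(standard = 1, psii_686 = 0, psii_698 = 0,
                          psi_720 = 3, vibronic = 0),
                        noise = noise_spec(spectrum_sigma = 0))
  fit <- fit_gaussians(sp)
  co <- fit$components
  extra <- co$area[co$center < 700 | co$center > 740]
  expect_lt(sum(extra), 0.01 * sum(co$area))
})

test_that("an absent PSI band yields no 720 nm component", {
  sp <- gen_spectrum77k(c(standard = 1, psii_686 = 2, psii_698 = 1.2,
                          psi_720 = 0, vibronic = 0.5),
                        noise = noise_spec(seed = 4))
  fit <- fit_gaussians(sp)
  co <- fit$components
  expect_lt(co$area[co$role == "PSI"], 0.01 * sum(co$area))
})

test_that("photosystem quenching follows (A_dark - A_light)/A_light", {
  sp <- gen_spectrum77k(default_77k_areas,
                        noise = noise_spec(spectrum_sigma = 0))
  fit <- fit_gaussians(sp)
  q0 <- ps_quenching(fit, fit)
  expect_equal(q0$psii_q, 0)
  expect_equal(q0$psi_q, 0)

  mk <- function(psii, psi) {
    f <- fit
    f$components$area <- c(psii / 2, psii / 2, psi, 0.3)
    f
  }
  q <- ps_quenching(mk(2, 1.5), mk(1, 1.0))
  expect_equal(q$psii_q, 1.0)
  expect_equal(q$psi_q, 0.5)
  # the A_dark convention divides by the dark areas instead
  qd <- ps_quenching(mk(2, 1.5), mk(1, 1.0), convention = "dark")
  expect_equal(qd$psii_q, 0.5)
})

test_that("quenching is invariant to a common rescaling of both spectra", {
  dark <- c(standard = 1, psii_686 = 2, psii_698 = 1.2, psi_720 = 2.5,
            vibronic = 0.8)
  light <- c(standard = 1, psii_686 = 1.0, psii_698 = 0.6, psi_720 = 1.8,
             vibronic = 0.6)
  fit_of <- function(a, scale) fit_gaussians(normalize_to_standard(
    gen_spectrum77k(a * scale, noise = noise_spec(spectrum_sigma = 0))))
  q1 <- ps_quenching(fit_of(dark, 1), fit_of(light, 1))
  q2 <- ps_quenching(fit_of(dark, 13), fit_of(light, 13))
  expect_equal(q1$psii_q, q2$psii_q, tolerance = 1e-6)
  expect_equal(q1$psi_q, q2$psi_q, tolerance = 1e-6)
  expect_gt(q1$psii_q, 0)
})

test_that("weaker synthetic quenching (the DTT condition) lowers both statistics", {
  dark <- default_77k_areas
  light <- dark * c(1, 0.5, 0.5, 0.6, 0.8)      # strong quenching
  light_dtt <- dark * c(1, 0.85, 0.85, 0.9, 0.95)  # inhibitor: weak quenching
  f <- function(a, cond) fit_gaussians(normalize_to_standard(
    gen_spectrum77k(a, noise = noise_spec(seed = 8), condition = cond)))
  q <- ps_quenching(f(dark, "dark"), f(light, "light"))
  q_dtt <- ps_quenching(f(dark, "dark"), f(light_dtt, "light_dtt"))
  expect_lt(q_dtt$psii_q, q$psii_q)
  expect_lt(q_dtt$psi_q, q$psi_q)
})

test_that("77 K spectra round-trip through delimited text", {
  sp <- gen_spectrum77k(noise = noise_spec(seed = 3), condition = "light")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum77k(sp, path)
  sp2 <- read_spectrum77k(path)
  expect_equal(sp2$intensity, sp$intensity, tolerance = 1e-6)
  expect_equal(sp2$condition, "light")
})
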