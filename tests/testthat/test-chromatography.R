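gauss_trace <- function(centers, areas, sigma = 0.08, offset = 0,
                        rt = seq(0, 15, by = 0.01)) {
  y <- rep(offset, length(rt))
  for (i in seq_along(centers))
    y <- y + areas[i] / (sigma * sqrt(2 * pi)) *
      exp(-0.5 * ((rt - centers[i]) / sigma)^2)
  chromatogram(rt, y)
}

test_that("a noiseless Gaussian peak is integrated to its true area", {
  ch <- gauss_trace(5, 100)
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$area, 100, tolerance = 0.01)
  expect_equal(pk$apex_time, 5, tolerance = 0.011)
})

test_that("baseline-separated peaks are each recovered within 1%", {
  ch <- gauss_trace(c(4, 9), c(80, 150))
  pk <- detect_peaks(ch)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$area, c(80, 150), tolerance = 0.01)
})

test_that("flat or empty traces give an empty peak table, not an error", {
  flat <- chromatogram(seq(0, 15, by = 0.01), rep(3, 1501))
  expect_s3_class(detect_peaks(flat), "peak_table")
  expect_equal(nrow(detect_peaks(flat)), 0)
})

test_that("peak areas are invariant to a uniform baseline offset", {
  a0 <- detect_peaks(gauss_trace(c(4, 9), c(80, 150)))$area
  a5 <- detect_peaks(gauss_trace(c(4, 9), c(80, 150), offset = 25))$area
  expect_equal(a0, a5, tolerance = 1e-6)
})

test_that("quantification is linear in area via the response factor", {
  cal <- data.frame(pigment = "zea", rt_center = 6.6, rt_min = 6.1,
                    rt_max = 7.1, response_factor = 0.5)
  pk <- detect_peaks(gauss_trace(6.6, 2))
  prof <- quantify_peaks(pk, cal)
  expect_equal(prof$zea, 1.0, tolerance = 0.01)
})

test_that("a missing peak is reported below detection, two peaks are ambiguous", {
  cal <- default_calibration()
  prof <- quantify_peaks(detect_peaks(gauss_trace(6.6, 100)), cal)
  expect_equal(prof$vio, 0)
  expect_true("vio" %in% prof$below_detection)
  expect_false("zea" %in% prof$below_detection)
  two <- detect_peaks(gauss_trace(c(6.3, 6.9), c(100, 100)))
  expect_error(quantify_peaks(two, cal), class = "xq_data_error")
})

test_that("unassigned peaks are kept in the annotated table", {
  pk <- detect_peaks(gauss_trace(c(6.6, 14.5), c(100, 60)))
  prof <- quantify_peaks(pk, default_calibration())
  ann <- attr(prof, "peaks")
  expect_equal(nrow(ann), 2)
  expect_true(is.na(ann$assigned_pigment[ann$apex_time > 14]))
})

test_that("a synthetic chromatogram round-trips to its generating profile", {
  truth <- pigment_profile(1.2, 0.4, 0.9, neo = 0.6, lut = 2.2, chl_b = 30,
                           chl_a = 100, beta_car = 8)
  ch <- gen_chromatogram(truth, noise = noise_spec(chrom_sigma = 0))
  prof <- quantify_peaks(detect_peaks(ch))
  got <- c(prof$vio, prof$ant, prof$zea, prof$neo, prof$lut, prof$chl_b,
           prof$chl_a, prof$beta_car)
  want <- c(1.2, 0.4, 0.9, 0.6, 2.2, 30, 100, 8)
  expect_lt(max(abs(got / want - 1)), 0.02)
  expect_lt(abs(deepoxidation_index(prof) - deepoxidation_index(truth)), 0.01)
})

test_that("assay readout flags a signal-free series and normalizes a ramp", {
  t <- 0:10
  wl <- seq(470, 560, by = 1)
  flat <- list(time = t, wavelength = wl,
               absorbance = matrix(0.1, length(t), length(wl)))
  ak <- assay_readout(flat)
  expect_true(attr(ak, "no_activity"))
  expect_true(all(abs(ak$delta_norm) < 1e-12))

  ramp <- outer(seq(0, 0.02, length.out = length(t)),
                exp(-0.5 * ((wl - 505) / 10)^2)) + 0.1
  ak2 <- assay_readout(list(time = t, wavelength = wl, absorbance = ramp))
  expect_false(attr(ak2, "no_activity"))
  expect_equal(ak2$delta_norm[length(t)], 1.0)
  expect_true(all(diff(ak2$delta_norm) > 0))
})

test_that("simulated assay spectra reproduce the zeaxanthin kinetics", {
  sim <- simulate_in_vitro(cv_model())
  sp <- gen_assay_spectra(sim)
  ak <- assay_readout(sp)
  zea <- attr(sp, "truth")
  expect_lt(max(abs(ak$delta_norm - zea / zea[length(zea)])), 0.01)
})

test_that("chromatograms round-trip through delimited text", {
  ch <- gen_chromatogram(pigment_profile(1, 0.5, 0.5),
                         noise = noise_spec(seed = 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chromatogram(ch, path)
  ch2 <- read_chromatogram(path)
  expect_equal(ch2$absorbance, ch$absorbance, tolerance = 1e-6)
  expect_equal(ch2$detection_wavelength, ch$detection_wavelength)
})
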