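#' Noise specification for the synthetic-instrument generators
#'
#' One seed drives every source of randomness; the same spec produces
#' byte-identical synthetic data. Noise models match the instruments:
#' multiplicative Gaussian for PAM fluorescence and emission spectra,
#' additive Gaussian baseline noise for chromatograms, Poisson counting
#' noise for photon-counting decays.
#'
#' @param seed integer RNG seed.
#' @param pam_sigma relative (multiplicative) noise of PAM fluorescence.
#' @param spectrum_sigma relative noise of 77 K spectra.
#' @param chrom_sigma additive chromatogram baseline noise (mAU).
#' @param decay_peak_counts expected counts in the peak decay bin.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(seed = 1, pam_sigma = 0.005, spectrum_sigma = 0.01,
                       chrom_sigma = 0.5, decay_peak_counts = 1e4) {
  check_nonneg(c(pam_sigma, spectrum_sigma, chrom_sigma, decay_peak_counts),
               "noise parameters")
  structure(list(seed = as.integer(seed), pam_sigma = pam_sigma,
                 spectrum_sigma = spectrum_sigma, chrom_sigma = chrom_sigma,
                 decay_peak_counts = decay_peak_counts),
            class = "noise_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic PAM trace from a simulation
#'
#' Inverts the NPQ definition: each saturating pulse rises to
#' `fm0 / (1 + NPQ(t))`, the baseline follows
#' `fo0 / (1 + NPQ(t))` between pulses (steady-state fluorescence tracks
#' the same quenching), and multiplicative Gaussian noise is applied.
#' Ground-truth pulse heights are recorded in attribute `"truth"`.
#'
#' @param sim an `xc_sim` from [simulate_in_vivo()] covering the schedule.
#' @param schedule the [light_schedule()] (defaults to the one simulated).
#' @param fm0 dark-adapted maximal fluorescence (a.u.).
#' @param fo0 dark baseline fluorescence (a.u.).
#' @param noise a [noise_spec()].
#' @param dt sampling interval (s).
#' @param pulse_width duration of the saturating-pulse spike (s).
#' @return A [pam_trace()] with attribute `"truth"` (data frame `time`,
#'   `npq`, `fm_prime` at pulse times).
#' @export
gen_pam_trace <- function(sim, schedule = sim$schedule, fm0 = 2, fo0 = 0.4,
                          noise = noise_spec(), dt = 0.2,
                          pulse_width = 0.6) {
  stopifnot(inherits(sim, "xc_sim"), inherits(schedule, "light_schedule"))
  tr <- sim$trajectory
  total <- sum(schedule$segments$duration)
  if (max(tr$time) < total - 1e-9)
    stop_data("simulation does not cover the schedule duration")
  time <- seq(0, total, by = dt)
  npq_t <- stats::approx(tr$time, tr$npq_total, xout = time, rule = 2)$y
  pulses <- schedule_pulse_times(schedule)
  base <- fo0 / (1 + npq_t)
  f <- base
  for (tp in pulses) {
    sel <- time >= tp - pulse_width / 2 & time <= tp + pulse_width / 2
    npq_p <- stats::approx(tr$time, tr$npq_total, xout = tp, rule = 2)$y
    f[sel] <- fm0 / (1 + npq_p)
  }
  f_noisy <- with_seed(noise$seed,
                       f * (1 + stats::rnorm(length(f), 0, noise$pam_sigma)))
  out <- pam_trace(time, pmax(f_noisy, 1e-6), schedule, pulses)
  npq_pulse <- stats::approx(tr$time, tr$npq_total, xout = pulses, rule = 2)$y
  attr(out, "truth") <- data.frame(time = pulses, npq = npq_pulse,
                                   fm_prime = fm0 / (1 + npq_pulse))
  out
}

#' Generate a synthetic 77 K emission spectrum
#'
#' Sum of Gaussian bands -- the GFP internal standard (511 nm) and the
#' PSII (686, 698 nm), PSI (720 nm) and vibronic (745 nm) chlorophyll
#' bands -- with multiplicative Gaussian noise. Ground-truth band areas
#' are recorded in attribute `"truth"`.
#'
#' @param areas named numeric: band areas for `standard`, `psii_686`,
#'   `psii_698`, `psi_720`, `vibronic`.
#' @param noise a [noise_spec()].
#' @param wavelength wavelength grid (nm).
#' @param condition label stored on the spectrum.
#' @return A [spectrum77k()] with attribute `"truth"`.
#' @export
gen_spectrum77k <- function(areas = c(standard = 1, psii_686 = 2.0,
                                      psii_698 = 1.2, psi_720 = 2.5,
                                      vibronic = 0.8),
                            noise = noise_spec(),
                            wavelength = seq(490, 790, by = 0.5),
                            condition = "dark") {
  check_nonneg(areas, "areas")
  bands <- data.frame(
    name = c("standard", "psii_686", "psii_698", "psi_720", "vibronic"),
    center = c(512, 686, 698, 720, 745),
    sigma = c(4.5, 7, 9, 11, 16))  # standard band fully inside 500-540 nm
  y <- numeric(length(wavelength))
  for (i in seq_len(nrow(bands))) {
    a <- areas[[bands$name[i]]]
    if (is.null(a) || is.na(a)) a <- 0
    y <- y + a / (bands$sigma[i] * sqrt(2 * pi)) *
      exp(-0.5 * ((wavelength - bands$center[i]) / bands$sigma[i])^2)
  }
  y_noisy <- with_seed(noise$seed + 1L,
                       y * (1 + stats::rnorm(length(y), 0,
                                             noise$spectrum_sigma)))
  out <- spectrum77k(wavelength, y_noisy, condition = condition)
  attr(out, "truth") <- areas
  out
}

#' Generate a synthetic photon-counting decay
#'
#' Multi-exponential decay convolved with a Gaussian IRF, wrapped at the
#' repetition period, scaled so the expected peak bin holds
#' `noise$decay_peak_counts` counts, then Poisson-sampled. The noiseless
#' expectation and the (noiseless) IRF are attached.
#'
#' @param lifetimes component lifetimes (ps).
#' @param amplitudes amplitude fractions (normalized internally).
#' @param irf_fwhm Gaussian IRF full width at half maximum (ps).
#' @param noise a [noise_spec()]; `decay_peak_counts` sets the scale.
#' @param time_bins uniform grid (ps).
#' @param t0 IRF center (ps).
#' @param rep_period laser repetition period (ps).
#' @return A [decay_trace()] (with the IRF attached) plus attribute
#'   `"truth"` (list `lifetimes`, `amplitudes`, `tau_avg`, `expected`).
#' @export
gen_decay <- function(lifetimes, amplitudes, irf_fwhm = 30,
                      noise = noise_spec(),
                      time_bins = seq(0, 2500, by = 2), t0 = 200,
                      rep_period = 20000) {
  check_nonneg(c(lifetimes, amplitudes), "decay parameters")
  if (length(lifetimes) != length(amplitudes))
    stop_data("one amplitude per lifetime required")
  a <- amplitudes / sum(amplitudes)
  sigma <- irf_fwhm / (2 * sqrt(2 * log(2)))
  m <- numeric(length(time_bins))
  for (i in seq_along(lifetimes))
    m <- m + a[i] * emg_decay(time_bins, lifetimes[i], t0, sigma, rep_period)
  m <- m / max(m) * noise$decay_peak_counts
  counts <- with_seed(noise$seed + 2L, stats::rpois(length(m), m))
  irf <- exp(-0.5 * ((time_bins - t0) / sigma)^2)
  out <- decay_trace(time_bins, counts, irf = irf, rep_period = rep_period)
  attr(out, "truth") <- list(lifetimes = lifetimes, amplitudes = a,
                             tau_avg = sum(a * lifetimes), expected = m)
  out
}

#' Generate a synthetic HPLC chromatogram from a pigment profile
#'
#' One Gaussian peak per pigment at its calibration window center with
#' area `concentration / response_factor`, plus additive Gaussian baseline
#' noise. The generating profile is attached as ground truth, making the
#' generator the measurable inverse of [detect_peaks()] +
#' [quantify_peaks()].
#'
#' @param profile a [pigment_profile()].
#' @param calibration as [default_calibration()].
#' @param noise a [noise_spec()]; `chrom_sigma` is the baseline noise.
#' @param retention_time grid (min).
#' @param peak_sigma chromatographic peak width (min).
#' @param baseline constant baseline offset (mAU).
#' @return A [chromatogram()] with attribute `"truth"` (the profile).
#' @export
gen_chromatogram <- function(profile, calibration = default_calibration(),
                             noise = noise_spec(),
                             retention_time = seq(0, 15, by = 0.01),
                             peak_sigma = 0.08, baseline = 0) {
  stopifnot(inherits(profile, "pigment_profile"))
  y <- rep(baseline, length(retention_time))
  for (j in seq_len(nrow(calibration))) {
    conc <- profile[[calibration$pigment[j]]]
    if (is.null(conc) || is.na(conc) || conc == 0) next
    area <- conc / calibration$response_factor[j]
    y <- y + area / (peak_sigma * sqrt(2 * pi)) *
      exp(-0.5 * ((retention_time - calibration$rt_center[j]) / peak_sigma)^2)
  }
  y_noisy <- with_seed(noise$seed + 3L,
                       y + stats::rnorm(length(y), 0, noise$chrom_sigma))
  out <- chromatogram(retention_time, y_noisy)
  attr(out, "truth") <- profile
  out
}

#' Generate synthetic assay absorption spectra from an in-vitro simulation
#'
#' Maps the simulated zeaxanthin series linearly onto an absorption
#' increase at 505 nm (a Gaussian feature of width 10 nm) over a flat
#' reference spectrum, emulating the spectrophotometric de-epoxidation
#' assay readout.
#'
#' @param sim an `xc_sim` from [simulate_in_vitro()].
#' @param times sampling times (min).
#' @param delta_a505_per_zea absorption increase at 505 nm per unit
#'   zeaxanthin.
#' @param noise a [noise_spec()]; `spectrum_sigma` used additively
#'   relative to the base absorbance.
#' @param a_base flat background absorbance.
#' @return A list (`time`, `wavelength`, `absorbance` matrix) suitable for
#'   [assay_readout()], with attribute `"truth"` (the zea series at
#'   `times`).
#' @export
gen_assay_spectra <- function(sim, times = seq(0, 60, by = 2),
                              delta_a505_per_zea = 0.05,
                              noise = noise_spec(spectrum_sigma = 0),
                              a_base = 0.1) {
  stopifnot(inherits(sim, "xc_sim"))
  tr <- sim$trajectory
  zea_t <- stats::approx(tr$time, tr$zea, xout = times, rule = 2)$y
  wavelength <- seq(470, 560, by = 1)
  feat <- exp(-0.5 * ((wavelength - 505) / 10)^2)
  ab <- with_seed(noise$seed + 4L, {
    m <- outer(zea_t * delta_a505_per_zea, feat) + a_base
    m + matrix(stats::rnorm(length(m), 0, noise$spectrum_sigma * a_base),
               nrow = nrow(m))
  })
  out <- list(time = times, wavelength = wavelength, absorbance = ab)
  attr(out, "truth") <- zea_t
  out
}
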