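#' 77 K fluorescence emission spectrum
#'
#' At liquid-nitrogen temperature photochemistry is blocked and the PSII
#' (686, 698 nm) and PSI (~720 nm) emission bands are resolvable; a GFP
#' internal standard band near 511 nm allows quantitative comparison of
#' spectra recorded on different samples.
#'
#' @param wavelength increasing wavelength grid (nm).
#' @param intensity emission intensity (arbitrary units).
#' @param condition free-text acquisition label, e.g. `"dark"`,
#'   `"light"`, `"light_dtt"`.
#' @return An object of class `spectrum77k`.
#' @export
spectrum77k <- function(wavelength, intensity, condition = "dark") {
  check_finite(wavelength, "wavelength")
  check_finite(intensity, "intensity")
  if (length(wavelength) != length(intensity))
    stop_data("wavelength and intensity lengths differ")
  if (any(diff(wavelength) <= 0))
    stop_data("wavelength must be strictly increasing")
  structure(list(wavelength = wavelength, intensity = intensity,
                 condition = condition),
            class = "spectrum77k")
}

#' @export
print.spectrum77k <- function(x, ...) {
  cat(sprintf("77 K emission spectrum (%s): %d points, %g-%g nm\n",
              x$condition, length(x$wavelength), min(x$wavelength),
              max(x$wavelength)))
  invisible(x)
}

#' @export
plot.spectrum77k <- function(x, ...) {
  plot(x$wavelength, x$intensity, type = "l", xlab = "wavelength (nm)",
       ylab = "emission (a.u.)", main = x$condition, ...)
  invisible(x)
}

#' Normalize a spectrum to its internal-standard band
#'
#' Scales intensities so the integrated area inside the standard window
#' (default 500-540 nm, the GFP band) equals 1. Spectra normalized this way
#' are directly comparable even when acquired at different gains or
#' chlorophyll contents.
#'
#' @param s a [spectrum77k()].
#' @param standard_window length-2 numeric, nm.
#' @return The rescaled `spectrum77k`, with the applied factor in attribute
#'   `"standard_area"`.
#' @export
normalize_to_standard <- function(s, standard_window = c(500, 540)) {
  stopifnot(inherits(s, "spectrum77k"))
  sel <- s$wavelength >= standard_window[1] & s$wavelength <= standard_window[2]
  if (sum(sel) < 2)
    stop_data("spectrum does not cover the standard window")
  area <- pracma::trapz(s$wavelength[sel], s$intensity[sel])
  if (area <= 0)
    stop_data("no signal in the standard window: cannot normalize")
  out <- spectrum77k(s$wavelength, s$intensity / area, s$condition)
  attr(out, "standard_area") <- area
  out
}

#' Gaussian deconvolution of a 77 K emission spectrum
#'
#' Fits a sum of Gaussian bands by bounded nonlinear least squares
#' (Levenberg-Marquardt): centers are constrained within `center_tol` nm of
#' their initial values, widths and areas are positive. The default band
#' set is the two PSII bands (686, 698 nm), the PSI band (720 nm) and one
#' vibronic satellite (745 nm) excluded from both photosystem sums.
#'
#' @param s a [spectrum77k()], typically standard-normalized.
#' @param init_centers initial band centers (nm).
#' @param roles one role per band: `"PSII"`, `"PSI"`, `"vibronic"` or
#'   `"standard"`.
#' @param init_sigma initial band widths (nm), recycled.
#' @param center_tol allowed center shift (nm).
#' @param fit_window wavelength range (nm) used for fitting.
#' @return An object of class `gauss77k_fit` with a `components` data frame
#'   (`center`, `sigma`, `area`, `role`) and `residual_rms`.
#' @export
fit_gaussians <- function(s, init_centers = c(686, 698, 720, 745),
                          roles = c("PSII", "PSII", "PSI", "vibronic"),
                          init_sigma = 8, center_tol = 5,
                          fit_window = c(650, 780)) {
  stopifnot(inherits(s, "spectrum77k"))
  if (length(roles) != length(init_centers))
    stop_data("one role per initial center is required")
  if (any(init_centers < min(s$wavelength) | init_centers > max(s$wavelength)))
    stop_data("init_centers outside the spectral range")
  sel <- s$wavelength >= fit_window[1] & s$wavelength <= fit_window[2]
  wl <- s$wavelength[sel]
  y <- s$intensity[sel]
  nb <- length(init_centers)
  sig0 <- rep_len(init_sigma, nb)
  ## crude initial amplitudes from the signal at the centers
  amp0 <- pmax(stats::approx(wl, y, xout = init_centers, rule = 2)$y, 1e-8)
  par0 <- c(init_centers, sig0, log(amp0))
  lower <- c(init_centers - center_tol, rep(1, nb), rep(-30, nb))
  upper <- c(init_centers + center_tol, rep(40, nb), rep(30, nb))
  model <- function(p) {
    ctr <- p[1:nb]; sg <- p[nb + 1:nb]; amp <- exp(p[2 * nb + 1:nb])
    rowSums(vapply(seq_len(nb),
                   function(i) amp[i] * exp(-0.5 * ((wl - ctr[i]) / sg[i])^2),
                   numeric(length(wl))))
  }
  fit <- minpack.lm::nls.lm(par0, lower, upper,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, maxfev = 50000))
  if (fit$info == 0 || fit$info == 9)
    stop_convergence("Gaussian deconvolution did not converge (info ",
                     fit$info, ", rsstrace tail ",
                     paste(signif(utils::tail(fit$rsstrace, 3), 4),
                           collapse = ", "), ")")
  p <- fit$par
  ctr <- p[1:nb]; sg <- p[nb + 1:nb]; amp <- exp(p[2 * nb + 1:nb])
  comp <- data.frame(center = ctr, sigma = sg,
                     area = amp * sg * sqrt(2 * pi), role = roles)
  structure(list(components = comp,
                 residual_rms = sqrt(mean(fit$fvec^2)),
                 condition = s$condition, fit_window = fit_window,
                 convergence_info = fit$info),
            class = "gauss77k_fit")
}

#' @export
print.gauss77k_fit <- function(x, ...) {
  cat(sprintf("Gaussian deconvolution (%s), residual RMS %.4g\n",
              x$condition, x$residual_rms))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %-8s center %.1f nm, sigma %.2f nm, area %.4g\n",
                comp$role[i], comp$center[i], comp$sigma[i], comp$area[i]))
  invisible(x)
}

#' @export
coef.gauss77k_fit <- function(object, ...) object$components

#' @export
predict.gauss77k_fit <- function(object, wavelength, ...) {
  comp <- object$components
  rowSums(vapply(seq_len(nrow(comp)),
                 function(i) comp$area[i] / (comp$sigma[i] * sqrt(2 * pi)) *
                   exp(-0.5 * ((wavelength - comp$center[i]) / comp$sigma[i])^2),
                 numeric(length(wavelength))))
}

role_area <- function(fit, role) {
  sum(fit$components$area[fit$components$role == role])
}

#' Photosystem-specific 77 K quenching statistic
#'
#' Light-induced quenching of each photosystem from the deconvolved band
#' areas: `(A_dark - A_light) / A_light`, where `A` is the summed area of
#' the PSII bands (686 + 698 nm) or of the PSI band (720 nm). The
#' `"dark"` convention divides by `A_dark` instead.
#'
#' @param dark,light `gauss77k_fit` objects for the dark-adapted and
#'   light-treated spectra (both standard-normalized).
#' @param convention `"light"` (default) or `"dark"` denominator.
#' @return An object of class `ps_quenching`: list with `psii_q`, `psi_q`.
#' @export
ps_quenching <- function(dark, light, convention = c("light", "dark")) {
  stopifnot(inherits(dark, "gauss77k_fit"), inherits(light, "gauss77k_fit"))
  convention <- match.arg(convention)
  q <- function(role) {
    a_d <- role_area(dark, role)
    a_l <- role_area(light, role)
    if (a_l <= 0 || (convention == "dark" && a_d <= 0))
      stop_data("zero ", role, " band area in the denominator condition")
    (a_d - a_l) / if (convention == "light") a_l else a_d
  }
  for (f in list(dark, light))
    if (!all(c("PSII", "PSI") %in% f$components$role))
      stop_data("fits must carry PSII and PSI band roles")
  structure(list(psii_q = q("PSII"), psi_q = q("PSI"),
                 convention = convention),
            class = "ps_quenching")
}

#' @export
print.ps_quenching <- function(x, ...) {
  cat(sprintf("77 K quenching ((A_dark - A_light)/A_%s):\n", x$convention))
  cat(sprintf("  PSII: %.4f\n  PSI:  %.4f\n", x$psii_q, x$psi_q))
  invisible(x)
}

#' Write / read a 77 K spectrum as two-column delimited text
#'
#' @param s a `spectrum77k`.
#' @param path file path.
#' @export
write_spectrum77k <- function(s, path) {
  stopifnot(inherits(s, "spectrum77k"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# condition: ", s$condition), con)
  utils::write.table(data.frame(wavelength_nm = s$wavelength,
                                intensity = s$intensity),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum77k
#' @export
read_spectrum77k <- function(path) {
  hdr <- readLines(path, n = 1)
  cond <- if (grepl("^# condition:", hdr[1]))
    sub("^# condition: ", "", hdr[1]) else "unknown"
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  spectrum77k(tab[[1]], tab[[2]], condition = cond)
}
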