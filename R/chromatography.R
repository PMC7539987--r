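#' HPLC chromatogram
#'
#' @param retention_time strictly increasing retention-time grid (min).
#' @param absorbance detector signal (mAU).
#' @param detection_wavelength nm (single detection channel).
#' @return An object of class `chromatogram`.
#' @export
chromatogram <- function(retention_time, absorbance,
                         detection_wavelength = 440) {
  check_finite(retention_time, "retention_time")
  check_finite(absorbance, "absorbance")
  if (length(retention_time) != length(absorbance))
    stop_data("retention_time and absorbance lengths differ")
  if (length(retention_time) < 2 || any(diff(retention_time) <= 0))
    stop_data("retention_time must be strictly increasing")
  structure(list(retention_time = retention_time, absorbance = absorbance,
                 detection_wavelength = detection_wavelength),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("Chromatogram: %d points, %.2f-%.2f min, detection %g nm\n",
              length(x$retention_time), min(x$retention_time),
              max(x$retention_time), x$detection_wavelength))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ...) {
  plot(x$retention_time, x$absorbance, type = "l",
       xlab = "retention time (min)", ylab = "absorbance (mAU)", ...)
  invisible(x)
}

#' Detect chromatographic peaks
#'
#' Local maxima exceeding a prominence threshold; each peak is integrated by
#' the trapezoid rule between its bounding valleys after subtracting a
#' linear baseline drawn between those valleys, so uniform baseline offsets
#' do not change areas.
#'
#' @param chrom a [chromatogram()].
#' @param min_prominence minimal height of the apex above the higher of its
#'   two bounding valleys (mAU).
#' @param min_width minimal peak width (min) at half prominence.
#' @return A data frame of class `peak_table` with columns `apex_time`,
#'   `height`, `area`, `assigned_pigment` (filled by [quantify_peaks()]).
#' @export
detect_peaks <- function(chrom, min_prominence = 5, min_width = 0.02) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$retention_time
  y <- chrom$absorbance
  n <- length(y)
  empty <- data.frame(apex_time = numeric(), height = numeric(),
                      area = numeric(),
                      assigned_pigment = character())
  class(empty) <- c("peak_table", "data.frame")
  if (n < 3) return(empty)
  ## strict local maxima (plateau apexes take the first sample)
  is_max <- which(y[2:(n - 1)] >= y[1:(n - 2)] & y[2:(n - 1)] > y[3:n]) + 1
  if (!length(is_max)) return(empty)
  rows <- list()
  for (i in is_max) {
    ## descend to bounding valleys
    l <- i; while (l > 1 && y[l - 1] <= y[l]) l <- l - 1
    r <- i; while (r < n && y[r + 1] <= y[r]) r <- r + 1
    prom <- y[i] - max(y[l], y[r])
    if (prom < min_prominence) next
    ## width at half prominence above the baseline
    base <- y[l] + (y[r] - y[l]) * (t[l:r] - t[l]) / (t[r] - t[l])
    yc <- y[l:r] - base
    half <- (y[i] - max(y[l], y[r])) / 2
    above <- t[l:r][yc >= half]
    if (length(above) < 2 || diff(range(above)) < min_width) next
    area <- pracma::trapz(t[l:r], yc)
    rows[[length(rows) + 1]] <- data.frame(apex_time = t[i], height = y[i],
                                           area = max(area, 0),
                                           assigned_pigment = NA_character_)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$apex_time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Default pigment calibration table
#'
#' Retention-time windows and linear response factors for the pigments of
#' the 15-min reversed-phase gradient. The windows and factors are
#' synthetic conventions (the published separation protocol does not list
#' them); they are what the synthetic chromatogram generator uses, so
#' generation and quantification agree by construction.
#'
#' @return Data frame with columns `pigment`, `rt_center` (min), `rt_min`,
#'   `rt_max`, `response_factor` (concentration per mAU min).
#' @export
default_calibration <- function() {
  data.frame(
    pigment = c("neo", "vio", "ant", "lut", "zea", "chl_b", "chl_a",
                "beta_car"),
    rt_center = c(2.6, 3.6, 4.6, 5.6, 6.6, 8.6, 10.2, 13.0),
    rt_min = c(2.1, 3.1, 4.1, 5.1, 6.1, 8.0, 9.6, 12.4),
    rt_max = c(3.1, 4.1, 5.1, 6.1, 7.1, 9.2, 10.8, 13.6),
    response_factor = c(0.010, 0.012, 0.011, 0.009, 0.013, 0.008, 0.007,
                        0.012))
}

#' Quantify a peak table against a calibration
#'
#' Each calibration window may contain at most one peak; concentration is
#' peak area times the response factor. Pigments with no peak in their
#' window are reported as zero with a below-detection flag; peaks assigned
#' to no window are kept in the returned table, not silently dropped.
#'
#' @param peaks a `peak_table` from [detect_peaks()].
#' @param calibration a data frame as from [default_calibration()].
#' @param unit_label unit of the resulting concentrations.
#' @return A [pigment_profile()] with attribute `"peaks"` (the annotated
#'   peak table, unassigned peaks included).
#' @export
quantify_peaks <- function(peaks, calibration = default_calibration(),
                           unit_label = "mol / 100 Chl") {
  stopifnot(inherits(peaks, "peak_table"))
  cal <- calibration
  o <- order(cal$rt_min)
  if (any(cal$rt_max[o][-nrow(cal)] > cal$rt_min[o][-1]))
    stop_data("calibration windows overlap")
  conc <- stats::setNames(rep(0, nrow(cal)), cal$pigment)
  below <- character()
  pk <- as.data.frame(peaks)
  for (j in seq_len(nrow(cal))) {
    hit <- which(pk$apex_time >= cal$rt_min[j] & pk$apex_time <= cal$rt_max[j])
    if (length(hit) > 1)
      stop_data(sprintf(
        "ambiguous assignment: %d peaks (at %s min) in the %s window",
        length(hit), paste(round(pk$apex_time[hit], 3), collapse = ", "),
        cal$pigment[j]))
    if (length(hit) == 1) {
      conc[j] <- pk$area[hit] * cal$response_factor[j]
      pk$assigned_pigment[hit] <- cal$pigment[j]
    } else {
      below <- c(below, cal$pigment[j])
    }
  }
  get <- function(nm) if (nm %in% names(conc)) unname(conc[nm]) else NA_real_
  out <- pigment_profile(vio = get("vio"), ant = get("ant"), zea = get("zea"),
                         neo = get("neo"), lut = get("lut"),
                         beta_car = get("beta_car"), chl_a = get("chl_a"),
                         chl_b = get("chl_b"), unit_label = unit_label,
                         below_detection = below)
  attr(out, "peaks") <- pk
  out
}

#' Spectrophotometric de-epoxidation assay readout
#'
#' Violaxanthin-to-zeaxanthin conversion raises absorption near 505 nm; the
#' 540 nm channel serves as reference. The readout is the kinetics of
#' A505 - A540 normalized to its maximum over the series.
#'
#' @param spectra a list with elements `time` (min), `wavelength` (nm grid
#'   covering 480-520 and 540 nm) and `absorbance` (matrix, one row per
#'   time point).
#' @return An object of class `assay_kinetics`: data frame `time`, `a505`,
#'   `a540`, `delta`, `delta_norm`, with attribute `"no_activity"` set when
#'   max(a505 - a540) is not positive (then `delta_norm` is left
#'   unnormalized).
#' @export
assay_readout <- function(spectra) {
  wl <- spectra$wavelength
  if (min(wl) > 480 || max(wl) < 540)
    stop_data("spectra must cover 480-520 nm and the 540 nm reference")
  ab <- spectra$absorbance
  if (is.null(dim(ab))) ab <- matrix(ab, nrow = 1)
  a505 <- apply(ab, 1, function(s) stats::approx(wl, s, xout = 505)$y)
  a540 <- apply(ab, 1, function(s) stats::approx(wl, s, xout = 540)$y)
  delta <- a505 - a540
  no_act <- max(delta) <= 0
  out <- data.frame(time = spectra$time, a505 = a505, a540 = a540,
                    delta = delta,
                    delta_norm = if (no_act) delta else delta / max(delta))
  class(out) <- c("assay_kinetics", "data.frame")
  attr(out, "no_activity") <- no_act
  out
}

#' Write / read a chromatogram as delimited text
#'
#' @param chrom a `chromatogram`.
#' @param path file path.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# detection_wavelength_nm: ", chrom$detection_wavelength),
             con)
  utils::write.table(data.frame(retention_time_min = chrom$retention_time,
                                absorbance_mau = chrom$absorbance),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  hdr <- readLines(path, n = 1)
  wl <- if (grepl("^# detection_wavelength_nm:", hdr[1]))
    as.numeric(sub("^# detection_wavelength_nm: ", "", hdr[1])) else 440
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  chromatogram(tab[[1]], tab[[2]], detection_wavelength = wl)
}
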