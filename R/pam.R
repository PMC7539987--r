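#' Saturating-pulse PAM fluorescence trace
#'
#' @param time sampling times (s).
#' @param fluorescence fluorescence signal (arbitrary units, positive).
#' @param schedule the [light_schedule()] applied during acquisition.
#' @param pulse_times times (s) of the saturating pulses; must lie within
#'   the sampled range.
#' @return An object of class `pam_trace`.
#' @export
pam_trace <- function(time, fluorescence, schedule, pulse_times) {
  check_finite(time, "time")
  check_finite(fluorescence, "fluorescence")
  if (length(time) != length(fluorescence))
    stop_data("time and fluorescence lengths differ")
  if (any(fluorescence <= 0))
    stop_data("fluorescence must be positive")
  if (any(pulse_times < min(time) | pulse_times > max(time)))
    stop_data("pulse_times outside the sampled range")
  stopifnot(inherits(schedule, "light_schedule"))
  structure(list(time = time, fluorescence = fluorescence,
                 schedule = schedule, pulse_times = sort(pulse_times)),
            class = "pam_trace")
}

#' @export
print.pam_trace <- function(x, ...) {
  cat(sprintf("PAM trace: %d samples over %.0f s, %d saturating pulses\n",
              length(x$time), diff(range(x$time)), length(x$pulse_times)))
  invisible(x)
}

#' @export
plot.pam_trace <- function(x, ...) {
  plot(x$time, x$fluorescence, type = "l", xlab = "time (s)",
       ylab = "fluorescence (a.u.)", ...)
  graphics::abline(v = x$pulse_times, col = "grey80", lty = 3)
  invisible(x)
}

## pulses that fall inside the initial dark-adapted segment
dark_pulse_idx <- function(trace) {
  seg <- trace$schedule$segments
  if (seg$irradiance[1] != 0) return(integer())
  which(trace$pulse_times <= seg$duration[1])
}

#' Extract Fm and the Fm' series from a PAM trace
#'
#' Fm is the maximal fluorescence in the pulse window(s) of the initial
#' dark-adapted segment; Fm' is the maximum within each subsequent pulse
#' window. When a window holds two samples of equal maximum, the first
#' occurrence is used (a message notes the tie).
#'
#' @param trace a [pam_trace()].
#' @param window half-width (s) of the search window around each annotated
#'   pulse time.
#' @return List with `fm` (scalar), `fm_prime` (data frame: `time`,
#'   `fm_prime`, one row per post-dark pulse).
#' @export
extract_pulses <- function(trace, window = 0.4) {
  stopifnot(inherits(trace, "pam_trace"))
  dark <- dark_pulse_idx(trace)
  if (!length(dark))
    stop_data("no saturating pulse in the dark-adapted segment: Fm undefined")
  peak_at <- function(tp) {
    sel <- which(trace$time >= tp - window & trace$time <= tp + window)
    if (!length(sel)) return(NA_real_)
    y <- trace$fluorescence[sel]
    hits <- which(y == max(y))
    if (length(hits) > 1)
      message(sprintf("pulse at t = %g s: %d samples tie for the maximum; using the first",
                      tp, length(hits)))
    max(y)
  }
  fm <- max(vapply(trace$pulse_times[dark], peak_at, numeric(1)))
  rest <- setdiff(seq_along(trace$pulse_times), dark)
  fmp <- vapply(trace$pulse_times[rest], peak_at, numeric(1))
  list(fm = fm,
       fm_prime = data.frame(time = trace$pulse_times[rest], fm_prime = fmp))
}

#' Non-photochemical quenching from Fm and Fm'
#'
#' NPQ = (Fm - Fm') / Fm', elementwise over the Fm' series.
#'
#' @param fm dark-adapted maximal fluorescence (scalar, positive).
#' @param fm_prime numeric vector (or the data frame from
#'   [extract_pulses()]) of light-/recovery-phase maxima.
#' @return Numeric vector of NPQ values (or a data frame `time`, `npq` when
#'   a data frame was supplied).
#' @export
compute_npq <- function(fm, fm_prime) {
  if (is.data.frame(fm_prime)) {
    npq <- compute_npq(fm, fm_prime$fm_prime)
    return(data.frame(time = fm_prime$time, npq = npq))
  }
  check_finite(c(fm, fm_prime), "fluorescence maxima")
  if (fm <= 0) stop_data("fm must be positive")
  if (any(fm_prime <= 0)) stop_data("all fm_prime must be positive")
  (fm - fm_prime) / fm_prime
}

#' Decompose NPQ into fast- and slowly relaxing fractions
#'
#' The slowly relaxing fraction (qI, or qZ when zeaxanthin-driven -- the
#' two are operationally indistinguishable in a single relaxation protocol)
#' is the NPQ remaining at the end of dark recovery; qE is the fraction
#' that relaxed, i.e. NPQ at the last pulse in light minus that residual.
#' By construction `q_e + q_islow` equals NPQ at the end of illumination.
#'
#' @param npq data frame `time`, `npq` (as from [compute_npq()]).
#' @param schedule the [light_schedule()]; must end with a dark segment.
#' @param endpoint `"last"` uses the last pulse of each phase; `"mean_k"`
#'   averages the last `k` pulses.
#' @param k number of pulses averaged when `endpoint = "mean_k"`.
#' @return List with `q_e`, `q_islow`, `npq_light_end`.
#' @export
decompose_npq <- function(npq, schedule, endpoint = c("last", "mean_k"),
                          k = 1) {
  stopifnot(inherits(schedule, "light_schedule"))
  endpoint <- match.arg(endpoint)
  seg <- schedule$segments
  nseg <- nrow(seg)
  if (seg$irradiance[nseg] != 0)
    stop_data("schedule must end with a dark-recovery segment")
  bounds <- seg_bounds(schedule)
  light_idx <- which(seg$irradiance > 0)
  if (!length(light_idx)) stop_data("schedule has no light segment")
  last_light <- max(light_idx)
  in_light <- npq$time > bounds[last_light] &
    npq$time <= bounds[last_light + 1] + 1e-9
  in_dark <- npq$time > bounds[nseg]
  if (!any(in_light) || !any(in_dark))
    stop_data("no pulses found in the final light or dark segment")
  pick <- function(v) {
    v <- v[order(v$time), , drop = FALSE]
    m <- if (endpoint == "last") 1 else min(k, nrow(v))
    mean(utils::tail(v$npq, m))
  }
  npq_light <- pick(npq[in_light, , drop = FALSE])
  q_islow <- pick(npq[in_dark, , drop = FALSE])
  list(q_e = npq_light - q_islow, q_islow = q_islow,
       npq_light_end = npq_light)
}

#' Maximum PSII quantum yield Fv/Fm
#'
#' Fo is the median dark fluorescence before the first saturating pulse;
#' Fm the dark-adapted pulse maximum; Fv/Fm = (Fm - Fo)/Fm.
#'
#' @param trace a [pam_trace()].
#' @param window pulse search half-width (s).
#' @return Fv/Fm fraction in `(0, 1)`.
#' @export
fv_fm <- function(trace, window = 0.4) {
  stopifnot(inherits(trace, "pam_trace"))
  dark <- dark_pulse_idx(trace)
  if (!length(dark))
    stop_data("no dark-adapted pulse: Fm undefined")
  first_pulse <- min(trace$pulse_times[dark])
  pre <- trace$fluorescence[trace$time < first_pulse - window]
  if (!length(pre))
    stop_data("no pre-pulse dark baseline: Fo undefined")
  fo <- stats::median(pre)
  fm <- extract_pulses(trace, window)$fm
  if (fm <= fo) stop_data("Fm <= Fo: trace is not a dark-adapted induction")
  (fm - fo) / fm
}

#' Full NPQ analysis of a PAM trace
#'
#' Convenience wrapper: pulse extraction, NPQ kinetics, Fv/Fm and the
#' qE / slowly-relaxing decomposition.
#'
#' @param trace a [pam_trace()].
#' @param window pulse search half-width (s).
#' @param endpoint,k forwarded to [decompose_npq()].
#' @return An object of class `npq_result`.
#' @export
npq_analysis <- function(trace, window = 0.4, endpoint = "last", k = 1) {
  px <- extract_pulses(trace, window)
  npq <- compute_npq(px$fm, px$fm_prime)
  dec <- decompose_npq(npq, trace$schedule, endpoint = endpoint, k = k)
  structure(list(fm = px$fm, fm_prime = px$fm_prime, npq = npq,
                 fv_fm = fv_fm(trace, window), q_e = dec$q_e,
                 q_islow = dec$q_islow,
                 npq_light_end = dec$npq_light_end),
            class = "npq_result")
}

#' @export
print.npq_result <- function(x, ...) {
  cat("NPQ analysis\n")
  cat(sprintf("  Fm = %.4g, Fv/Fm = %.3f\n", x$fm, x$fv_fm))
  cat(sprintf("  NPQ at end of light = %.3f (qE %.3f, qI/qZ %.3f)\n",
              x$npq_light_end, x$q_e, x$q_islow))
  invisible(x)
}

#' @export
summary.npq_result <- function(object, ...) {
  cat("NPQ kinetics at pulse times:\n")
  print(utils::head(object$npq, 100))
  print(object)
  invisible(object)
}

#' Write / read a PAM trace as delimited text
#'
#' Tab-separated `time`, `fluorescence`, `irradiance`, `pulse` columns: the
#' light schedule travels as an inline irradiance annotation and pulse flag
#' rather than a sidecar file.
#'
#' @param trace a `pam_trace`.
#' @param path file path.
#' @export
write_pam_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pam_trace"))
  seg <- trace$schedule$segments
  bounds <- seg_bounds(trace$schedule)
  irr <- seg$irradiance[pmin(findInterval(trace$time, bounds,
                                          rightmost.closed = TRUE),
                             nrow(seg))]
  pulse <- as.integer(trace$time %in% trace$pulse_times)
  ## mark the sample nearest each pulse time
  pulse <- integer(length(trace$time))
  pulse[vapply(trace$pulse_times,
               function(tp) which.min(abs(trace$time - tp)), integer(1))] <- 1L
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pulse_interval_s: %g", trace$schedule$pulse_interval),
             con)
  utils::write.table(data.frame(time_s = trace$time,
                                fluorescence = trace$fluorescence,
                                irradiance = irr, pulse = pulse),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pam_trace
#' @export
read_pam_trace <- function(path) {
  hdr <- readLines(path, n = 1)
  pint <- if (grepl("^# pulse_interval_s:", hdr[1]))
    as.numeric(sub("^# pulse_interval_s: ", "", hdr[1])) else 60
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ## rebuild the segment structure from the irradiance annotation
  r <- rle(tab$irradiance)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  dur <- tab$time_s[ends] - c(tab$time_s[1] - diff(tab$time_s[1:2]),
                              tab$time_s[ends[-length(ends)]])
  sched <- light_schedule(pmax(dur, diff(tab$time_s[1:2])), r$values,
                          pulse_interval = pint)
  pam_trace(tab$time_s, tab$fluorescence, sched,
            pulse_times = tab$time_s[tab$pulse == 1])
}
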