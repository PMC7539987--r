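#' pH-activity profile of a violaxanthin de-epoxidase
#'
#' Violaxanthin de-epoxidase (VDE) is activated by lumen acidification: its
#' activity is maximal near pH 5.1 and falls off towards neutral pH. The
#' profile is modelled as a product of two logistic terms -- an acid-side rise
#' and an alkaline-side fall -- translated so that the analytic maximum sits
#' exactly at `ph_opt`, and normalized so the activity there equals 1.
#'
#' The steepness of the alkaline-side logistic controls how fast activity is
#' lost above the optimum; the chlorophyte enzyme loses activity at
#' neutral pH much faster than the plant enzyme, which the default profiles
#' encode (see [vde_ph_profile()]).
#'
#' @param ph_opt pH of maximal activity (default 5.1).
#' @param slope_acid steepness (per pH unit) of the acid-side activation.
#' @param slope_alkaline steepness (per pH unit) of the alkaline-side loss.
#' @param offset half-distance (pH units) between the two logistic midpoints.
#' @param species_label free-text label carried through printing.
#' @return An object of class `ph_profile`.
#' @examples
#' pr <- vde_ph_profile("c_vulgaris")
#' ph_activity(5.1, pr)  # 1 by construction
#' @export
ph_profile <- function(ph_opt = 5.1, slope_acid = 3, slope_alkaline = 3,
                       offset = 0.7, species_label = "custom") {
  check_finite(c(ph_opt, slope_acid, slope_alkaline, offset), "profile parameters")
  if (slope_acid <= 0 || slope_alkaline <= 0 || offset <= 0)
    stop_data("slopes and offset must be positive")
  raw <- function(ph) {
    stats::plogis(slope_acid * (ph - (ph_opt - offset))) *
      stats::plogis(-slope_alkaline * (ph - (ph_opt + offset)))
  }
  ## locate the analytic maximum of the raw product; translate so it lands on
  ## ph_opt exactly and scale to 1 there
  opt <- stats::optimize(raw, interval = c(ph_opt - 3 * offset, ph_opt + 3 * offset),
                         maximum = TRUE, tol = 1e-10)
  structure(list(ph_opt = ph_opt, slope_acid = slope_acid,
                 slope_alkaline = slope_alkaline, offset = offset,
                 shift = opt$maximum - ph_opt, peak_value = opt$objective,
                 species_label = species_label),
            class = "ph_profile")
}

#' Default VDE pH-activity profiles
#'
#' Both shipped profiles peak at pH 5.1. The *C. vulgaris* profile has a much
#' steeper alkaline-side slope than the *A. thaliana* profile, so that the
#' chlorophyte enzyme retains far less activity at neutral pH; the acid side
#' below the optimum is a modelling convention (it is not constrained by
#' enzyme assays in either species).
#'
#' @param species `"a_thaliana"` or `"c_vulgaris"`.
#' @return A `ph_profile`.
#' @export
vde_ph_profile <- function(species = c("c_vulgaris", "a_thaliana")) {
  species <- match.arg(species)
  switch(species,
    a_thaliana = ph_profile(5.1, slope_acid = 3.0, slope_alkaline = 2.0,
                            offset = 0.8, species_label = "A. thaliana"),
    c_vulgaris = ph_profile(5.1, slope_acid = 3.0, slope_alkaline = 6.0,
                            offset = 0.45, species_label = "C. vulgaris"))
}

#' Normalized VDE activity at a given pH
#'
#' @param ph pH value(s) in `[3, 9]`.
#' @param profile a [ph_profile()].
#' @return Activity fraction(s) in `[0, 1]`; exactly 1 at `profile$ph_opt`.
#' @export
ph_activity <- function(ph, profile) {
  stopifnot(inherits(profile, "ph_profile"))
  check_finite(ph, "ph")
  if (any(ph < 3 | ph > 9))
    stop_domain("pH outside the supported range [3, 9]")
  p <- profile
  x <- ph + p$shift  # evaluate the raw curve at its own coordinates
  raw <- stats::plogis(p$slope_acid * (x - (p$ph_opt - p$offset))) *
    stats::plogis(-p$slope_alkaline * (x - (p$ph_opt + p$offset)))
  pmin(raw / p$peak_value, 1)
}

#' @export
print.ph_profile <- function(x, ...) {
  cat("VDE pH-activity profile (", x$species_label, ")\n", sep = "")
  cat(sprintf("  optimum pH: %.2f (activity 1 by construction)\n", x$ph_opt))
  cat(sprintf("  slopes: acid %.2f, alkaline %.2f per pH unit\n",
              x$slope_acid, x$slope_alkaline))
  cat(sprintf("  activity at pH 7.0: %.3f\n", ph_activity(7, x)))
  invisible(x)
}

#' @export
predict.ph_profile <- function(object, ph = seq(4, 7.5, by = 0.1), ...) {
  data.frame(ph = ph, activity = ph_activity(ph, object))
}

#' @export
plot.ph_profile <- function(x, from = 3.5, to = 8, n = 200, ...) {
  ph <- seq(from, to, length.out = n)
  plot(ph, ph_activity(ph, x), type = "l", xlab = "pH",
       ylab = "relative VDE activity", main = x$species_label, ...)
  graphics::abline(v = x$ph_opt, lty = 3)
  invisible(x)
}
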