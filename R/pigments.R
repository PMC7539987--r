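#' Pigment profile
#'
#' Container for the xanthophyll-cycle pigments (violaxanthin, antheraxanthin,
#' zeaxanthin) and optional accessory pigments, all in one common unit
#' (typically mol per 100 chlorophylls, or uM for reconstituted assays).
#'
#' @param vio,ant,zea xanthophyll-cycle pigment concentrations (required).
#' @param neo,lut,beta_car,chl_a,chl_b optional accessory pigment
#'   concentrations in the same unit.
#' @param unit_label unit carried with the profile; never converted.
#' @param below_detection character vector of pigment names reported below
#'   the detection limit (bookkeeping from quantification).
#' @return An object of class `pigment_profile`.
#' @examples
#' p <- pigment_profile(vio = 2, ant = 1, zea = 1)
#' deepoxidation_index(p)  # 0.375
#' @export
pigment_profile <- function(vio, ant, zea, neo = NA_real_, lut = NA_real_,
                            beta_car = NA_real_, chl_a = NA_real_,
                            chl_b = NA_real_, unit_label = "mol / 100 Chl",
                            below_detection = character()) {
  conc <- c(vio = vio, ant = ant, zea = zea, neo = neo, lut = lut,
            beta_car = beta_car, chl_a = chl_a, chl_b = chl_b)
  known <- conc[!is.na(conc)]
  check_nonneg(unname(known), "pigment concentrations")
  structure(list(vio = vio, ant = ant, zea = zea, neo = neo, lut = lut,
                 beta_car = beta_car, chl_a = chl_a, chl_b = chl_b,
                 unit_label = unit_label, below_detection = below_detection),
            class = "pigment_profile")
}

#' De-epoxidation index
#'
#' DI = (\[Zea\] + 0.5 \[Ant\]) / (\[Zea\] + \[Ant\] + \[Vio\]). 0 means the
#' pool is fully epoxidated (all violaxanthin), 1 fully de-epoxidated (all
#' zeaxanthin); the intermediate antheraxanthin carries half weight because
#' only one of its two epoxide groups has been removed.
#'
#' @param p a [pigment_profile()], or the violaxanthin concentration if
#'   `ant` and `zea` are given.
#' @param ant,zea antheraxanthin and zeaxanthin concentrations when `p` is
#'   numeric.
#' @return DI in `[0, 1]`.
#' @export
deepoxidation_index <- function(p, ant = NULL, zea = NULL) {
  if (inherits(p, "pigment_profile")) {
    vio <- p$vio; ant <- p$ant; zea <- p$zea
  } else {
    vio <- p
    if (is.null(ant) || is.null(zea))
      stop_data("supply ant and zea when the first argument is numeric")
  }
  check_nonneg(c(vio, ant, zea), "pigment pools")
  tot <- vio + ant + zea
  if (any(tot <= 0))
    stop_domain("DI undefined: violaxanthin + antheraxanthin + zeaxanthin is zero")
  (zea + 0.5 * ant) / tot
}

#' @export
print.pigment_profile <- function(x, digits = 4, ...) {
  cat("Pigment profile [", x$unit_label, "]\n", sep = "")
  conc <- c(vio = x$vio, ant = x$ant, zea = x$zea, neo = x$neo, lut = x$lut,
            beta_car = x$beta_car, chl_a = x$chl_a, chl_b = x$chl_b)
  conc <- conc[!is.na(conc)]
  for (nm in names(conc))
    cat(sprintf("  %-9s %.*g%s\n", nm, digits, conc[[nm]],
                if (nm %in% x$below_detection) "  (below detection)" else ""))
  cat(sprintf("  DI = %.4f\n", deepoxidation_index(x)))
  invisible(x)
}

#' Write / read a pigment profile as delimited text
#'
#' Two-column tab-separated table (`pigment`, `concentration`) with the unit
#' recorded on a `# unit:` comment line.
#'
#' @param p a `pigment_profile`.
#' @param path file path.
#' @export
write_pigment_profile <- function(p, path) {
  stopifnot(inherits(p, "pigment_profile"))
  conc <- c(vio = p$vio, ant = p$ant, zea = p$zea, neo = p$neo, lut = p$lut,
            beta_car = p$beta_car, chl_a = p$chl_a, chl_b = p$chl_b)
  conc <- conc[!is.na(conc)]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# unit: ", p$unit_label), con)
  if (length(p$below_detection))
    writeLines(paste0("# below_detection: ",
                      paste(p$below_detection, collapse = ",")), con)
  utils::write.table(data.frame(pigment = names(conc),
                                concentration = unname(conc)),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pigment_profile
#' @param path file path.
#' @export
read_pigment_profile <- function(path) {
  hdr <- readLines(path, n = 5)
  unit <- sub("^# unit: ", "", grep("^# unit:", hdr, value = TRUE)[1])
  bd <- grep("^# below_detection:", hdr, value = TRUE)
  bd <- if (length(bd)) strsplit(sub("^# below_detection: ", "", bd[1]), ",")[[1]]
        else character()
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  conc <- stats::setNames(tab$concentration, tab$pigment)
  get <- function(nm) if (nm %in% names(conc)) conc[[nm]] else NA_real_
  pigment_profile(vio = get("vio"), ant = get("ant"), zea = get("zea"),
                  neo = get("neo"), lut = get("lut"),
                  beta_car = get("beta_car"), chl_a = get("chl_a"),
                  chl_b = get("chl_b"),
                  unit_label = if (is.na(unit)) "unknown" else unit,
                  below_detection = bd)
}
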