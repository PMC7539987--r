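#' Write / read a kinetic model as a flat key-value config file
#'
#' One `key = value` pair per line, `#` comments allowed. Unknown keys are
#' rejected on read. Default config files for both shipped species are
#' installed under `extdata/` (see
#' `system.file("extdata", package = "xanthoq")`).
#'
#' @param model a [kinetic_model()].
#' @param path file path.
#' @export
write_kinetic_config <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  p <- model$ph_profile
  fmt <- function(x) sprintf("%.17g", x)  # lossless numeric round trip
  kv <- c(
    species_label = model$species_label,
    k_de1 = fmt(model$k_de1), k_de2 = fmt(model$k_de2),
    k_ep = fmt(model$k_ep),
    dtt_inhibition = fmt(model$dtt_inhibition),
    vivo_rate_scale = fmt(model$vivo_rate_scale),
    ph_opt = fmt(p$ph_opt), slope_acid = fmt(p$slope_acid),
    slope_alkaline = fmt(p$slope_alkaline), ph_offset = fmt(p$offset),
    ph_dark = fmt(model$light_to_ph$ph_dark),
    ph_min = fmt(model$light_to_ph$ph_min),
    light_k_half = fmt(model$light_to_ph$k_half),
    ph_tau = fmt(model$light_to_ph$tau))
  qv <- vapply(model$q_params, fmt, "")
  names(qv) <- paste0("q_", names(model$q_params))
  kv <- c(kv, qv)
  writeLines(c("# xanthoq kinetic model configuration",
               sprintf("%s = %s", names(kv), unname(kv))), path)
  invisible(path)
}

#' @rdname write_kinetic_config
#' @export
read_kinetic_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(parts) != 2
  if (any(bad)) stop_data("malformed config line: ", lines[bad][1])
  kv <- stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
  known <- c("species_label", "k_de1", "k_de2", "k_ep", "dtt_inhibition",
             "vivo_rate_scale", "ph_opt", "slope_acid", "slope_alkaline",
             "ph_offset", "ph_dark", "ph_min", "light_k_half", "ph_tau",
             paste0("q_", names(default_q_params())))
  unknown <- setdiff(names(kv), known)
  if (length(unknown))
    stop_data("unknown config key(s): ", paste(unknown, collapse = ", "))
  num <- function(key, default) {
    if (key %in% names(kv)) as.numeric(kv[[key]]) else default
  }
  qp <- default_q_params()
  for (nm in names(qp)) qp[[nm]] <- num(paste0("q_", nm), qp[[nm]])
  profile <- ph_profile(ph_opt = num("ph_opt", 5.1),
                        slope_acid = num("slope_acid", 3),
                        slope_alkaline = num("slope_alkaline", 3),
                        offset = num("ph_offset", 0.7),
                        species_label = if ("species_label" %in% names(kv))
                          kv[["species_label"]] else "custom")
  kinetic_model(k_de1 = num("k_de1", NA), k_de2 = num("k_de2", NA),
                k_ep = num("k_ep", 0.02), ph_profile = profile,
                dtt_inhibition = num("dtt_inhibition", 0),
                light_to_ph = list(ph_dark = num("ph_dark", 7),
                                   ph_min = num("ph_min", 5),
                                   k_half = num("light_k_half", 500),
                                   tau = num("ph_tau", 30)),
                q_params = qp,
                vivo_rate_scale = num("vivo_rate_scale", 4),
                species_label = profile$species_label)
}
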