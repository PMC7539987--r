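#' @keywords internal
"_PACKAGE"

## Internal validation helpers ------------------------------------------------

stop_domain <- function(...) {
  stop(structure(class = c("xq_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("xq_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_convergence <- function(...) {
  stop(structure(class = c("xq_convergence_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, name) {
  if (!all(is.finite(x)))
    stop_data(name, " must be finite")
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_finite(x, name)
  if (any(x < 0)) stop_data(name, " must be non-negative")
  invisible(x)
}

## complementary error function, used by the decay model
erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
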