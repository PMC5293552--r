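#' @importFrom rlang %||% abort warn .data
#' @importFrom stats dnorm plogis rnorm runif var approx integrate
NULL

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 6 significant digits, the on-disk decimal convention used by all writers
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

assert_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}
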