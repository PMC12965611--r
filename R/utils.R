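#' @importFrom rlang abort warn inform
#' @importFrom stats predict rnorm runif sd quantile cor plogis rbinom setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

drp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "mographdrp_error"), ...)
}

# validated positive scalar integer
chk_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    drp_abort(sprintf("`%s` must be a single positive integer", name),
              "drp_config_error")
  as.integer(x)
}

chk_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x >= hi)
    drp_abort(sprintf("`%s` must be a number in [%s, %s)", name, lo, hi),
              "drp_config_error")
  as.numeric(x)
}

# sub-seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587)
}
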