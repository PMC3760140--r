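#' @importFrom rlang %||% .data
#' @importFrom stats rnorm runif rbinom plogis qlogis pnorm pchisq sd setNames
#' @keywords internal
"_PACKAGE"

# Reflect values into [lower, upper], applying the reflection map repeatedly
# until every element is inside the bounds.
reflect_into_bounds <- function(x, lower, upper) {
  stopifnot(lower < upper)
  while (any(x < lower | x > upper)) {
    x <- ifelse(x > upper, 2 * upper - x, x)
    x <- ifelse(x < lower, 2 * lower - x, x)
  }
  x
}

softmax2 <- function(u) {
  u <- u - max(u)
  e <- exp(u)
  e / sum(e)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

abort_bad_arg <- function(name, msg) {
  stop(sprintf("`%s` %s", name, msg), call. = FALSE)
}
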