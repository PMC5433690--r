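## shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## enum check helper: returns invisible(TRUE) or dies naming permitted values
check_enum <- function(x, allowed, what) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad) > 0L)
    stopf("invalid %s value(s) %s; permitted values: {%s}",
          what, paste0("'", bad, "'", collapse = ", "),
          paste(allowed, collapse = ", "))
  invisible(TRUE)
}

check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stopf("'%s' must contain probabilities in [0, 1]", what)
  invisible(TRUE)
}

#' Format a p-value in the report style
#'
#' P-values are printed with three decimals; values that would round to
#' 0.000 (that is, below 0.0005) are printed as `"< 0.001"`, matching the
#' convention of clinical summary tables.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of formatted p-values.
#' @examples
#' format_p(c(0.1963, 0.0004, 1))
#' @export
format_p <- function(p) {
  out <- ifelse(is.na(p), "-",
                ifelse(p < 0.0005, "< 0.001", sprintf("%.3f", p)))
  out
}

## moments of a truncated normal on [lo, hi] (used to validate recovery of
## rejection-sampled ages against the distribution actually simulated)
tnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}
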