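#' @keywords internal
"_PACKAGE"

# Half-up rounding to match how percentages are conventionally printed in
# clinical reports (55/120 -> 46%). base::round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Robust SD via scaled median absolute deviation.
robust_sd <- function(x) {
  stats::mad(x, constant = 1.4826)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}
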