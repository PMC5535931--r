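#' @keywords internal
"_PACKAGE"

# Round half away from zero; base round() ties to even, which does not match
# spectral-count occupancy reporting conventions (e.g. 21.875 -> 21.9).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Group mean with a detection floor applied to the aggregate.
floored_mean <- function(x, floor = 0.1) {
  max(mean(x), floor)
}

stop_apmsq <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_apmsq(what, " must be numeric in [0, 1]")
  }
  invisible(x)
}

# Stable lexicographic row order over every column, left to right (C locale).
canonical_row_order <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  keys <- lapply(df, function(col) if (is.character(col) || is.factor(col)) as.character(col) else col)
  do.call(order, c(unname(keys), list(method = "radix")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
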