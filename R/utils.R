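# Rounding that matches how the source tables were typeset: ties away from
# zero. base::round() is round-half-even, which disagrees on e.g. 0.985.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_positive <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

assert_nonnegative <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be nonnegative and finite", call. = FALSE)
  }
  invisible(x)
}
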