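#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the printed percentages in
#' the package's summary tables. Base R's `round()` rounds half to even,
#' which would print 22.5 as 22; clinical tables conventionally print 23.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector, rounded.
#' @examples
#' round_half_up(22.5)   # 23
#' round_half_up(0.255, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# shared abort helpers: every user-facing validation error carries a class
# prefixed "sharedcare_" so callers can condition on it
abort_sc <- function(message, class) {
  rlang::abort(message, class = paste0("sharedcare_", class))
}

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    abort_sc(sprintf("`%s` must be a single probability%s, got %s.",
                     name, if (open) " strictly inside (0, 1)" else "",
                     paste(format(x), collapse = ", ")),
             "invalid_design")
  }
  invisible(x)
}

# derive a stream of child seeds (< 2^31) from one user seed
child_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  (as.double(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647 + 1
}
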