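#' Round half away from zero
#'
#' Commercial ("half-up") rounding, matching how the study's tables print
#' values. `base::round()` rounds half to even, which disagrees on exact
#' .5 ties (e.g. 0.25 -> 0.2 instead of 0.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(11.15, 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# internal: stop with a classed condition so tests can match on class
stop_vlcfa <- function(msg, class) {
  abort(msg, class = c(class, "vlcfa_error"))
}

# internal: check a scalar is a single non-NA value of given predicate
assert_scalar <- function(x, what, ok) {
  if (length(x) != 1 || is.na(x) || !ok(x)) {
    stop_vlcfa(sprintf("`%s` must be a single valid value", what),
               "vlcfa_bad_argument")
  }
  invisible(x)
}
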