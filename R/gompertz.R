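#' Inverse-CDF draw from a Gompertz lifespan distribution
#'
#' The Gompertz hazard \eqn{h(t) = a e^{bt}} is the canonical model of adult
#' insect mortality: a baseline rate `a` that doubles every `log(2)/b` days.
#' The corresponding survival function is
#' \eqn{S(t) = \exp\{-(a/b)(e^{bt} - 1)\}}, which inverts in closed form, so
#' a uniform variate `u` maps to the death time
#' \deqn{t = (1/b) \log\{1 - (b/a) \log u\}.}
#'
#' @param a Baseline hazard scale per day (> 0).
#' @param b Exponential rate of hazard increase per day (> 0).
#' @param u Uniform variate(s) in (0, 1); vectorised. `a` may also be a
#'   vector (per-individual hazard scale), recycled against `u`.
#' @return Death time(s) in days, strictly positive.
#' @examples
#' # median of a Gompertz with a doubling time of ~7 days
#' sample_gompertz(3.5e-4, 0.1, 0.5)
#' @export
sample_gompertz <- function(a, b, u) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("`a` must be positive and finite", call. = FALSE)
  }
  if (length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("`b` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1)) {
    stop("`u` must lie strictly inside (0, 1)", call. = FALSE)
  }
  log1p(-(b / a) * log(u)) / b
}

#' Gompertz survival function
#'
#' @inheritParams sample_gompertz
#' @param t Time(s) in days, >= 0.
#' @return S(t) = exp(-(a/b)(e^{bt} - 1)).
#' @export
gompertz_survival <- function(t, a, b) {
  exp(-(a / b) * expm1(b * t))
}
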