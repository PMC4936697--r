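#' Sugar Factory production dynamics
#'
#' One turn of the factory: with workforce `x` and current production `p`
#' (both in thousands-of-tons / worker units 1..12), the next production is
#' `clip(2 x - p + u_r, 1, 12)`, where `u_r` is the environment noise in
#' `{-1, 0, 1}`. Participants are never told this rule; the doubling and
#' the negative dependence on current production are what make the system
#' intransparent.
#'
#' @param p Current production, integer in 1..12.
#' @param x Workforce, integer in 1..12.
#' @param u_r Environment noise, in `{-1, 0, 1}`.
#' @return Next production, integer in 1..12. Vectorized.
#' @examples
#' production_step(6, 7, 0)  # 8
#' @export
production_step <- function(p, x, u_r) {
  if (any(p < 1 | p > 12) || any(x < 1 | x > 12) || any(!u_r %in% c(-1, 0, 1))) {
    stop("production_step inputs out of range")
  }
  pmin(pmax(2 * x - p + u_r, 1), 12)
}

#' On-target indicator
#'
#' A production is scored as on target when it lies within one unit of the
#' goal production 9, i.e. in `{8, 9, 10}`. The band compensates for the
#' `u_r` noise, so that staying on target every round is achievable.
#'
#' @param p Production, integer in 1..12.
#' @return 0/1 indicator. Vectorized.
#' @export
on_target <- function(p) {
  if (any(p < 1 | p > 12)) stop("production out of range")
  as.integer(abs(p - 9) <= 1)
}

#' Episode score
#'
#' The score of an episode is the number of rounds on target.
#'
#' @param indicators Vector of 0/1 per-round indicators.
#' @return Integer sum, in `[0, length(indicators)]`.
#' @export
episode_score <- function(indicators) {
  if (any(!indicators %in% c(0L, 1L))) stop("indicators must be 0/1")
  as.integer(sum(indicators))
}
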