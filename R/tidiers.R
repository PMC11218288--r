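#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulated training course
#'
#' One row per round: performance, requirements, parameters and the
#' controller's decision.
#'
#' @param x A `dda_course` from [simulate_course()].
#' @param ... Unused.
#' @return A tibble, `nrow == n_rounds`.
#' @export
tidy.dda_course <- function(x, ...) {
  x$trajectory
}

#' One-row summary of a training course
#'
#' @param x A `dda_course`.
#' @param window Rolling-mean window (rounds) for the comfort-band share.
#' @param ... Unused.
#' @return A one-row tibble: round counts, mean hit rates, the share of
#'   the last 50 rounds whose rolling hit rate sat in the comfort band,
#'   final requirements and points.
#' @export
glance.dda_course <- function(x, window = 10, ...) {
  tr <- x$trajectory
  roll <- rolling_hit_rate(tr$hit_rate, window = window)
  last50 <- utils::tail(seq_len(nrow(tr)), 50)
  lo <- x$dda$lower_hit_threshold
  up <- x$dda$upper_hit_threshold
  fr <- x$final_requirements
  tibble::tibble(
    n_rounds = nrow(tr),
    mean_hit_rate = mean(tr$hit_rate),
    mean_hit_rate_last50 = mean(tr$hit_rate[last50]),
    in_band_share_last50 = mean(roll[last50] >= lo & roll[last50] <= up),
    final_range_azimuth = fr$range_requirement[["shoulder_azimuth"]],
    final_range_elevation = fr$range_requirement[["shoulder_elevation"]],
    final_range_elbow = fr$range_requirement[["elbow"]],
    final_strength = fr$strength_requirement,
    total_points = sum(tr$points)
  )
}

#' Rolling per-round hit rate
#'
#' Mean of the last `window` rounds' hit rates at each round (fewer at
#' the start of the course). This is the statistic used to judge whether
#' the controller holds the player inside the comfort band: the per-round
#' hit rate of a ~9-target round is quantized to ninths, so band
#' membership is assessed on the smoothed rate.
#'
#' @param hit_rates Numeric vector of per-round hit rates.
#' @param window Number of rounds to average over (default 10).
#' @return Numeric vector, same length.
#' @export
rolling_hit_rate <- function(hit_rates, window = 10) {
  n <- length(hit_rates)
  vapply(seq_len(n), function(k) {
    mean(hit_rates[max(1, k - window + 1):k])
  }, numeric(1))
}
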