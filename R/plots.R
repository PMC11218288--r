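#' Plot a training-course trajectory
#'
#' Three stacked panels over rounds: rolling hit rate against the
#' comfort band, the range requirements, and the strength requirement.
#'
#' @param object A `dda_course` from [simulate_course()].
#' @param window Rolling window for the smoothed hit rate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dda_course <- function(object, window = 10, ...) {
  tr <- object$trajectory
  tr$rolling <- rolling_hit_rate(tr$hit_rate, window)
  long <- dplyr::bind_rows(
    tibble::tibble(round = tr$round, panel = "hit rate (rolling)",
                   series = "hit rate", value = tr$rolling),
    tidyr::pivot_longer(
      tr[, c("round", "range_req_azimuth", "range_req_elevation",
             "range_req_elbow")],
      -"round", names_to = "series", values_to = "value",
      names_prefix = "range_req_") |>
      dplyr::mutate(panel = "range requirement (deg)"),
    tibble::tibble(round = tr$round, panel = "strength requirement",
                   series = "strength", value = tr$strength_req)
  )
  band <- tibble::tibble(panel = "hit rate (rolling)",
                         ymin = object$dda$lower_hit_threshold,
                         ymax = object$dda$upper_hit_threshold)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_rect(data = band,
                       ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                       xmin = -Inf, xmax = Inf, inherit.aes = FALSE,
                       fill = "grey85", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "round", y = NULL, colour = NULL,
                  title = "Adaptive difficulty trajectory") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the DDA controller surface
#'
#' Evaluates [compute_adjustment()] on a hit-rate x miss-beyond grid and
#' renders one output (range or strength adjustment, as the signed
#' percentage of the maximum step) as a filled raster: the flat zero
#' band between the thresholds, the graded reduction region below, and
#' the increase region above.
#'
#' @param dda A [dda_config()].
#' @param output `"range_pct"` or `"strength_pct"`.
#' @param n Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_dda_surface <- function(dda = dda_config(), output = c("range_pct",
                                                            "strength_pct"),
                             n = 61) {
  output <- match.arg(output)
  grid <- tidyr::expand_grid(hit_rate = seq(0, 1, length.out = n),
                             miss_beyond = seq(0, 1, length.out = n))
  grid$value <- purrr::map2_dbl(grid$hit_rate, grid$miss_beyond, function(h, m) {
    n_t <- 100L
    n_h <- round(h * n_t)
    n_m <- n_t - n_h
    pos <- if (n_m > 0) c(rep(0.9, round(m * n_m)),
                          rep(0.1, n_m - round(m * n_m))) else numeric()
    perf <- round_performance(n_t, n_h, pos, dda$range_fraction_threshold)
    compute_adjustment(perf, dda)[[output]]
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$hit_rate, y = .data$miss_beyond,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "hit rate", y = "beyond-range miss share",
                  fill = paste0(output, "\n(of max step)"),
                  title = "DDA controller surface") +
    ggplot2::theme_minimal()
}

#' Plot a fuzzy partition
#'
#' Membership curves of every set over the support; the default strength
#' partition shows the III/IV/V split of the MMT-grade axis.
#'
#' @param partition A [fuzzy_partition()].
#' @param n Evaluation points.
#' @return A ggplot object.
#' @export
plot_partition <- function(partition = strength_partition(), n = 401) {
  grid <- seq(partition$support[1], partition$support[2], length.out = n)
  long <- purrr::imap(partition$sets, function(mf, lab) {
    tibble::tibble(x = grid, set = lab,
                   degree = evaluate_membership(grid, mf))
  }) |> dplyr::bind_rows()
  long$set <- factor(long$set, levels = names(partition$sets))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$degree,
                                     colour = .data$set)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "variable", y = "membership degree", colour = "set") +
    ggplot2::theme_minimal()
}
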