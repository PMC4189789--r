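# Publication-style summary figure.

#' Plot block success rates against gap distance
#'
#' Group mean (+/- SEM over mice) percent successful crossings per gap
#' distance, one line per session block, faceted by genotype -- the
#' standard way of displaying tactile-learning performance on this assay.
#'
#' @param summary a [block_rates()] result.
#' @return a ggplot object.
#' @export
plot_block_rates <- function(summary) {
  stopifnot(inherits(summary, "block_summary"))
  sem <- function(x) if (length(x) < 2L) 0 else sd(x) / sqrt(length(x))
  d <- summary$rates |>
    dplyr::filter(!is.na(.data$rate)) |>
    dplyr::group_by(.data$genotype, .data$distance_cm, .data$block) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     sem_rate = sem(.data$rate), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$distance_cm, y = .data$mean_rate,
    colour = .data$block, group = .data$block)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rate - .data$sem_rate,
      ymax = .data$mean_rate + .data$sem_rate)) +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = "Gap distance (cm)", y = "Successful crossings (%)",
                  colour = "Sessions") +
    ggplot2::theme_classic()
}
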