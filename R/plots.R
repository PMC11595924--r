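#' Plot a rank table
#'
#' Scatter of average rank against aggregate STI, the two selection indices:
#' tolerant accessions sit top-left (high STI, low AR). The best and worst
#' few accessions are labelled.
#'
#' @param object A `peg_rank_table`.
#' @param n_label Number of accessions to label at each extreme (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peg_rank_table <- function(object, n_label = 3, ...) {
  df <- tibble::as_tibble(object)
  lab <- df[df$final_rank <= n_label |
              df$final_rank > nrow(df) - n_label, ]
  ggplot2::ggplot(df, ggplot2::aes(x = ar, y = sti)) +
    ggplot2::geom_point(ggplot2::aes(colour = final_rank)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = accession),
                       vjust = -0.6, size = 3) +
    ggplot2::scale_colour_viridis_c(direction = -1) +
    ggplot2::labs(
      x = "average rank (AR, lower = better)",
      y = "stress tolerance index (STI, higher = better)",
      colour = "final rank",
      title = paste0("Accession ranking (", df$scope[1], " scope)")
    ) +
    ggplot2::theme_minimal()
}

#' Plot trait dose response
#'
#' Accession-mean distributions of one trait across the three treatments —
#' the summary underlying box-chart figures in germination screens.
#'
#' @param data A study table.
#' @param trait Trait code.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(data, trait) {
  trait_code <- trait
  am <- accession_means(as_study_table(data)) |>
    dplyr::filter(.data$trait == trait_code)
  td <- trait_descriptors()
  units <- td$units[td$trait == trait_code]
  ggplot2::ggplot(am, ggplot2::aes(x = treatment, y = mean_value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "treatment (PEG dose)",
                  y = paste0(trait_code, " (", units, ")"),
                  title = paste0(trait_code, " across stress levels")) +
    ggplot2::theme_minimal()
}

#' Plot tolerance-class trait profiles
#'
#' Class means with standard-deviation bars per stress treatment, for the
#' traits in a biomarker report.
#'
#' @param object A `peg_biomarker_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.peg_biomarker_report <- function(object, ...) {
  df <- tidyr::unnest(tibble::as_tibble(object)[c("groups")], "groups")
  ggplot2::ggplot(df, ggplot2::aes(x = class, y = mean, fill = class)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           width = 0.25) +
    ggplot2::facet_grid(trait ~ treatment, scales = "free_y") +
    ggplot2::labs(x = "tolerance class", y = "class mean ± SD") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
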