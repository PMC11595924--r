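#' Compare tolerance classes on one trait under one stress treatment
#'
#' The integrative ("omics-style") step of the screen: once accessions are
#' classified as high / moderate / low tolerance, each trait is tested for
#' differences between the classes under each stress level. Statistics are
#' computed over *accession means* within each class (one value per
#' accession), so the reported standard deviations reflect between-accession
#' spread; set `level = "replicate"` to work on raw replicate values instead.
#' A one-way ANOVA across classes provides the p-value and the error term
#' protecting the Duncan letter display on the class means.
#'
#' @param data A study table.
#' @param classes A [classify()] result (accession -> class).
#' @param trait Trait code.
#' @param treatment Stress treatment (`"T1"` or `"T2"`).
#' @param alpha Significance level for the letters and the `significant`
#'   flag; default 0.01.
#' @param level `"accession"` (default) or `"replicate"`.
#' @return A `peg_group_stats` tibble with one row per class: `trait`,
#'   `treatment`, `class`, `n`, `mean`, `sd`, `letters`; attributes
#'   `p_value`, `significant`, `alpha`.
#' @export
group_trait_stats <- function(data, classes, trait, treatment, alpha = 0.01,
                              level = c("accession", "replicate")) {
  data <- as_study_table(data)
  level <- match.arg(level)
  trait_code <- trait
  treatment_code <- normalize_treatment(treatment)
  sub <- dplyr::filter(data, .data$trait == trait_code,
                       .data$treatment == treatment_code)
  if (nrow(sub) == 0) {
    abort(paste0("No observations for ", trait_code, " under ",
                 treatment_code, "."),
          class = "pegscreen_validation_error")
  }
  obs <- if (level == "accession") {
    sub |>
      dplyr::group_by(accession) |>
      dplyr::summarise(value = mean(value), .groups = "drop")
  } else {
    dplyr::select(sub, accession, value)
  }
  merged <- dplyr::inner_join(obs,
                              tibble::as_tibble(classes)[c("accession", "class")],
                              by = "accession")
  sizes <- table(merged$class)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Every tolerance class needs at least two members with data.",
          class = "pegscreen_validation_error")
  }
  fit <- one_way_anova(split(merged$value, merged$class))
  g <- glance(fit)
  p_value <- fit$p_value[fit$source == "between"]

  stats <- merged |>
    dplyr::group_by(class) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(value), sd = sd(value),
                     .groups = "drop")
  class_means <- setNames(stats$mean, as.character(stats$class))
  dm <- duncan_letters(class_means,
                       n_per_mean = setNames(stats$n, as.character(stats$class))[names(class_means)],
                       mse = g$mse, error_df = g$df_error, alpha = alpha)
  letter_map <- setNames(dm$groups$letters, dm$groups$level)

  out <- stats |>
    dplyr::mutate(trait = trait_code, treatment = treatment_code,
                  letters = unname(letter_map[as.character(class)])) |>
    dplyr::select(trait, treatment, class, n, mean, sd, letters)
  attr(out, "p_value") <- p_value
  attr(out, "significant") <- is.finite(p_value) && p_value <= alpha
  attr(out, "alpha") <- alpha
  class(out) <- c("peg_group_stats", class(out))
  out
}

#' Biomarker report over traits and stress treatments
#'
#' Runs [group_trait_stats()] for every requested trait under every stress
#' treatment and collects the class means, letters and p-values into one
#' table.
#'
#' @param data A study table.
#' @param classes A [classify()] result.
#' @param traits Traits to analyse; defaults to the seven biochemical traits.
#' @param stress_treatments Stress levels; default `c("T1", "T2")`.
#' @inheritParams group_trait_stats
#' @return A `peg_biomarker_report` tibble with one row per
#'   (trait, treatment): `trait`, `treatment`, `p_value`, `significant`, and
#'   a `groups` list-column of per-class statistics.
#' @export
biomarker_report <- function(data, classes,
                             traits = NULL,
                             stress_treatments = c("T1", "T2"),
                             alpha = 0.01,
                             level = c("accession", "replicate")) {
  level <- match.arg(level)
  td <- trait_descriptors()
  traits <- traits %||% td$trait[td$category == "biochemical"]
  combos <- expand.grid(trait = traits, treatment = stress_treatments,
                        stringsAsFactors = FALSE)
  rows <- purrr::pmap(combos, function(trait, treatment) {
    gs <- group_trait_stats(data, classes, trait, treatment,
                            alpha = alpha, level = level)
    tibble::tibble(
      trait = trait, treatment = treatment,
      p_value = attr(gs, "p_value"),
      significant = attr(gs, "significant"),
      groups = list(tibble::as_tibble(gs))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("peg_biomarker_report", class(out))
  out
}

#' Identify biomarker traits
#'
#' A trait qualifies as a biomarker when its tolerance-class comparison is
#' significant under *every* stress treatment in the report (conjunction
#' rule). Traits are returned ordered by their worst-case (largest) p-value,
#' most convincing first.
#'
#' @param report A [biomarker_report()] (or any tibble with `trait`,
#'   `treatment`, `p_value` columns).
#' @param alpha Significance threshold; defaults to the report's alpha.
#' @return A tibble `trait`, `worst_p`, possibly empty.
#' @export
identify_biomarkers <- function(report, alpha = NULL) {
  alpha <- alpha %||% attr(report, "alpha") %||% 0.01
  if (nrow(report) == 0) {
    abort("Empty biomarker report.", class = "pegscreen_invalid_input")
  }
  n_treat <- length(unique(report$treatment))
  report |>
    dplyr::group_by(trait) |>
    dplyr::summarise(
      worst_p = max(p_value),
      all_sig = dplyr::n() == n_treat && all(p_value <= alpha),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$all_sig) |>
    dplyr::arrange(.data$worst_p) |>
    dplyr::select(trait, worst_p)
}
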