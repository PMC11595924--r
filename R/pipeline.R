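# prefix stage name onto any error escaping a pipeline stage
with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      abort(paste0("Stage '", stage, "' failed: ", conditionMessage(e)),
            class = "pegscreen_pipeline_error", parent = e)
    }
  )
}

#' Format p-values for reports
#'
#' Values below `1e-4` print as `"<0.0001"`; others are rounded to four
#' decimals. Internal computations always keep full precision; this runs at
#' the report layer only.
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001", formatC(round(p, 4), format = "fg")))
}

#' Read a ranking configuration from YAML
#'
#' The file may declare `ranked_traits`, `sti_traits`, `orientation` (a
#' trait-to-orientation map) and `final_order_policy` (a scope-to-policy
#' map); omitted fields keep the [ranking_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `peg_ranking_config`.
#' @export
read_ranking_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- ranking_config()
  policy <- defaults$final_order_policy
  if (!is.null(y$final_order_policy)) {
    upd <- unlist(y$final_order_policy)
    policy[names(upd)] <- upd
  }
  ranking_config(
    ranked_traits = y$ranked_traits %||% defaults$ranked_traits,
    sti_traits = y$sti_traits %||% defaults$sti_traits,
    orientation = unlist(y$orientation) %||% character(),
    final_order_policy = policy
  )
}

# Table-2-shaped two-way ANOVA report: one row per trait
anova_report_table <- function(study, alpha_stars = 0.001) {
  traits <- intersect(trait_names(), unique(study$trait))
  purrr::map_dfr(traits, function(tr) {
    tab <- two_way_anova(study, tr)
    eff <- function(src, col) tab[[col]][tab$source == src]
    tibble::tibble(
      trait = tr,
      ms_accession = round(eff("accession", "mean_sq"), 2),
      p_accession = format_p_value(eff("accession", "p_value")),
      stars_accession = significance_stars(eff("accession", "p_value")),
      ms_peg = round(eff("peg", "mean_sq"), 2),
      p_peg = format_p_value(eff("peg", "p_value")),
      stars_peg = significance_stars(eff("peg", "p_value")),
      ms_interaction = round(eff("interaction", "mean_sq"), 2),
      p_interaction = format_p_value(eff("interaction", "p_value")),
      stars_interaction = significance_stars(eff("interaction", "p_value")),
      degenerate = attr(tab, "degenerate")
    )
  })
}

# Table-3-shaped rank report for one scope
rank_report_table <- function(rank_table) {
  tibble::tibble(
    accession = rank_table$accession,
    sti = round(rank_table$sti, 2),
    ar = round(rank_table$ar, 2),
    rank = rank_table$final_rank
  )
}

# Table-4-shaped biomarker report: one row per (treatment, trait) with
# "mean +/- sd letter" per class
biomarker_report_table <- function(report) {
  purrr::pmap_dfr(report, function(trait, treatment, p_value, significant, groups) {
    cells <- setNames(
      sprintf("%.2f ± %.2f %s", groups$mean, groups$sd, groups$letters),
      as.character(groups$class)
    )
    tibble::tibble(
      treatment = treatment, trait = trait,
      p_value = format_p_value(p_value),
      significant = ifelse(significant, "Yes", "No"),
      high = cells[["high"]], moderate = cells[["moderate"]],
      low = cells[["low"]]
    )
  })
}

#' Run the full screening pipeline
#'
#' Orchestrates every stage on one input source — either a study-table CSV
#' (`input`) or the synthetic generator (`generator`), never both — and
#' writes the standard report bundle to `outdir`:
#'
#' * `descriptives.csv` — min/max/mean and accession-effect F per trait and
#'   treatment;
#' * `anova.csv` — two-way accession x PEG mean squares and p-values per
#'   trait;
#' * `rank_T1.csv`, `rank_T2.csv`, `rank_combined.csv` — STI/AR rank tables;
#' * `classes.csv` — tolerance classes from the combined scope;
#' * `biomarkers.csv` — tolerance-class comparison per biochemical trait and
#'   stress level;
#' * `run_log.txt` — configuration echo, seed and package version.
#'
#' Report values are rounded to two decimals (round-half-even) at emission
#' only; the returned bundle keeps full precision. Given a seed the run is
#' deterministic.
#'
#' @param input Path to a study-table CSV, or a data frame.
#' @param generator A [generator_config()] used instead of `input`.
#' @param ranking A [ranking_config()].
#' @param alpha Significance level for letters and biomarker flags
#'   (default 0.01).
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param seed Optional seed; overrides the generator's.
#' @return Invisibly, a list with elements `study`, `descriptives`, `anova`,
#'   `ranks` (list of three `peg_rank_table`s), `classes`, `biomarkers` and
#'   `biomarker_traits`.
#' @export
run_full_pipeline <- function(input = NULL, generator = NULL,
                              ranking = ranking_config(), alpha = 0.01,
                              outdir = NULL, seed = NULL) {
  if (is.null(input) == is.null(generator)) {
    abort("Provide exactly one input source: `input` or `generator`.",
          class = "pegscreen_invalid_input")
  }
  if (!is.null(generator)) {
    if (!is.null(seed)) generator$seed <- seed
    sim <- with_stage("simulate", generate_study(generator))
    study <- sim$study
  } else if (is.character(input)) {
    study <- with_stage("read", read_trait_table(input))
  } else {
    study <- with_stage("read", as_study_table(input))
  }

  descriptives <- with_stage("summarize", summarize_study(study))
  anova_tab <- with_stage("anova", anova_report_table(study))
  if (any(anova_tab$degenerate)) {
    warn(paste0("Degenerate ANOVA (zero error variance) for trait(s): ",
                paste(anova_tab$trait[anova_tab$degenerate], collapse = ", "),
                "."))
  }
  ranks <- lapply(c(T1 = "T1", T2 = "T2", combined = "combined"), function(sc) {
    with_stage("rank", build_rank_table(study, ranking, scope = sc))
  })
  classes <- with_stage("classify", classify(ranks$combined))
  biomark <- with_stage("biomarkers",
                        biomarker_report(study, classes, alpha = alpha))
  biomarker_traits <- identify_biomarkers(biomark)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_csv(x, file.path(outdir, f), progress = FALSE)
    w(dplyr::mutate(descriptives,
                    dplyr::across(c(min, max, mean, f_statistic), ~ round(.x, 2)),
                    p_value = format_p_value(p_value)),
      "descriptives.csv")
    w(anova_tab, "anova.csv")
    for (sc in names(ranks)) w(rank_report_table(ranks[[sc]]),
                               paste0("rank_", sc, ".csv"))
    w(tibble::as_tibble(classes), "classes.csv")
    w(biomarker_report_table(biomark), "biomarkers.csv")
    log_lines <- c(
      paste0("pegscreen ", as.character(utils::packageVersion("pegscreen"))),
      paste0("seed: ", seed %||% generator$seed %||% "none"),
      paste0("alpha: ", alpha),
      paste0("input: ", if (is.null(generator)) "file/data" else "generator"),
      paste0("ranked_traits: ", paste(ranking$ranked_traits, collapse = ",")),
      paste0("sti_traits: ", paste(ranking$sti_traits, collapse = ",")),
      paste0("order_policy: ",
             paste(names(ranking$final_order_policy),
                   ranking$final_order_policy, sep = "=", collapse = " ")),
      paste0("biomarkers: ",
             paste(biomarker_traits$trait, collapse = ",") %||% "")
    )
    writeLines(log_lines, file.path(outdir, "run_log.txt"))
  }

  invisible(list(study = study, descriptives = descriptives,
                 anova = anova_tab, ranks = ranks, classes = classes,
                 biomarkers = biomark, biomarker_traits = biomarker_traits))
}
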