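#' Assemble and validate a study table
#'
#' A study table is the package's central container: one row per observed
#' replicate, keyed by `(accession, treatment, trait, replicate)`, with the
#' measured `value`. `study_table()` validates a data frame and returns it as a
#' classed tibble; every analysis function accepts either a validated table or
#' a plain data frame with the same columns (validation then runs on entry).
#'
#' Validation enforces: the five required columns; treatments parseable as
#' `T0`/`T1`/`T2` or as PEG percentages `0`/`7.5`/`15`; trait names drawn from
#' [trait_names()]; finite non-negative values with `GP` in `[0, 100]`;
#' positive integer replicates; and no duplicated key. Missing cells are
#' permitted (absence propagates); presence of the `T0` control is *not*
#' required here — it is checked by the stages that need it (the stress
#' tolerance index).
#'
#' @param data A data frame with columns `accession`, `treatment`,
#'   `replicate`, `trait`, `value`.
#' @return A `peg_study` tibble with normalised treatment codes.
#' @examples
#' study_table(data.frame(
#'   accession = "AC1", treatment = c("T0", "T1", "T2"),
#'   replicate = 1L, trait = "GP", value = c(96, 88, 72)
#' ))
#' @export
study_table <- function(data) {
  required <- c("accession", "treatment", "replicate", "trait", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Study table is missing column(s): ",
             paste(missing_cols, collapse = ", "), "."),
      class = "pegscreen_validation_error"
    )
  }
  data <- tibble::as_tibble(data)[required]
  data$accession <- as.character(data$accession)
  data$trait <- as.character(data$trait)

  tr <- normalize_treatment(data$treatment)
  if (anyNA(tr)) {
    bad <- which(is.na(tr))
    abort(
      paste0("Unrecognised treatment at row(s) ",
             paste(head(bad, 5), collapse = ", "),
             ": use T0/T1/T2 or PEG percent 0/7.5/15."),
      class = "pegscreen_validation_error"
    )
  }
  data$treatment <- tr

  unknown <- !(data$trait %in% trait_names())
  if (any(unknown)) {
    abort(
      paste0("Unknown trait(s) ",
             paste(unique(data$trait[unknown]), collapse = ", "),
             " at row(s) ", paste(head(which(unknown), 5), collapse = ", "),
             ". Permitted traits: ", paste(trait_names(), collapse = ", "), "."),
      class = "pegscreen_validation_error"
    )
  }

  data$value <- as.numeric(data$value)
  bad_value <- !is.finite(data$value) | data$value < 0
  bad_value <- bad_value | (data$trait == "GP" & data$value > 100)
  if (any(bad_value)) {
    abort(
      paste0("Invalid value (non-finite, negative, or GP outside [0, 100]) ",
             "at row(s) ", paste(head(which(bad_value), 5), collapse = ", "), "."),
      class = "pegscreen_validation_error"
    )
  }

  rep_num <- suppressWarnings(as.numeric(data$replicate))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    abort("`replicate` must contain positive integers.",
          class = "pegscreen_validation_error")
  }
  data$replicate <- as.integer(rep_num)

  dup <- duplicated(data[c("accession", "treatment", "trait", "replicate")])
  if (any(dup)) {
    first_dup <- which(dup)[1]
    abort(
      paste0("Duplicate (accession, treatment, trait, replicate) key at row ",
             first_dup, ": ", data$accession[first_dup], "/",
             data$treatment[first_dup], "/", data$trait[first_dup],
             "/rep ", data$replicate[first_dup], "."),
      class = "pegscreen_validation_error"
    )
  }

  class(data) <- c("peg_study", class(data))
  data
}

as_study_table <- function(data) {
  if (inherits(data, "peg_study")) data else study_table(data)
}

#' Read or write a study table as CSV
#'
#' The on-disk format is a plain UTF-8 comma-separated file with a header row
#' `accession,treatment,replicate,trait,value` (decimal point, not comma).
#' `read_trait_table()` validates on load; `write_trait_table()` round-trips
#' with it field-for-field.
#'
#' @param path File path.
#' @param data A study table (or coercible data frame).
#' @return `read_trait_table()` returns a validated `peg_study` tibble;
#'   `write_trait_table()` invisibly returns `path`.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "pegscreen_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  study_table(raw)
}

#' @rdname read_trait_table
#' @export
write_trait_table <- function(data, path) {
  data <- as_study_table(data)
  if (nrow(data) == 0) {
    abort("Refusing to write an empty study table.",
          class = "pegscreen_validation_error")
  }
  readr::write_csv(as.data.frame(data), path, progress = FALSE)
  invisible(path)
}

#' Accession-level means over replicates
#'
#' Averages replicate values within each `(accession, treatment, trait)` cell.
#' Cells with no data are absent from the output, never imputed as zero.
#'
#' @param data A study table.
#' @return A tibble with columns `accession`, `treatment`, `trait`,
#'   `mean_value`, `n_reps`.
#' @export
accession_means <- function(data) {
  data <- as_study_table(data)
  data |>
    dplyr::group_by(accession, treatment, trait) |>
    dplyr::summarise(
      mean_value = mean(value),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
}

#' Descriptive summary of one trait under one treatment
#'
#' Reproduces the layout of a screening study's descriptive table: the
#' minimum, maximum and mean of the accession-level means, plus the F
#' statistic and p-value of a one-way completely-randomised-design ANOVA with
#' accession as the factor (replicates as the error term). With zero
#' within-accession variance the F ratio is degenerate and is flagged rather
#' than reported as a number.
#'
#' @param data A study table.
#' @param trait Trait code, e.g. `"GP"`.
#' @param treatment Treatment code `"T0"`, `"T1"` or `"T2"`.
#' @return A one-row tibble: `trait`, `treatment`, `min`, `max`, `mean`,
#'   `f_statistic`, `p_value`, `degenerate`.
#' @export
summarize_trait <- function(data, trait, treatment) {
  data <- as_study_table(data)
  trait_code <- trait
  treatment_code <- normalize_treatment(treatment)
  sub <- dplyr::filter(data, .data$trait == trait_code,
                       .data$treatment == treatment_code)
  if (nrow(sub) == 0) {
    abort(paste0("No observations for ", trait_code, " under ",
                 treatment_code, "."),
          class = "pegscreen_validation_error")
  }
  cell_means <- sub |>
    dplyr::group_by(accession) |>
    dplyr::summarise(m = mean(value), n = dplyr::n(), .groups = "drop")
  if (nrow(cell_means) < 2) {
    abort("Descriptive summary needs at least two accessions.",
          class = "pegscreen_validation_error")
  }
  if (any(cell_means$n < 2)) {
    abort("Descriptive summary needs at least two replicates per accession.",
          class = "pegscreen_validation_error")
  }
  groups <- split(sub$value, sub$accession)
  fit <- one_way_anova(groups)
  acc_row <- fit[fit$source == "between", ]
  tibble::tibble(
    trait = trait_code,
    treatment = treatment_code,
    min = min(cell_means$m),
    max = max(cell_means$m),
    mean = mean(cell_means$m),
    f_statistic = acc_row$f_statistic,
    p_value = acc_row$p_value,
    degenerate = attr(fit, "degenerate")
  )
}

#' Descriptive summaries for every trait-by-treatment combination
#'
#' Convenience wrapper applying [summarize_trait()] across all traits and
#' treatments present in the table.
#'
#' @param data A study table.
#' @return A tibble with one row per (trait, treatment).
#' @export
summarize_study <- function(data) {
  data <- as_study_table(data)
  combos <- dplyr::distinct(data, trait, treatment)
  purrr::pmap_dfr(combos, function(trait, treatment) {
    summarize_trait(data, trait, treatment)
  })
}
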