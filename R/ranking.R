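#' Ranking configuration
#'
#' Controls which traits enter the two selection indices and how the final
#' ordering is drawn.
#'
#' * `ranked_traits` — traits whose per-accession ranks are averaged into the
#'   average rank (AR). Default: all twelve traits except lipid peroxidation
#'   (`LP`), i.e. eleven components, the set under which published AR values
#'   in this assay family come out as multiples of 1/11.
#' * `sti_traits` — traits aggregated into the stress tolerance index.
#'   Default: germination percentage plus seedling growth (`"SG"`, a derived
#'   trait computed as root length + shoot length per replicate before
#'   averaging).
#' * `orientation` — named character vector of per-trait overrides
#'   (`"higher_is_better"` / `"lower_is_better"`); unset traits keep the
#'   defaults from [trait_descriptors()].
#' * `final_order_policy` — per scope, `"sti_desc"` (descending STI, ties by
#'   ascending AR then accession id) or `"ar_asc"` (ascending AR, ties by
#'   descending STI then accession id). Defaults: `sti_desc` for the
#'   single-stress scopes T1 and T2, `ar_asc` for the combined scope.
#'
#' @param ranked_traits Character vector of trait codes for AR.
#' @param sti_traits Character vector of trait codes for STI (may include
#'   `"SG"`).
#' @param orientation Named character vector of orientation overrides.
#' @param final_order_policy Named character vector with entries for `T1`,
#'   `T2` and `combined`.
#' @return A `peg_ranking_config` list.
#' @export
ranking_config <- function(ranked_traits = setdiff(trait_names(), "LP"),
                           sti_traits = c("GP", "SG"),
                           orientation = character(),
                           final_order_policy = c(T1 = "sti_desc",
                                                  T2 = "sti_desc",
                                                  combined = "ar_asc")) {
  if (length(ranked_traits) == 0) {
    abort("`ranked_traits` must be non-empty.", class = "pegscreen_invalid_input")
  }
  if (length(sti_traits) == 0) {
    abort("`sti_traits` must be non-empty.", class = "pegscreen_invalid_input")
  }
  allowed <- c(trait_names(), "SG")
  bad <- setdiff(c(ranked_traits, sti_traits, names(orientation)), allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown trait(s) in ranking config: ",
                 paste(bad, collapse = ", "), "."),
          class = "pegscreen_invalid_input")
  }
  if (!all(orientation %in% c("higher_is_better", "lower_is_better"))) {
    abort("Orientation overrides must be 'higher_is_better' or 'lower_is_better'.",
          class = "pegscreen_invalid_input")
  }
  policy <- final_order_policy
  for (sc in c("T1", "T2", "combined")) {
    if (is.na(policy[sc] %||% NA)) {
      abort(paste0("`final_order_policy` must name scope ", sc, "."),
            class = "pegscreen_invalid_input")
    }
  }
  if (!all(policy %in% c("sti_desc", "ar_asc"))) {
    abort("Order policies must be 'sti_desc' or 'ar_asc'.",
          class = "pegscreen_invalid_input")
  }
  structure(
    list(ranked_traits = ranked_traits, sti_traits = sti_traits,
         orientation = orientation, final_order_policy = policy),
    class = "peg_ranking_config"
  )
}

# effective orientation for a trait under a config ("SG" behaves like growth)
trait_orientation <- function(trait, config) {
  if (trait %in% names(config$orientation)) {
    return(config$orientation[[trait]])
  }
  if (trait == "SG") return("higher_is_better")
  td <- trait_descriptors()
  td$orientation[td$trait == trait]
}

#' Rank accessions on one trait
#'
#' Rank 1 is the best accession according to the trait's orientation; ties
#' receive the average of the ranks they span (mid-ranks).
#'
#' @param values Named numeric vector (accession -> trait value).
#' @param orientation `"higher_is_better"` or `"lower_is_better"`.
#' @return Named numeric vector of ranks.
#' @examples
#' rank_by_trait(c(A = 10, B = 5, C = 1), "higher_is_better")
#' @export
rank_by_trait <- function(values, orientation = "higher_is_better") {
  if (length(values) < 2) {
    abort("Need at least two accessions to rank.",
          class = "pegscreen_invalid_input")
  }
  if (!all(is.finite(values))) {
    abort("Trait values must be finite.", class = "pegscreen_invalid_input")
  }
  if (orientation == "higher_is_better") {
    rank(-values, ties.method = "average")
  } else if (orientation == "lower_is_better") {
    rank(values, ties.method = "average")
  } else {
    abort("Unknown orientation.", class = "pegscreen_invalid_input")
  }
}

#' Average rank over a trait set
#'
#' @param ranks Non-empty numeric vector of per-trait ranks for one accession.
#' @return Arithmetic mean of the ranks.
#' @export
average_rank <- function(ranks) {
  if (length(ranks) == 0) {
    abort("Cannot average an empty rank list.", class = "pegscreen_invalid_input")
  }
  mean(ranks)
}

# accession x treatment means for the STI traits, deriving SG = RL + SL
# per replicate before averaging
sti_trait_means <- function(data, sti_traits) {
  plain <- setdiff(sti_traits, "SG")
  out <- accession_means(dplyr::filter(data, .data$trait %in% plain))
  if ("SG" %in% sti_traits) {
    rl_sl <- dplyr::filter(data, .data$trait %in% c("RL", "SL"))
    wide <- tidyr::pivot_wider(rl_sl, names_from = trait, values_from = value)
    if (!all(c("RL", "SL") %in% names(wide)) || anyNA(wide$RL) || anyNA(wide$SL)) {
      abort("Seedling growth (SG) needs matching RL and SL replicates.",
            class = "pegscreen_validation_error")
    }
    sg <- wide |>
      dplyr::mutate(trait = "SG", value = .data$RL + .data$SL) |>
      dplyr::group_by(accession, treatment, trait) |>
      dplyr::summarise(mean_value = mean(value), n_reps = dplyr::n(),
                       .groups = "drop")
    out <- dplyr::bind_rows(out, sg)
  }
  out
}

# aggregate STI for one stress treatment over the configured trait set
aggregate_sti_for_scope <- function(sti_means, sti_traits, stress_treatment) {
  per_acc <- lapply(sti_traits, function(tr) {
    sub <- dplyr::filter(sti_means, .data$trait == tr)
    ctrl <- dplyr::filter(sub, .data$treatment == "T0")
    strs <- dplyr::filter(sub, .data$treatment == stress_treatment)
    if (nrow(ctrl) == 0) {
      abort(paste0("STI stage: no control (T0) data for trait ", tr, "."),
            class = "pegscreen_validation_error")
    }
    merged <- dplyr::inner_join(
      dplyr::select(ctrl, accession, y_control = mean_value),
      dplyr::select(strs, accession, y_stress = mean_value),
      by = "accession"
    )
    grand <- mean(ctrl$mean_value)
    merged$sti <- compute_sti(merged$y_control, merged$y_stress, grand)
    dplyr::select(merged, accession, sti)
  })
  dplyr::bind_rows(per_acc) |>
    dplyr::group_by(accession) |>
    dplyr::summarise(sti = aggregate_sti(sti), .groups = "drop")
}

#' Build a rank table for one scope
#'
#' Combines the two selection indices for every accession under a scope:
#'
#' * scope `"T1"` or `"T2"` — per-trait values are the accession means under
#'   that stress treatment; the aggregate STI uses that treatment against the
#'   T0 control.
#' * scope `"combined"` — per-trait values are the mean of the accession's T1
#'   and T2 means (ranked after averaging), and the aggregate STI is
#'   [combined_sti()] of the two single-scope STIs.
#'
#' Per-trait ranks (mid-ranks for ties, respecting orientation) are averaged
#' into AR over `config$ranked_traits`; the final rank is assigned by the
#' scope's `final_order_policy`.
#'
#' @param data A study table; must contain T0 and the scope's stress
#'   treatment(s) for every accession and configured trait.
#' @param config A [ranking_config()].
#' @param scope `"T1"`, `"T2"` or `"combined"`.
#' @return A `peg_rank_table` tibble: `accession`, one `rank_<trait>` column
#'   per ranked trait, `ar`, `sti`, `final_rank`, `scope`.
#' @export
build_rank_table <- function(data, config = ranking_config(), scope = "combined") {
  data <- as_study_table(data)
  if (!scope %in% c("T1", "T2", "combined")) {
    abort("`scope` must be 'T1', 'T2' or 'combined'.",
          class = "pegscreen_invalid_input")
  }
  if (!"T0" %in% data$treatment) {
    abort("STI stage: study table has no T0 control observations.",
          class = "pegscreen_validation_error")
  }
  accessions <- sort(unique(data$accession))
  means <- accession_means(dplyr::filter(data, .data$trait %in% config$ranked_traits))

  stress_levels <- if (scope == "combined") c("T1", "T2") else scope
  scope_vals <- means |>
    dplyr::filter(.data$treatment %in% stress_levels) |>
    dplyr::group_by(accession, trait) |>
    dplyr::summarise(value = mean(mean_value), n_treat = dplyr::n(),
                     .groups = "drop")
  if (any(scope_vals$n_treat != length(stress_levels))) {
    bad <- scope_vals$accession[scope_vals$n_treat != length(stress_levels)][1]
    abort(paste0("Accession ", bad, " lacks data under some of: ",
                 paste(stress_levels, collapse = ", "), "."),
          class = "pegscreen_validation_error")
  }
  # every accession must carry every ranked trait
  counts <- dplyr::count(scope_vals, accession)
  incomplete <- counts$accession[counts$n != length(config$ranked_traits)]
  if (length(incomplete) > 0) {
    abort(paste0("Accession ", incomplete[1],
                 " is missing one or more ranked traits."),
          class = "pegscreen_validation_error")
  }

  rank_cols <- lapply(config$ranked_traits, function(tr) {
    sub <- dplyr::filter(scope_vals, .data$trait == tr)
    v <- setNames(sub$value, sub$accession)[accessions]
    rank_by_trait(v, trait_orientation(tr, config))
  })
  rank_mat <- do.call(cbind, rank_cols)
  colnames(rank_mat) <- paste0("rank_", config$ranked_traits)
  ar <- rowMeans(rank_mat)

  sm <- sti_trait_means(data, config$sti_traits)
  if (scope == "combined") {
    s1 <- aggregate_sti_for_scope(sm, config$sti_traits, "T1")
    s2 <- aggregate_sti_for_scope(sm, config$sti_traits, "T2")
    sti_tbl <- dplyr::inner_join(s1, s2, by = "accession",
                                 suffix = c("_t1", "_t2")) |>
      dplyr::mutate(sti = combined_sti(.data$sti_t1, .data$sti_t2)) |>
      dplyr::select(accession, sti)
  } else {
    sti_tbl <- aggregate_sti_for_scope(sm, config$sti_traits, scope)
  }
  sti <- setNames(sti_tbl$sti, sti_tbl$accession)[accessions]
  if (anyNA(sti)) {
    abort(paste0("STI stage: accession ", accessions[which(is.na(sti))[1]],
                 " lacks control or stress data for the STI traits."),
          class = "pegscreen_validation_error")
  }

  policy <- config$final_order_policy[[scope]]
  ord <- if (policy == "sti_desc") {
    order(-sti, ar, accessions)
  } else {
    order(ar, -sti, accessions)
  }
  final_rank <- integer(length(accessions))
  final_rank[ord] <- seq_along(accessions)

  out <- dplyr::bind_cols(
    tibble::tibble(accession = accessions),
    tibble::as_tibble(rank_mat),
    tibble::tibble(ar = unname(ar), sti = unname(sti), final_rank = final_rank,
                   scope = scope)
  ) |>
    dplyr::arrange(final_rank)
  attr(out, "config") <- config
  class(out) <- c("peg_rank_table", class(out))
  out
}

#' Assign tolerance classes from a rank table
#'
#' Slices the final-rank ordering into `n_groups` contiguous, near-equal
#' groups (any remainder goes to the best groups first). With the default
#' three groups the slices are labelled `high`, `moderate` and `low`
#' tolerance, best first.
#'
#' @param rank_table A [build_rank_table()] result.
#' @param n_groups Number of classes (>= 2, <= number of accessions).
#' @return A `peg_classes` tibble: `accession`, `final_rank`, `class` (factor,
#'   best class first); attribute `boundaries` records the slice sizes.
#' @export
classify <- function(rank_table, n_groups = 3) {
  n <- nrow(rank_table)
  if (n_groups < 2 || n_groups > n) {
    abort("`n_groups` must be between 2 and the number of accessions.",
          class = "pegscreen_invalid_input")
  }
  base <- n %/% n_groups
  sizes <- rep(base, n_groups)
  extra <- n - base * n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- if (n_groups == 3) {
    c("high", "moderate", "low")
  } else {
    paste0("class", seq_len(n_groups))
  }
  out <- rank_table |>
    dplyr::arrange(final_rank) |>
    dplyr::transmute(
      accession,
      final_rank,
      class = factor(rep(labels, times = sizes), levels = labels)
    )
  attr(out, "boundaries") <- setNames(sizes, labels)
  class(out) <- c("peg_classes", class(out))
  out
}

#' @export
tidy.peg_rank_table <- function(x, ...) {
  tibble::as_tibble(x)[c("accession", "sti", "ar", "final_rank", "scope")]
}

#' @export
glance.peg_rank_table <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    scope = x$scope[1],
    n_accessions = nrow(x),
    n_ranked_traits = length(cfg$ranked_traits),
    order_policy = cfg$final_order_policy[[x$scope[1]]]
  )
}
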