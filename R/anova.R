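new_anova_table <- function(rows, degenerate = FALSE) {
  out <- tibble::as_tibble(rows)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("peg_anova", class(out))
  out
}

# near-zero test for sums of squares, scaled to the problem
.ss_is_zero <- function(ss, ss_total) ss <= 1e-12 * max(ss_total, 1)

#' One-way analysis of variance (completely randomised design)
#'
#' Decomposes total variation into between-group and within-group sums of
#' squares and tests the group effect with `F = MS_between / MS_within`
#' against the F distribution. This is the workhorse behind the descriptive
#' summaries (accession effect per trait and treatment) and the
#' tolerance-class comparisons.
#'
#' When every group has zero internal variance the error mean square is zero:
#' the fit is flagged `degenerate`, with `F = Inf`, `p = 0` if the group means
#' differ, and `F = NaN` if all values are identical.
#'
#' @param data Either a list of numeric vectors (one per group) or a data
#'   frame containing `value` and `group` columns.
#' @param value,group Column names (tidy-eval) when `data` is a data frame.
#' @return A `peg_anova` tibble with rows `between`, `within`, `total` and
#'   columns `source`, `df`, `sum_sq`, `mean_sq`, `f_statistic`, `p_value`;
#'   attribute `degenerate` flags a zero error mean square.
#' @examples
#' one_way_anova(list(g1 = c(1, 2), g2 = c(3, 4)))
#' @export
one_way_anova <- function(data, value = value, group = group) {
  if (is.data.frame(data)) {
    v <- dplyr::pull(data, {{ value }})
    g <- dplyr::pull(data, {{ group }})
    groups <- split(as.numeric(v), g)
  } else if (is.list(data)) {
    groups <- lapply(data, as.numeric)
  } else {
    abort("`data` must be a data frame or a list of numeric vectors.")
  }
  if (length(groups) < 2) {
    abort("One-way ANOVA needs at least two groups.",
          class = "pegscreen_validation_error")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    abort("Every group needs at least two values.",
          class = "pegscreen_validation_error")
  }
  y <- unlist(groups, use.names = FALSE)
  if (!all(is.finite(y))) {
    abort("Group values must be finite.", class = "pegscreen_validation_error")
  }
  n <- length(y)
  k <- length(groups)
  grand <- mean(y)
  group_means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(sizes * (group_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_within <- sum(vapply(seq_along(groups),
                          function(i) sum((groups[[i]] - group_means[i])^2),
                          numeric(1)))
  df_b <- k - 1
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w

  degenerate <- .ss_is_zero(ss_within, ss_total)
  if (degenerate) {
    f <- if (.ss_is_zero(ss_between, max(ss_total, 1))) NaN else Inf
    p <- if (is.nan(f)) NaN else 0
  } else {
    f <- ms_b / ms_w
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }

  new_anova_table(
    tibble::tibble(
      source = c("between", "within", "total"),
      df = c(df_b, df_w, n - 1),
      sum_sq = c(ss_between, ss_within, ss_total),
      mean_sq = c(ms_b, ms_w, NA_real_),
      f_statistic = c(f, NA_real_, NA_real_),
      p_value = c(p, NA_real_, NA_real_)
    ),
    degenerate = degenerate
  )
}

#' Balanced two-way factorial ANOVA (accession x PEG concentration)
#'
#' Fixed-effects decomposition of one trait's replicate values into accession,
#' PEG-treatment, interaction and error sums of squares, each effect tested
#' against the error mean square. The genotype-by-treatment interaction row is
#' the signal tolerance screening exploits: it measures differential accession
#' response across stress levels.
#'
#' The standard balanced-design formulas require an identical replicate count
#' (>= 2) in every (accession, treatment) cell; an unbalanced table is
#' rejected with instructions to subset or rebalance rather than silently
#' switching to a different sum-of-squares type.
#'
#' @param data A study table.
#' @param trait Trait code to analyse.
#' @return A `peg_anova` tibble with rows `accession`, `peg`, `interaction`,
#'   `error`, `total`.
#' @export
two_way_anova <- function(data, trait) {
  data <- as_study_table(data)
  trait_code <- trait
  sub <- dplyr::filter(data, .data$trait == trait_code)
  if (nrow(sub) == 0) {
    abort(paste0("No observations for trait ", trait_code, "."),
          class = "pegscreen_validation_error")
  }
  counts <- sub |>
    dplyr::count(accession, treatment)
  a <- length(unique(sub$accession))
  b <- length(unique(sub$treatment))
  if (a < 2 || b < 2) {
    abort("Two-way ANOVA needs at least two accessions and two treatments.",
          class = "pegscreen_validation_error")
  }
  if (nrow(counts) != a * b || length(unique(counts$n)) != 1) {
    abort(
      paste0("Unbalanced design for trait ", trait_code,
             ": every (accession, treatment) cell must have the same ",
             "replicate count. Subset or rebalance the table first."),
      class = "pegscreen_validation_error"
    )
  }
  r <- counts$n[1]
  if (r < 2) {
    abort("Two-way ANOVA needs at least two replicates per cell.",
          class = "pegscreen_validation_error")
  }

  grand <- mean(sub$value)
  acc_means <- tapply(sub$value, sub$accession, mean)
  trt_means <- tapply(sub$value, sub$treatment, mean)
  cell_means <- tapply(sub$value, list(sub$accession, sub$treatment), mean)

  ss_a <- r * b * sum((acc_means - grand)^2)
  ss_b <- r * a * sum((trt_means - grand)^2)
  ss_cells <- r * sum((cell_means - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_total <- sum((sub$value - grand)^2)
  ss_e <- ss_total - ss_cells

  df_a <- a - 1
  df_b <- b - 1
  df_ab <- df_a * df_b
  df_e <- a * b * (r - 1)

  ms <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, ss_e / df_e)
  degenerate <- .ss_is_zero(ss_e, ss_total)
  if (degenerate) {
    effect_ss <- c(ss_a, ss_b, ss_ab)
    f <- ifelse(.ss_is_zero(effect_ss, max(ss_total, 1)), NaN, Inf)
    p <- ifelse(is.nan(f), NaN, 0)
  } else {
    f <- ms[1:3] / ms[4]
    p <- pf(f, c(df_a, df_b, df_ab), df_e, lower.tail = FALSE)
  }

  new_anova_table(
    tibble::tibble(
      source = c("accession", "peg", "interaction", "error", "total"),
      df = c(df_a, df_b, df_ab, df_e, a * b * r - 1),
      sum_sq = c(ss_a, ss_b, ss_ab, ss_e, ss_total),
      mean_sq = c(ms, NA_real_),
      f_statistic = c(f, NA_real_, NA_real_),
      p_value = c(p, NA_real_, NA_real_)
    ),
    degenerate = degenerate
  )
}

#' Two-way ANOVA for every trait
#'
#' @param data A study table.
#' @param traits Traits to analyse; defaults to all traits present.
#' @return A tibble stacking each trait's [two_way_anova()] rows with a
#'   leading `trait` column.
#' @export
anova_by_trait <- function(data, traits = NULL) {
  data <- as_study_table(data)
  traits <- traits %||% intersect(trait_names(), unique(data$trait))
  purrr::map_dfr(traits, function(tr) {
    tab <- two_way_anova(data, tr)
    dplyr::bind_cols(tibble::tibble(trait = tr), tibble::as_tibble(tab))
  })
}

#' Significance stars for p-values
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, `ns`
#' otherwise, mirroring screening-study report conventions.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' @export
tidy.peg_anova <- function(x, ...) {
  tibble::tibble(
    term = x$source,
    df = x$df,
    sumsq = x$sum_sq,
    meansq = x$mean_sq,
    statistic = x$f_statistic,
    p.value = x$p_value
  )
}

#' @export
glance.peg_anova <- function(x, ...) {
  err <- x[x$source %in% c("within", "error"), ]
  tibble::tibble(
    df_error = err$df,
    mse = err$mean_sq,
    n = x$df[x$source == "total"] + 1L,
    degenerate = attr(x, "degenerate")
  )
}
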