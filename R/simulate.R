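#' Generator configuration
#'
#' Describes a synthetic PEG-screening experiment: `n_accessions` genotypes,
#' three treatments (control plus two stress doses), `n_reps` replicate
#' dishes of `seeds_per_dish` seeds, and twelve traits with genotype main
#' effects, dose responses and a genotype-by-treatment interaction driven by
#' a single latent tolerance score per accession.
#'
#' The expected cell mean for accession *i*, trait *t* at normalised dose *s*
#' is
#' \deqn{\mu_t \, g_i \, [1 - d_t s (1 - e_t \, tol_i)]}
#' for declining traits and
#' \deqn{\mu_t \, g_i \, [1 + u_t s (1 + e_t \, tol_i)]}
#' for accumulating traits, where `g_i` is a mild lognormal genotype effect
#' (mean 1), `tol_i` the accession's tolerance score in `[0, 1]`, and
#' `e_t = tolerance_effect * tolerance_signal[t]`. Lipid peroxidation, a
#' damage marker, is amplified by *sensitivity*: its interaction term uses
#' `(1 + e_t (1 - tol_i))`. Dry weight accumulates under stress (a known
#' feature of this assay), exercising the orientation machinery downstream.
#'
#' The per-trait slopes `d_t`/`u_t` are not set directly: the configuration
#' stores each trait's control baseline `mu_t` and its full-dose grand-mean
#' ratio `stress_ratio`, and the slopes are solved so that the *expected
#' grand mean* at dose 1 equals `mu_t * stress_ratio` after averaging over
#' genotypes and tolerance scores. Calibration therefore survives any change
#' to `tolerance_effect` or `tolerance_signal`.
#'
#' Replicate noise is a normal deviation with coefficient of variation
#' `noise_cv`, truncated at zero; germination is generated as a true binomial
#' count out of `seeds_per_dish` with the success probability tied to the
#' same mean structure (clamped to `[0, 1]`), so GP always lands in
#' `[0, 100]`.
#'
#' @param n_accessions Number of accessions (default 64).
#' @param n_reps Replicate dishes per cell (default 5).
#' @param seeds_per_dish Seeds per dish for the germination count (default 25).
#' @param trait_params Tibble `trait`, `baseline`, `stress_ratio`,
#'   `direction` (`"declining"`/`"accumulating"`), `tolerance_link`
#'   (`"tolerance"`/`"sensitivity"`). Defaults to [default_trait_params()].
#' @param traits Subset of traits to generate (default: all in
#'   `trait_params`).
#' @param tolerance_effect Interaction strength `e` (default 1: the most
#'   tolerant accession suffers no decline in a fully linked trait).
#' @param tolerance_signal Named per-trait multiplier on `tolerance_effect`
#'   (default 1 for every trait); set entries to 0 to silence the tolerance
#'   link of individual traits.
#' @param genotype_sdlog Standard deviation (log scale) of the lognormal
#'   genotype effect (default 0.01: genotype main effects are kept mild so
#'   that the planted tolerance score, not general vigour, drives the
#'   stress-treatment ordering).
#' @param noise_cv Replicate coefficient of variation, scalar or named per
#'   trait (default 0.03, a tightly controlled in-vitro assay; germination
#'   additionally carries irreducible binomial counting noise).
#' @param tolerance_scores `NULL` for evenly spaced scores over `[0, 1]` in
#'   accession order, or a numeric vector of length `n_accessions`.
#' @param seed RNG seed used by [generate_study()]; `NULL` uses the current
#'   RNG state.
#' @return A `peg_generator_config` list.
#' @export
generator_config <- function(n_accessions = 64,
                             n_reps = 5,
                             seeds_per_dish = 25,
                             trait_params = default_trait_params(),
                             traits = NULL,
                             tolerance_effect = 1,
                             tolerance_signal = NULL,
                             genotype_sdlog = 0.01,
                             noise_cv = 0.03,
                             tolerance_scores = NULL,
                             seed = NULL) {
  if (n_accessions < 2 || n_reps < 1 || seeds_per_dish < 1) {
    abort("Need n_accessions >= 2, n_reps >= 1, seeds_per_dish >= 1.",
          class = "pegscreen_invalid_input")
  }
  traits <- traits %||% trait_params$trait
  bad <- setdiff(traits, trait_params$trait)
  if (length(bad) > 0) {
    abort(paste0("No generator parameters for trait(s): ",
                 paste(bad, collapse = ", "), "."),
          class = "pegscreen_invalid_input")
  }
  if (any(trait_params$baseline <= 0) || any(trait_params$stress_ratio <= 0)) {
    abort("Baselines and stress ratios must be positive.",
          class = "pegscreen_invalid_input")
  }
  sig <- setNames(rep(1, length(trait_params$trait)), trait_params$trait)
  if (!is.null(tolerance_signal)) {
    unknown <- setdiff(names(tolerance_signal), names(sig))
    if (length(unknown) > 0) {
      abort(paste0("tolerance_signal names unknown trait(s): ",
                   paste(unknown, collapse = ", "), "."),
            class = "pegscreen_invalid_input")
    }
    sig[names(tolerance_signal)] <- tolerance_signal
  }
  if (any(sig < 0) || tolerance_effect < 0) {
    abort("Tolerance effect and signals must be non-negative.",
          class = "pegscreen_invalid_input")
  }
  if (is.null(tolerance_scores)) {
    tolerance_scores <- seq(0, 1, length.out = n_accessions)
  }
  if (length(tolerance_scores) != n_accessions ||
      any(tolerance_scores < 0) || any(tolerance_scores > 1)) {
    abort("`tolerance_scores` must be length n_accessions, in [0, 1].",
          class = "pegscreen_invalid_input")
  }
  cv <- noise_cv
  if (length(cv) == 1 && is.null(names(cv))) {
    cv <- setNames(rep(cv, length(trait_params$trait)), trait_params$trait)
  }
  if (any(cv < 0)) {
    abort("`noise_cv` must be non-negative.", class = "pegscreen_invalid_input")
  }
  cfg <- structure(
    list(n_accessions = n_accessions, n_reps = n_reps,
         seeds_per_dish = seeds_per_dish,
         trait_params = tibble::as_tibble(trait_params),
         traits = traits,
         tolerance_effect = tolerance_effect,
         tolerance_signal = sig,
         genotype_sdlog = genotype_sdlog,
         noise_cv = cv,
         tolerance_scores = tolerance_scores,
         seed = seed),
    class = "peg_generator_config"
  )
  # fail fast if any expected mean would go negative
  invisible(dose_slopes(cfg))
  cfg
}

#' Default per-trait generator parameters
#'
#' Control baselines and full-dose (15% PEG) grand-mean ratios matching the
#' descriptive statistics of a 64-accession tomato PEG-6000 screen:
#' morphological traits decline under stress (except dry weight, which
#' accumulates) and all biochemical pools rise.
#'
#' @return A tibble `trait`, `baseline`, `stress_ratio`, `direction`,
#'   `tolerance_link`.
#' @export
default_trait_params <- function() {
  tibble::tribble(
    ~trait, ~baseline, ~t2_mean, ~direction,     ~tolerance_link,
    "GP",    90.10,  80.04,  "declining",    "tolerance",
    "RL",     8.21,   4.65,  "declining",    "tolerance",
    "SL",     7.08,   3.63,  "declining",    "tolerance",
    "FW",    47.35,  30.25,  "declining",    "tolerance",
    "DW",     1.95,   3.08,  "accumulating", "tolerance",
    "PC",   854.45, 2295.87, "accumulating", "tolerance",
    "SSC",  129.97, 220.88,  "accumulating", "tolerance",
    "TPC",   78.33, 389.86,  "accumulating", "tolerance",
    "AC",   557.82, 732.29,  "accumulating", "tolerance",
    "GPA",    0.20,   0.40,  "accumulating", "tolerance",
    "CAT",   88.88, 178.77,  "accumulating", "tolerance",
    "LP",     4.55,   6.39,  "accumulating", "sensitivity"
  ) |>
    dplyr::mutate(stress_ratio = .data$t2_mean / .data$baseline) |>
    dplyr::select(trait, baseline, stress_ratio, direction, tolerance_link)
}

#' The calibrated reference screen configuration
#'
#' The study conditions the package's simulations emulate: 64 accessions,
#' 5 replicates of 25 seeds, all twelve traits at their default baselines and
#' stress ratios, a strong tolerance effect, mild genotype spread, low
#' replicate noise, evenly spaced tolerance scores and a fixed seed. Two
#' calls return identical configurations.
#'
#' @param seed RNG seed (default 20241118).
#' @return A `peg_generator_config`.
#' @export
default_paper_like_config <- function(seed = 20241118) {
  generator_config(seed = seed)
}

# Solve the per-trait dose slope so the expected grand mean at dose 1 equals
# baseline * stress_ratio, averaging over tolerance scores (E[g] = 1).
# Returns tibble trait, slope, direction, tolerance_link, e_t.
dose_slopes <- function(config) {
  tp <- config$trait_params[config$trait_params$trait %in% config$traits, ]
  tolbar <- mean(config$tolerance_scores)
  tol_min <- min(config$tolerance_scores)
  out <- tp
  out$e_t <- config$tolerance_effect * config$tolerance_signal[tp$trait]
  out$slope <- NA_real_
  for (i in seq_len(nrow(out))) {
    r <- out$stress_ratio[i]
    e <- out$e_t[i]
    if (out$direction[i] == "declining") {
      denom <- 1 - e * tolbar
      if (denom <= 0) {
        abort(paste0("Tolerance effect too strong for declining trait ",
                     out$trait[i], " (expected decline vanishes)."),
              class = "pegscreen_invalid_input")
      }
      d <- (1 - r) / denom
      worst <- 1 - d * (1 - e * tol_min)
      if (worst <= 0) {
        abort(paste0("Parameters give a non-positive expected mean for ",
                     out$trait[i], " in the least tolerant accession."),
              class = "pegscreen_invalid_input")
      }
      out$slope[i] <- d
    } else {
      link_bar <- if (out$tolerance_link[i] == "tolerance") tolbar else 1 - tolbar
      out$slope[i] <- (r - 1) / (1 + e * link_bar)
    }
  }
  out
}

#' Expected grand means under a generator configuration
#'
#' Closed-form expectation of the grand mean (over accessions and
#' replicates) of each generated trait under each treatment — the quantity
#' the generator is calibrated to. Used by the Monte-Carlo checks.
#'
#' @param config A [generator_config()].
#' @return A tibble `trait`, `treatment`, `expected`.
#' @export
generator_grand_means <- function(config) {
  sl <- dose_slopes(config)
  tolbar <- mean(config$tolerance_scores)
  tr <- treatments()
  grid <- tidyr::expand_grid(trait = sl$trait, treatment = tr$treatment)
  grid <- grid |>
    dplyr::left_join(tr, by = "treatment") |>
    dplyr::left_join(sl, by = "trait")
  link_bar <- ifelse(grid$tolerance_link == "tolerance", tolbar, 1 - tolbar)
  factor <- ifelse(
    grid$direction == "declining",
    1 - grid$slope * grid$dose * (1 - grid$e_t * tolbar),
    1 + grid$slope * grid$dose * (1 + grid$e_t * link_bar)
  )
  tibble::tibble(trait = grid$trait, treatment = grid$treatment,
                 expected = grid$baseline * factor)
}

#' Generate a synthetic study table with ground truth
#'
#' Draws one full experiment under a [generator_config()]: a validated study
#' table plus the planted tolerance scores and their tertile classes. The
#' same seed always reproduces the same table.
#'
#' @param config A [generator_config()].
#' @return A list with elements `study` (a `peg_study` tibble) and `truth`
#'   (tibble `accession`, `tolerance_score`, `class` with levels
#'   high/moderate/low by score tertile, best first).
#' @examples
#' sim <- generate_study(generator_config(n_accessions = 4, seed = 1))
#' dplyr::count(sim$study, treatment)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "peg_generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_accessions
  accessions <- sprintf("AC%d", seq_len(n))
  tol <- config$tolerance_scores
  sl <- dose_slopes(config)
  tr <- treatments()
  sdlog <- config$genotype_sdlog

  rows <- vector("list", nrow(sl) * nrow(tr))
  idx <- 1
  for (t_i in seq_len(nrow(sl))) {
    trait <- sl$trait[t_i]
    # one genotype effect per accession and trait, mean 1
    g <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    e <- sl$e_t[t_i]
    link <- if (sl$tolerance_link[t_i] == "tolerance") tol else 1 - tol
    for (s_i in seq_len(nrow(tr))) {
      dose <- tr$dose[s_i]
      factor <- if (sl$direction[t_i] == "declining") {
        1 - sl$slope[t_i] * dose * (1 - e * tol)
      } else {
        1 + sl$slope[t_i] * dose * (1 + e * link)
      }
      cell_mean <- sl$baseline[t_i] * g * factor
      if (trait == "GP") {
        p <- pmin(pmax(cell_mean / 100, 0), 1)
        if (config$noise_cv[["GP"]] == 0) {
          # noiseless limit: report the expected proportion exactly
          value <- rep(100 * p, each = config$n_reps)
        } else {
          counts <- rbinom(n * config$n_reps, size = config$seeds_per_dish,
                           prob = rep(p, each = config$n_reps))
          value <- 100 * counts / config$seeds_per_dish
        }
      } else {
        mu <- rep(cell_mean, each = config$n_reps)
        value <- rnorm(n * config$n_reps, mean = mu,
                       sd = config$noise_cv[[trait]] * mu)
        value <- pmax(value, 0)  # truncate at zero
      }
      rows[[idx]] <- tibble::tibble(
        accession = rep(accessions, each = config$n_reps),
        treatment = tr$treatment[s_i],
        replicate = rep(seq_len(config$n_reps), times = n),
        trait = trait,
        value = value
      )
      idx <- idx + 1
    }
  }
  study <- study_table(dplyr::bind_rows(rows))

  # tertile classes by planted score, best first (ties by accession order)
  ord <- order(-tol, seq_len(n))
  sizes <- rep(n %/% 3, 3)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  cls <- character(n)
  cls[ord] <- rep(c("high", "moderate", "low"), times = sizes)
  truth <- tibble::tibble(
    accession = accessions,
    tolerance_score = tol,
    class = factor(cls, levels = c("high", "moderate", "low"))
  )
  list(study = study, truth = truth)
}
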