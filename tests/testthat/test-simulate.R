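test_that("the reference configuration is pure and carries the calibration", {
  c1 <- default_paper_like_config()
  c2 <- default_paper_like_config()
  expect_identical(c1, c2)
  tp <- c1$trait_params
  expect_equal(tp$baseline[tp$trait == "GP"], 90.10)
  expect_equal(tp$baseline[tp$trait == "PC"], 854.45)
  expect_equal(c1$n_accessions, 64)
  expect_equal(c1$n_reps, 5)
  expect_equal(c1$seeds_per_dish, 25)
})

test_that("identical seeds reproduce identical study tables", {
  s1 <- generate_study(generator_config(n_accessions = 6, seed = 101))
  s2 <- generate_study(generator_config(n_accessions = 6, seed = 101))
  expect_identical(s1$study, s2$study)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_study(generator_config(n_accessions = 6, seed = 102))
  expect_false(identical(s1$study$value, s3$study$value))
})

test_that("silencing all variation makes every rank column an all-tie", {
  cfg <- generator_config(n_accessions = 5, n_reps = 2, tolerance_effect = 0,
                          genotype_sdlog = 0, noise_cv = 0, seed = 1)
  sim <- generate_study(cfg)
  rt <- build_rank_table(sim$study, scope = "combined")
  rank_cols <- dplyr::select(tibble::as_tibble(rt), dplyr::starts_with("rank_"))
  expect_true(all(vapply(rank_cols, function(x) all(x == 3), logical(1))))
})

test_that("control cells are untouched by the stress machinery", {
  cfg <- generator_config(n_accessions = 4, n_reps = 2, genotype_sdlog = 0,
                          noise_cv = 0, seed = 2)
  sim <- generate_study(cfg)
  ctrl <- accession_means(sim$study) |> dplyr::filter(treatment == "T0")
  tp <- cfg$trait_params
  for (tr in tp$trait) {
    expect_equal(ctrl$mean_value[ctrl$trait == tr],
                 rep(tp$baseline[tp$trait == tr], 4),
                 tolerance = 1e-9)
  }
})

test_that("noise-free grand means are monotone in dose, trait by trait", {
  cfg <- generator_config(genotype_sdlog = 0, noise_cv = 0, seed = 4)
  gm <- accession_means(generate_study(cfg)$study) |>
    dplyr::group_by(trait, treatment) |>
    dplyr::summarise(m = mean(mean_value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = treatment, values_from = m)
  declining <- c("GP", "RL", "SL", "FW")
  for (tr in declining) {
    row <- gm[gm$trait == tr, ]
    expect_true(row$T0 > row$T1 && row$T1 > row$T2, label = tr)
  }
  for (tr in setdiff(trait_names(), declining)) {
    row <- gm[gm$trait == tr, ]
    expect_true(row$T0 < row$T1 && row$T1 < row$T2, label = tr)
  }
})

test_that("empirical grand means sit within Monte-Carlo error of the calibration", {
  cfg <- generator_config(seed = 7)
  sim <- generate_study(cfg)
  expected <- generator_grand_means(cfg)
  obs <- accession_means(sim$study) |>
    dplyr::group_by(trait, treatment) |>
    dplyr::summarise(m = mean(mean_value), .groups = "drop")
  chk <- dplyr::inner_join(expected, obs, by = c("trait", "treatment"))
  # genotype sdlog 0.01 + replicate cv 0.03/sqrt(5), averaged over 64
  # accessions; GP gets a binomial-width allowance instead
  for (i in seq_len(nrow(chk))) {
    rel_se <- if (chk$trait[i] == "GP") 0.006 else
      sqrt(0.01^2 + (0.03 / sqrt(5))^2) / sqrt(64)
    expect_lt(abs(chk$m[i] - chk$expected[i]),
              4 * rel_se * chk$expected[i] + 1e-9)
  }
})

test_that("germination stays a valid percentage and uses the binomial grid", {
  sim <- generate_study(generator_config(seed = 8))
  gp <- sim$study$value[sim$study$trait == "GP"]
  expect_true(all(gp >= 0 & gp <= 100))
  expect_true(all(abs(gp * 25 / 100 - round(gp * 25 / 100)) < 1e-9))
})

test_that("the most tolerant accession wins under strong effect and low noise", {
  cfg <- generator_config(noise_cv = 0.01, genotype_sdlog = 0.002, seed = 9)
  sim <- generate_study(cfg)
  rt <- build_rank_table(sim$study, scope = "combined")
  best <- sim$truth$accession[which.max(sim$truth$tolerance_score)]
  expect_equal(rt$accession[rt$final_rank == 1], best)
})

test_that("ground-truth classes are score tertiles", {
  sim <- generate_study(generator_config(seed = 10))
  tr <- sim$truth[order(-sim$truth$tolerance_score), ]
  expect_equal(as.character(unique(tr$class)), c("high", "moderate", "low"))
  expect_equal(as.integer(table(tr$class)), c(22L, 21L, 21L))
})

test_that("impossible parameter combinations are rejected up front", {
  expect_error(generator_config(tolerance_effect = 3),
               class = "pegscreen_invalid_input")
  expect_error(generator_config(noise_cv = -0.1),
               class = "pegscreen_invalid_input")
  expect_error(generator_config(tolerance_scores = rep(2, 64)),
               class = "pegscreen_invalid_input")
  expect_error(generator_config(tolerance_signal = c(XX = 1)),
               class = "pegscreen_invalid_input")
})
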