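# three-class study on one biochemical trait with controllable class means
make_class_study <- function(class_means, n_per_class = 3, sd = 0.5,
                             trait = "PC", seed = 1) {
  set.seed(seed)
  acc <- sprintf("AC%d", seq_len(3 * n_per_class))
  cls <- rep(c("high", "moderate", "low"), each = n_per_class)
  grid <- expand.grid(accession = acc, treatment = c("T1", "T2"),
                      replicate = 1:2, stringsAsFactors = FALSE)
  grid$trait <- trait
  mu <- setNames(class_means, c("high", "moderate", "low"))
  grid$value <- mu[cls[match(grid$accession, acc)]] +
    rnorm(nrow(grid), sd = sd)
  grid$value <- pmax(grid$value, 0)
  classes <- tibble::tibble(
    accession = acc, final_rank = seq_along(acc),
    class = factor(cls, levels = c("high", "moderate", "low"))
  )
  list(study = study_table(grid), classes = classes)
}

test_that("identical class values yield equal means, one letter, no significance", {
  cs <- make_class_study(c(40, 40, 40), sd = 0)
  gs <- group_trait_stats(cs$study, cs$classes, "PC", "T1")
  expect_equal(gs$mean, rep(40, 3))
  expect_true(all(gs$letters == "a"))
  expect_false(attr(gs, "significant"))
})

test_that("overwhelming class separation yields three letters and p near zero", {
  cs <- make_class_study(c(100, 50, 10), sd = 0.2)
  gs <- group_trait_stats(cs$study, cs$classes, "PC", "T1")
  expect_setequal(gs$letters, c("a", "b", "c"))
  expect_lt(attr(gs, "p_value"), 1e-8)
  expect_true(attr(gs, "significant"))
  # high class carries 'a' (largest mean first)
  expect_equal(gs$letters[gs$class == "high"], "a")
})

test_that("group means weighted by size reconstruct the overall mean", {
  cs <- make_class_study(c(80, 50, 20), n_per_class = 4, sd = 3, seed = 2)
  gs <- group_trait_stats(cs$study, cs$classes, "PC", "T2")
  acc_means <- accession_means(cs$study) |>
    dplyr::filter(treatment == "T2") |>
    dplyr::pull(mean_value)
  expect_equal(sum(gs$mean * gs$n) / sum(gs$n), mean(acc_means))
})

test_that("a class with fewer than two members is rejected", {
  cs <- make_class_study(c(80, 50, 20))
  cl <- cs$classes
  idx <- which(cl$class == "low")[2:3]
  cl$class[idx] <- "moderate"
  expect_error(group_trait_stats(cs$study, cl, "PC", "T1"),
               class = "pegscreen_validation_error")
})

test_that("biomarker identification requires significance under every stress level", {
  report <- tibble::tibble(
    trait = c("PC", "PC", "SSC", "SSC", "AC", "AC"),
    treatment = rep(c("T1", "T2"), 3),
    p_value = c(1e-6, 1e-5,   # significant under both
                1e-6, 0.5,    # T1 only -> excluded
                0.3, 0.4)     # never
  )
  hits <- identify_biomarkers(report, alpha = 0.01)
  expect_equal(hits$trait, "PC")

  none <- identify_biomarkers(
    tibble::tibble(trait = "PC", treatment = c("T1", "T2"),
                   p_value = c(0.5, 0.6)), alpha = 0.01)
  expect_equal(nrow(none), 0)
})

test_that("the biomarker set grows monotonically with alpha", {
  report <- tibble::tibble(
    trait = rep(c("PC", "SSC", "TPC"), each = 2),
    treatment = rep(c("T1", "T2"), 3),
    p_value = c(1e-5, 1e-4, 0.004, 0.02, 0.2, 0.3)
  )
  for (pair in list(c(0.001, 0.01), c(0.01, 0.05), c(0.05, 0.5))) {
    s_small <- identify_biomarkers(report, alpha = pair[1])$trait
    s_large <- identify_biomarkers(report, alpha = pair[2])$trait
    expect_true(all(s_small %in% s_large))
  }
})

test_that("tolerance-linked traits separate the classes in a generated screen", {
  sim <- generate_study(generator_config(seed = 55))
  rt <- build_rank_table(sim$study, scope = "combined")
  rep <- biomarker_report(sim$study, classify(rt))
  expect_setequal(unique(rep$treatment), c("T1", "T2"))
  # every biochemical trait is tolerance-linked under the default generator:
  # the high class must out-accumulate the low class for proline
  pc <- dplyr::filter(rep, trait == "PC")
  for (i in seq_len(nrow(pc))) {
    g <- pc$groups[[i]]
    expect_gt(g$mean[g$class == "high"], g$mean[g$class == "low"])
  }
  expect_true(all(rep$significant[rep$trait %in% c("PC", "SSC", "TPC")]))
})
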