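test_that("per-trait ranking respects orientation and mid-rank ties", {
  expect_equal(rank_by_trait(c(A = 10, B = 5, C = 1), "higher_is_better"),
               c(A = 1, B = 2, C = 3))
  expect_equal(rank_by_trait(c(A = 10, B = 5, C = 1), "lower_is_better"),
               c(A = 3, B = 2, C = 1))
  expect_equal(rank_by_trait(c(A = 7, B = 7, C = 1), "higher_is_better"),
               c(A = 1.5, B = 1.5, C = 3))
  expect_error(rank_by_trait(c(A = 1), "higher_is_better"),
               class = "pegscreen_invalid_input")
})

test_that("average rank is the plain mean of per-trait ranks", {
  expect_equal(average_rank(c(3, 3, 3)), 3)
  # eleven components: AR values are multiples of 1/11
  r11 <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 2, 3)  # sums to 30
  expect_equal(average_rank(r11), 30 / 11)
  expect_equal(round(average_rank(r11), 2), 2.73)
  expect_error(average_rank(numeric(0)), class = "pegscreen_invalid_input")
})

# deterministic study: identical controls, accession-specific stress multipliers
make_dominance_study <- function(mult) {
  traits <- trait_names()
  base <- setNames(c(90, 8, 7, 47, 2, 850, 130, 78, 560, 0.2, 89, 4.5), traits)
  grid <- expand.grid(accession = names(mult), treatment = c("T0", "T1", "T2"),
                      replicate = 1:2, trait = traits, stringsAsFactors = FALSE)
  f <- ifelse(grid$treatment == "T0", 1, mult[grid$accession])
  # LP is lower-is-better: invert the advantage so the dominant accession
  # also dominates on damage
  f[grid$trait == "LP"] <- ifelse(grid$treatment[grid$trait == "LP"] == "T0",
                                  1, 2 - mult[grid$accession[grid$trait == "LP"]])
  grid$value <- base[grid$trait] * f * ifelse(grid$replicate == 1, 0.99, 1.01)
  study_table(grid)
}

test_that("an accession dominating every stress trait is ranked first everywhere", {
  st <- make_dominance_study(c(D = 0.95, M = 0.7, W = 0.5))
  for (sc in c("T1", "T2", "combined")) {
    rt <- build_rank_table(st, scope = sc)
    expect_equal(rt$accession[rt$final_rank == 1], "D")
    expect_equal(unname(rt$ar[rt$accession == "D"]), 1)
  }
})

test_that("identical accessions tie on both indices and break by id", {
  st <- make_dominance_study(c(A = 0.7, B = 0.7, C = 0.5))
  rt <- build_rank_table(st, scope = "combined")
  expect_equal(unname(rt$ar[rt$accession == "A"]),
               unname(rt$ar[rt$accession == "B"]))
  expect_equal(rt$sti[rt$accession == "A"], rt$sti[rt$accession == "B"])
  expect_lt(rt$final_rank[rt$accession == "A"], rt$final_rank[rt$accession == "B"])
})

test_that("missing control or missing traits fail with a named stage/accession", {
  st <- make_dominance_study(c(A = 0.8, B = 0.6))
  no_ctrl <- st[st$treatment != "T0", ]
  expect_error(build_rank_table(no_ctrl), regexp = "STI stage")
  gappy <- st[!(st$accession == "B" & st$trait == "CAT"), ]
  expect_error(build_rank_table(gappy), regexp = "B")
})

test_that("final ranks are a permutation and rank columns conserve mass", {
  set.seed(19)
  st <- random_study(n_acc = 8, n_reps = 3)
  for (sc in c("T1", "T2", "combined")) {
    rt <- build_rank_table(st, scope = sc)
    expect_setequal(rt$final_rank, 1:8)
    rank_cols <- dplyr::select(tibble::as_tibble(rt), dplyr::starts_with("rank_"))
    expect_true(all(abs(colMeans(rank_cols) - (8 + 1) / 2) < 1e-12))
    # continuous inputs are tie-free: AR * 11 must be an integer
    expect_true(all(abs(rt$ar * 11 - round(rt$ar * 11)) < 1e-9))
  }
})

test_that("combined STI equals the mean of the two scope STIs per accession", {
  set.seed(23)
  st <- random_study(n_acc = 6, n_reps = 3)
  t1 <- build_rank_table(st, scope = "T1")
  t2 <- build_rank_table(st, scope = "T2")
  cb <- build_rank_table(st, scope = "combined")
  m <- match(cb$accession, t1$accession)
  expect_equal(cb$sti, (t1$sti[m] + t2$sti[match(cb$accession, t2$accession)]) / 2)
})

test_that("combined scope ranks the T1/T2-averaged trait values", {
  set.seed(29)
  st <- random_study(n_acc = 5, n_reps = 2)
  cb <- build_rank_table(st, scope = "combined")
  am <- accession_means(st)
  avg <- am |>
    dplyr::filter(treatment %in% c("T1", "T2"), trait == "RL") |>
    dplyr::group_by(accession) |>
    dplyr::summarise(v = mean(mean_value), .groups = "drop")
  manual <- rank(-setNames(avg$v, avg$accession)[cb$accession])
  expect_equal(unname(cb$rank_RL), unname(manual))
})

test_that("improving one accession's stress performance never worsens its AR", {
  set.seed(37)
  st <- random_study(n_acc = 6, n_reps = 3)
  before <- build_rank_table(st, scope = "combined")
  target <- "AC3"
  boost <- st
  idx <- boost$accession == target & boost$treatment != "T0"
  up <- idx & boost$trait != "LP"
  dn <- idx & boost$trait == "LP"
  boost$value[up] <- boost$value[up] * 1.15
  boost$value[dn] <- boost$value[dn] * 0.85
  boost$value[boost$trait == "GP"] <- pmin(boost$value[boost$trait == "GP"], 100)
  after <- build_rank_table(study_table(as.data.frame(boost)), scope = "combined")
  expect_lte(after$ar[after$accession == target],
             before$ar[before$accession == target])
})

test_that("a single ranked trait makes AR ordering follow that trait", {
  set.seed(41)
  st <- random_study(n_acc = 5, n_reps = 2)
  cfg <- ranking_config(ranked_traits = "SL")
  rt <- build_rank_table(st, cfg, scope = "combined")
  expect_equal(unname(rt$ar), unname(rt$rank_SL))
  expect_equal(rt$final_rank, unname(rank(rt$ar)))
})

test_that("orientation overrides flip a rank column", {
  set.seed(43)
  st <- random_study(n_acc = 4, n_reps = 2)
  rt_hi <- build_rank_table(st, scope = "T1")
  rt_lo <- build_rank_table(st, ranking_config(orientation = c(RL = "lower_is_better")),
                            scope = "T1")
  n <- nrow(rt_hi)
  m <- match(rt_hi$accession, rt_lo$accession)
  expect_equal(unname(rt_lo$rank_RL[m]), n + 1 - unname(rt_hi$rank_RL))
})

test_that("classification slices the ranking into near-equal contiguous classes", {
  sim <- generate_study(generator_config(seed = 3))
  rt <- build_rank_table(sim$study, scope = "combined")
  cl <- classify(rt)
  expect_equal(as.integer(table(cl$class)), c(22L, 21L, 21L))
  expect_setequal(cl$accession, rt$accession)
  # best final ranks land in the high class
  expect_true(all(cl$final_rank[cl$class == "high"] <= 22))

  st3 <- make_dominance_study(c(A = 0.9, B = 0.7, C = 0.5))
  cl3 <- classify(build_rank_table(st3, scope = "combined"), n_groups = 3)
  expect_equal(as.character(cl3$class), c("high", "moderate", "low"))
  expect_error(classify(cl3, n_groups = 5), class = "pegscreen_invalid_input")
})

test_that("ranking config validates its inputs", {
  expect_error(ranking_config(ranked_traits = character()),
               class = "pegscreen_invalid_input")
  expect_error(ranking_config(ranked_traits = "XX"),
               class = "pegscreen_invalid_input")
  expect_error(ranking_config(orientation = c(RL = "sideways")),
               class = "pegscreen_invalid_input")
  expect_error(ranking_config(final_order_policy = c(T1 = "sti_desc")),
               class = "pegscreen_invalid_input")
})
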