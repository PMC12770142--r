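small_scenario <- function(seed = 1) {
  simulate_stability_scenario(n_train = 120, n_test = 60, n_stability = 80,
                              n_per_block = 10, seed = seed)
}

test_that("fold assignment is a label-stratified partition", {
  sc <- small_scenario()
  part <- stability_partition(sc$stability_tables)
  rep <- run_cv(sc$train, sc$test_tables["S2"], part, seed = 5,
                n_select = 5, models = c("S", "U"))
  folds <- rep$folds
  expect_length(folds, nrow(sc$train))
  expect_setequal(unique(folds), 1:5)
  y <- sc$train$label == "malignant"
  global_ratio <- mean(y)
  for (f in 1:5) {
    n_f <- sum(folds == f)
    expect_lt(abs(sum(y[folds == f]) - global_ratio * n_f), 1 + 1e-9)
  }
})

test_that("identical seeds reproduce the report exactly", {
  sc <- small_scenario(3)
  part <- stability_partition(sc$stability_tables)
  r1 <- run_cv(sc$train, sc$test_tables[c("S2", "S4")], part, seed = 7,
               n_select = 5, models = c("S", "U"))
  r2 <- run_cv(sc$train, sc$test_tables[c("S2", "S4")], part, seed = 7,
               n_select = 5, models = c("S", "U"))
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$comparisons, r2$comparisons)
})

test_that("test data cannot leak into fitting", {
  sc <- small_scenario(4)
  part <- stability_partition(sc$stability_tables)
  tabs <- sc$test_tables[c("S2", "S4")]
  r1 <- run_cv(sc$train, tabs, part, seed = 9, n_select = 5,
               models = c("S", "U"))
  # corrupt one test table with a label-revealing marker: train/valid rows
  # and the other test set must be unaffected
  tabs2 <- tabs
  tabs2$S4[[part$stable[1]]] <- as.numeric(tabs2$S4$label == "malignant") * 100
  r2 <- run_cv(sc$train, tabs2, part, seed = 9, n_select = 5,
               models = c("S", "U"))
  keep <- r1$per_fold$dataset %in% c("train", "valid", "test_S2")
  expect_identical(r1$per_fold[keep, ], r2$per_fold[keep, ])
})

test_that("stable-stratum models outperform unstable ones on perturbed settings", {
  for (seed in 1:2) {
    sc <- simulate_stability_scenario(n_train = 300, n_test = 150,
                                      n_stability = 150, n_per_block = 20,
                                      seed = seed)
    part <- stability_partition(sc$stability_tables)
    rep <- run_cv(sc$train, sc$test_tables[c("S3", "S4", "S9")], part,
                  seed = seed, models = c("S", "U"))
    m <- rep$means
    auc_s <- m$auc[m$model == "S" & grepl("^test_", m$dataset)]
    auc_u <- m$auc[m$model == "U" & grepl("^test_", m$dataset)]
    expect_true(all(auc_s > auc_u))
  }
})

test_that("empty strata are skipped with an explicit report entry", {
  sc <- small_scenario(6)
  part <- stability_partition(sc$stability_tables)
  part$unstable <- character(0)
  rep <- run_cv(sc$train, sc$test_tables["S2"], part, seed = 2,
                n_select = 5, models = c("S", "U"))
  expect_true(any(grepl("stratum U has no features", rep$skipped)))
  expect_false("U" %in% rep$per_fold$model)
})

test_that("pairwise comparisons are emitted on the reference setting", {
  sc <- small_scenario(8)
  part <- stability_partition(sc$stability_tables)
  rep <- run_cv(sc$train, sc$test_tables[c("S2", "S4")], part, seed = 3,
                n_select = 5, models = c("S", "U", "FULL"))
  cmp <- rep$comparisons
  expect_equal(nrow(cmp), 5 * choose(3, 2))
  expect_true(all(cmp$delong_p >= 0 & cmp$delong_p <= 1))
  expect_true(all(cmp$mcnemar_sens_p >= 0 & cmp$mcnemar_sens_p <= 1))
})

test_that("generalizability ranges are order-invariant and correct", {
  sc <- small_scenario(9)
  part <- stability_partition(sc$stability_tables)
  tabs <- sc$test_tables[c("S2", "S4", "S9")]
  rep1 <- run_cv(sc$train, tabs, part, seed = 4, n_select = 5,
                 models = c("S", "U"))
  rep2 <- run_cv(sc$train, rev(tabs), part, seed = 4, n_select = 5,
                 models = c("S", "U"))
  g1 <- generalizability_summary(rep1)
  g2 <- generalizability_summary(rep2)
  expect_equal(g1, g2)
  expect_equal(g1$auc_range, g1$auc_max - g1$auc_min)
})
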