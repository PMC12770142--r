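panel_icc <- function(tabs, feature) {
  icc_a1(sapply(tabs, function(t) t[[feature]]))$icc
}

test_that("target ICC of 1 yields identical columns and estimate 1", {
  tabs <- simulate_feature_panel(panel_spec(30, 2, target_icc = 1,
                                            settings = paste0("S", 1:3),
                                            seed = 4))
  expect_equal(panel_icc(tabs, "f0001"), 1)
})

test_that("target ICC 0.8 is recovered within sampling tolerance", {
  tabs <- simulate_feature_panel(panel_spec(200, 1, target_icc = 0.8,
                                            settings = paste0("S", 1:3),
                                            seed = 8))
  expect_lt(abs(panel_icc(tabs, "f0001") - 0.8), 0.05)
})

test_that("empty feature panels have zero feature columns", {
  tabs <- simulate_feature_panel(panel_spec(10, 0, seed = 1))
  expect_length(tabs, 10)
  expect_identical(colnames(tabs[[1]]), c("nodule_id", "setting_id", "label"))
})

test_that("target ICC outside [0,1] is rejected", {
  expect_error(panel_spec(10, 2, target_icc = 1.2), "target_icc")
})

test_that("empirical ICC converges to targets at n = 1000", {
  targets <- c(0.2, 0.5, 0.8, 0.95)
  tabs <- simulate_feature_panel(panel_spec(1000, 4, target_icc = targets,
                                            seed = 15))
  for (f in seq_along(targets)) {
    est <- panel_icc(tabs, sprintf("f%04d", f))
    expect_lt(abs(est - targets[f]), 0.02)
  }
})

test_that("rater offsets lower the absolute-agreement ICC", {
  offs <- matrix(c(0, 1.5, -1.5), nrow = 3, ncol = 1)
  with_off <- simulate_feature_panel(
    panel_spec(500, 1, target_icc = 0.9, settings = paste0("S", 1:3),
               setting_offsets = NULL, seed = 6))
  # same noise level, offsets added on top: agreement must drop
  spec2 <- panel_spec(500, 1, target_icc = 0.9, settings = paste0("S", 1:3),
                      seed = 6)
  tabs2 <- simulate_feature_panel(spec2)
  shifted <- Map(function(t, d) { t$f0001 <- t$f0001 + d; t },
                 tabs2, c(0, 1.5, -1.5))
  expect_lt(panel_icc(shifted, "f0001"), panel_icc(with_off, "f0001"))
})

test_that("offsets too large for the ICC target are rejected", {
  offs <- matrix(c(0, 5, -5), nrow = 3, ncol = 1)
  expect_error(
    simulate_feature_panel(panel_spec(50, 1, target_icc = 0.99,
                                      settings = paste0("S", 1:3),
                                      setting_offsets = offs, seed = 1)),
    "too large")
})

test_that("class effect shifts malignant means by the stated amount", {
  tabs <- simulate_feature_panel(panel_spec(2000, 1, target_icc = 0.8,
                                            class_effect = 1.5, seed = 10))
  t1 <- tabs[[1]]
  diff <- mean(t1$f0001[t1$label == "malignant"]) -
    mean(t1$f0001[t1$label == "benign"])
  se <- sqrt(4 / 1000)  # two groups of ~1000, unit-ish variance
  expect_lt(abs(diff - 1.5), 3 * se)
})

test_that("panel simulation is reproducible under a fixed seed", {
  s <- panel_spec(40, 3, target_icc = 0.7, seed = 123)
  expect_identical(simulate_feature_panel(s), simulate_feature_panel(s))
})
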