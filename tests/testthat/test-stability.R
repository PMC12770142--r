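test_that("high-agreement panels are classified fully stable in every group", {
  tabs <- simulate_feature_panel(panel_spec(500, 5, target_icc = 0.95,
                                            seed = 3))
  rec <- stability_by_group(tabs)
  for (g in unique(rec$group)) {
    expect_true(all(rec$category[rec$group == g] == "stable"), info = g)
  }
})

test_that("low-agreement panels are classified fully unstable", {
  tabs <- simulate_feature_panel(panel_spec(500, 5, target_icc = 0.2,
                                            seed = 4))
  rec <- stability_by_group(tabs)
  expect_true(all(rec$category == "unstable"))
})

test_that("identical data give identical records across repeated groups", {
  tabs <- simulate_feature_panel(panel_spec(50, 3, target_icc = 0.7, seed = 9))
  plan <- list(a = c("S2", "S3", "S4"), b = c("S2", "S3", "S4"))
  rec <- stability_by_group(tabs, plan)
  a <- rec[rec$group == "a", c("feature", "icc", "category")]
  b <- rec[rec$group == "b", c("feature", "icc", "category")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("a missing setting table is reported by name", {
  tabs <- simulate_feature_panel(panel_spec(20, 2, settings = c("S2", "S3"),
                                            seed = 1))
  expect_error(stability_by_group(tabs, list(g = c("S2", "S10"))), "S10")
})

test_that("category intersection implements exact set algebra", {
  rec <- expand.grid(feature = c("f1", "f2", "f3", "f4"),
                     group = c("g1", "g2", "g3", "g4"),
                     stringsAsFactors = FALSE)
  rec$icc <- 0.9
  rec$degenerate <- FALSE
  rec$category <- "stable"
  # f2 unstable in g4 only; f3 stable nowhere; f4 stable in g1 only
  rec$category[rec$feature == "f2" & rec$group == "g4"] <- "unstable"
  rec$category[rec$feature == "f3"] <- "intermediate"
  rec$category[rec$feature == "f4" & rec$group != "g1"] <- "intermediate"
  out <- intersect_categories(rec, "stable")
  expect_identical(out$features, "f1")
  expect_equal(unname(out$venn["g1+g2+g3+g4"]), 1)      # f1
  expect_equal(unname(out$venn["g1+g2+g3"]), 1)         # f2
  expect_equal(unname(out$venn["g1"]), 1)               # f4
  expect_equal(sum(out$venn), 3)                        # union size
})

test_that("stability partitions are disjoint and exhaustive", {
  tabs <- simulate_feature_panel(panel_spec(120, 9,
                                            target_icc = rep(c(0.95, 0.6, 0.2),
                                                             each = 3),
                                            seed = 8))
  part <- stability_partition(tabs)
  all_feats <- sort(c(part$stable, part$intermediate, part$unstable))
  expect_identical(all_feats, sort(feature_columns <- sprintf("f%04d", 1:9)))
  expect_length(intersect(part$stable, part$unstable), 0)
  expect_length(intersect(part$stable, part$intermediate), 0)
})

test_that("stability summaries report counts and fractions per category", {
  tabs <- simulate_feature_panel(panel_spec(200, 4,
                                            target_icc = c(0.97, 0.97, 0.2, 0.2),
                                            seed = 12))
  rec <- stability_by_group(tabs, list(thickness = c("S2", "S3", "S4")))
  s <- stability_summary(rec)
  expect_equal(sum(s$count), 4)
  expect_equal(sum(s$fraction), 1)
  expect_equal(s$count[s$category == "stable"], 2)
})
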