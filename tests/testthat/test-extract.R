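lv_fixture <- function(seed = 3) make_phantom_cohort(phantom_spec(1, seed = seed))[[1]]

test_that("the default configuration yields exactly 644 ordered features", {
  lv <- lv_fixture()
  fv <- extract_all(lv$volume, lv$mask)
  expect_length(fv, 644)
  prefix <- sub("_(shape|firstorder|glcm)_.*$", "", names(fv))
  counts <- table(prefix)
  expect_equal(unname(counts["original"]), 56)   # 14 shape + 18 FO + 24 GLCM
  derived <- counts[names(counts) != "original"]
  expect_length(derived, 14)
  expect_true(all(derived == 42))                # 18 FO + 24 GLCM each
})

test_that("extraction is bitwise deterministic", {
  lv <- lv_fixture(7)
  expect_identical(extract_all(lv$volume, lv$mask),
                   extract_all(lv$volume, lv$mask))
})

test_that("composed extraction equals the individual operations", {
  lv <- lv_fixture(11)
  cfg <- extract_config()
  fv <- extract_all(lv$volume, lv$mask, cfg)
  pp <- preprocess(lv$volume, lv$mask, cfg$preprocess)
  sh <- shape_features(pp$mask, pp$volume$spacing)
  fo <- first_order_features(pp$volume, pp$mask, cfg$preprocess$bin_width)
  gl <- glcm_features(pp$volume, pp$mask, cfg$preprocess$bin_width)
  expect_equal(unname(fv[paste0("original_shape_", names(sh))]), unname(sh))
  expect_equal(unname(fv[paste0("original_firstorder_", names(fo))]), unname(fo))
  expect_equal(unname(fv[paste0("original_glcm_", names(gl))]), unname(gl))
})

test_that("cohort extraction produces aligned per-setting tables", {
  cohort <- make_phantom_cohort(phantom_spec(2, seed = 19))
  settings <- acquisition_settings()
  tabs <- extract_cohort(cohort, settings[settings$setting_id %in%
                                            c("S2", "S10"), ])
  expect_named(tabs, c("S2", "S10"))
  expect_identical(colnames(tabs$S2), colnames(tabs$S10))
  expect_identical(tabs$S2$nodule_id, tabs$S10$nodule_id)
  expect_equal(ncol(tabs$S2), 3 + 644)
})

test_that("feature tables survive a CSV round trip", {
  tab <- simulate_feature_panel(panel_spec(5, 3, seed = 2))[[1]]
  path <- tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back, tab, tolerance = 1e-12)
})
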