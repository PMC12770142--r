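make_const_lv <- function(value = 50, dims = c(8, 8, 6)) {
  labeled_volume(volume_grid(array(value, dims), c(0.5, 0.5, 1)),
                 roi_mask(array(TRUE, dims)), "benign", "c1")
}

test_that("every setting preserves constant volumes (up to quantization)", {
  lv <- make_const_lv(50.2)
  for (sid in acquisition_settings()$setting_id) {
    out <- apply_setting(lv, sid)
    tol <- if (sid == "S1") 0.5 else 1e-9   # PACS rounds to integer HU
    expect_lt(max(abs(out$volume$data - 50.2)), tol + 1e-12)
  }
})

test_that("3 mm slices average an axial 0/300/0 profile to one 100 HU slab", {
  vox <- array(0, c(4, 4, 3)); vox[, , 2] <- 300
  lv <- labeled_volume(volume_grid(vox, c(0.5, 0.5, 1)),
                       roi_mask(array(TRUE, c(4, 4, 3))), "benign", "p")
  out <- apply_setting(lv, "S3")
  expect_equal(dim(out$volume$data)[3], 1L)
  expect_true(all(out$volume$data == 100))
  expect_equal(out$volume$spacing[3], 3)
})

test_that("the reference setting S2 is the identity", {
  lv <- make_phantom_cohort(phantom_spec(1, seed = 5))[[1]]
  expect_identical(apply_setting(lv, "S2"), lv)
})

test_that("slab averaging conserves the global mean for divisible extents", {
  set.seed(3)
  vox <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  lv <- labeled_volume(volume_grid(vox, c(0.5, 0.5, 1)),
                       roi_mask(array(TRUE, c(8, 8, 6))), "benign", "m")
  out <- apply_setting(lv, "S3")
  expect_equal(mean(out$volume$data), mean(vox), tolerance = 1e-12)
})

test_that("a trailing partial slab is averaged over its remaining slices", {
  vox <- array(0, c(4, 4, 5))
  vox[, , 4] <- 10; vox[, , 5] <- 20
  lv <- labeled_volume(volume_grid(vox, c(0.5, 0.5, 1)),
                       roi_mask(array(TRUE, c(4, 4, 5))), "benign", "t")
  out <- apply_setting(lv, "S3")  # slabs 1:3 and 4:5
  expect_equal(dim(out$volume$data)[3], 2L)
  expect_true(all(out$volume$data[, , 2] == 15))
})

test_that("matrix 512 halves in-plane dimensions and doubles spacing", {
  lv <- make_phantom_cohort(phantom_spec(1, seed = 9))[[1]]
  out <- apply_setting(lv, "S10")
  expect_equal(dim(out$volume$data)[1:2], dim(lv$volume$data)[1:2] / 2)
  expect_equal(out$volume$spacing[1:2], lv$volume$spacing[1:2] * 2)
  expect_identical(dim(out$mask$voxels), dim(out$volume$data))
  expect_gt(sum(out$mask$voxels), 0)
})

test_that("PACS transmission is a near-identity quantization", {
  lv <- make_phantom_cohort(phantom_spec(1, seed = 13))[[1]]
  out <- apply_setting(lv, "S1")
  expect_lte(max(abs(out$volume$data - lv$volume$data)), 0.5)
  expect_identical(out$mask$voxels, lv$mask$voxels)
})

test_that("setting transforms are deterministic", {
  lv <- make_phantom_cohort(phantom_spec(1, seed = 21))[[1]]
  expect_identical(apply_setting(lv, "S6"), apply_setting(lv, "S6"))
})

test_that("kernel ordering blurs soft kernels more than sharp ones", {
  lv <- make_phantom_cohort(phantom_spec(1, seed = 17))[[1]]
  sd_ref <- sd(lv$volume$data)
  sd_vsoft <- sd(apply_setting(lv, "S9")$volume$data)   # B_VSOFT_A
  sd_soft <- sd(apply_setting(lv, "S7")$volume$data)    # B_SOFT_C
  sd_vsharp <- sd(apply_setting(lv, "S6")$volume$data)  # B_VSHARP_D
  expect_lt(sd_vsoft, sd_soft)
  expect_lt(sd_soft, sd_ref)
  expect_gt(sd_vsharp, sd_ref)
})
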