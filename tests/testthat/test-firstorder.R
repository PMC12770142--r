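test_that("constant regions have degenerate dispersion and exact location", {
  v <- volume_grid(array(42, c(3, 3, 3)), c(1, 1, 1))
  m <- roi_mask(array(TRUE, c(3, 3, 3)))
  f <- first_order_features(v, m)
  expect_equal(unname(f[c("Mean", "Median", "Minimum", "Maximum")]),
               rep(42, 4))
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Range"]), 0)
  expect_true(is.na(f["Skewness"]) && is.na(f["Kurtosis"]))
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
})

test_that("uniformly occupied bins give entropy log2(N)", {
  # 4 bins x 10 voxels each, values centred in distinct bins
  vals <- rep(c(10, 35, 60, 85), each = 10)
  v <- volume_grid(array(vals, c(4, 10, 1)), c(1, 1, 1))
  m <- roi_mask(array(TRUE, c(4, 10, 1)))
  f <- first_order_features(v, m)
  expect_equal(unname(f["Entropy"]), log2(4))
  expect_equal(unname(f["Uniformity"]), 1 / 4)
})

test_that("all 18 statistics match the direct-formula oracle", {
  fx <- random_roi_volume(n_roi = 100, seed = 31)
  f <- first_order_features(fx$volume, fx$mask)
  o <- first_order_oracle(fx$volume$data[fx$mask$voxels], 1)
  expect_equal(f, o[names(f)], tolerance = 1e-10)
})

test_that("tiny ROIs are rejected for dispersion statistics", {
  v <- volume_grid(array(1, c(2, 2, 2)), c(1, 1, 1))
  m <- array(FALSE, c(2, 2, 2)); m[1] <- TRUE
  expect_error(first_order_features(v, roi_mask(m)), "degenerate ROI")
})

test_that("the mean is equivariant under affine intensity maps", {
  fx <- random_roi_volume(n_roi = 50, seed = 7)
  f1 <- first_order_features(fx$volume, fx$mask)
  v2 <- volume_grid(3 * fx$volume$data + 100, fx$volume$spacing)
  f2 <- first_order_features(v2, fx$mask)
  expect_equal(unname(f2["Mean"]), 3 * unname(f1["Mean"]) + 100)
  expect_equal(unname(f2["Variance"]), 9 * unname(f1["Variance"]))
})

test_that("first-order features ignore voxel storage order", {
  fx <- random_roi_volume(n_roi = 80, seed = 12)
  f1 <- first_order_features(fx$volume, fx$mask)
  rev3 <- function(a) a[dim(a)[1]:1, dim(a)[2]:1, dim(a)[3]:1]
  f2 <- first_order_features(volume_grid(rev3(fx$volume$data), c(1, 1, 1)),
                             roi_mask(rev3(fx$mask$voxels)))
  expect_equal(f1, f2)
})
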