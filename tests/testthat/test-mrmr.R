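make_selection_data <- function(n = 200, p_noise = 10, seed = 5) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  signal <- y * 3 + rnorm(n, 0, 0.3)      # effectively separates the classes
  x <- cbind(signal = signal,
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(x = scale(x), y = y)
}

test_that("a perfectly separating feature is selected first", {
  d <- make_selection_data()
  sel <- mrmr_select(d$x, d$y, m = 5)
  expect_identical(sel$features[1], "signal")
})

test_that("an exact duplicate of the first pick is not chosen second", {
  # moderate effects so relevance and redundancy are on comparable scales
  set.seed(6)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(signal = 1.2 * y + rnorm(n),
             info2 = 1.0 * y + rnorm(n),
             matrix(rnorm(n * 8), n,
                    dimnames = list(NULL, paste0("noise", 1:8))))
  x <- cbind(x, signal_dup = x[, "signal"])
  sel <- mrmr_select(scale(x), y, m = 3)
  expect_identical(sel$features[1], "signal")
  expect_false("signal_dup" %in% sel$features[2])
  expect_identical(sel$features[2], "info2")
})

test_that("requesting all candidates selects all, in relevance-aware order", {
  d <- make_selection_data(p_noise = 4)
  expect_warning(sel <- mrmr_select(d$x, d$y, m = 50), "selecting all")
  expect_setequal(sel$features, colnames(d$x))
})

test_that("selection is invariant to row order and feature scaling", {
  d <- make_selection_data(seed = 9)
  sel1 <- mrmr_select(d$x, d$y, m = 4)
  perm <- sample(nrow(d$x))
  sel2 <- mrmr_select(d$x[perm, ], d$y[perm], m = 4)
  expect_identical(sel1$features, sel2$features)
  sel3 <- mrmr_select(sweep(d$x, 2, c(2, rep(5, ncol(d$x) - 1)), "*"),
                      d$y, m = 4)
  expect_identical(sel1$features, sel3$features)
})

test_that("degenerate inputs are rejected or excluded", {
  d <- make_selection_data()
  expect_error(mrmr_select(d$x, rep(1, nrow(d$x))), "both classes")
  xc <- cbind(d$x, const = 0)
  expect_warning(sel <- mrmr_select(xc, d$y, m = 3), "constant")
  expect_false("const" %in% sel$features)
})
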