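test_that("balanced intercept-only fits give exactly zero", {
  f <- firth_fit(matrix(nrow = 10, ncol = 0), rep(c(0, 1), 5))
  expect_equal(unname(coef(f)), 0, tolerance = 1e-8)
})

test_that("the all-positive intercept equals the Jeffreys closed form", {
  # penalized proportion (n1 + 1/2) / (n + 1) = 0.9 -> logit = log(9)
  f <- firth_fit(matrix(nrow = 4, ncol = 0), rep(1, 4))
  expect_equal(unname(coef(f)), log(9), tolerance = 1e-5)
})

test_that("complete separation yields a finite slope matching the oracle", {
  x <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  f <- firth_fit(x, y)
  expect_true(all(is.finite(coef(f))))
  expect_lte(f$iterations, 100)
  oracle <- firth_oracle(x, y)
  expect_equal(unname(coef(f)), unname(oracle), tolerance = 1e-4)
})

test_that("two-parameter fits match penalized-likelihood maximization", {
  set.seed(8)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rbinom(30, 1, plogis(0.5 + x[, 1] - 0.8 * x[, 2]))
  f <- firth_fit(x, y)
  oracle <- firth_oracle(x, y)
  expect_equal(unname(coef(f)), unname(oracle), tolerance = 1e-4)
})

test_that("estimates stay finite on random small separable datasets", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))    # at least one case per class
    x <- matrix(y * 2 + rnorm(n, 0, 0.1), ncol = 1)  # near/complete separation
    f <- suppressWarnings(firth_fit(x, y))
    expect_true(all(is.finite(coef(f))))
  }
})

test_that("a vanishing penalty recovers the MLE on non-separable data", {
  set.seed(21)
  x <- matrix(rnorm(400), ncol = 2)
  y <- rbinom(200, 1, plogis(0.3 * x[, 1] - 0.2 * x[, 2]))
  f <- firth_fit(x, y, penalty_weight = 1e-8, tol = 1e-10)
  g <- glm(y ~ x, family = binomial)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-4)
})

test_that("collinear columns are dropped with a warning", {
  set.seed(4)
  x <- matrix(rnorm(40), ncol = 2)
  x <- cbind(x, dup = x[, 1])
  y <- rbinom(20, 1, 0.5); y[1] <- 0; y[2] <- 1
  expect_warning(f <- firth_fit(x, y), "collinear")
  expect_length(coef(f), 3)  # intercept + 2 independent columns
})

test_that("predictions reproduce fitted probabilities and obey the boundary", {
  set.seed(12)
  x <- matrix(rnorm(60), ncol = 2)
  y <- rbinom(30, 1, plogis(x[, 1]))
  f <- firth_fit(x, y)
  pr <- predict(f, x)
  eta <- drop(cbind(1, x) %*% coef(f))
  expect_equal(pr$probability, plogis(eta), tolerance = 1e-12)
  # all-zero coefficients: p = 0.5 everywhere, boundary counts positive
  f0 <- f; f0$coefficients[] <- 0
  pr0 <- predict(f0, x)
  expect_true(all(pr0$probability == 0.5))
  expect_true(all(pr0$predicted == 1L))
})

test_that("probabilities are monotone in positively weighted covariates", {
  f <- structure(list(coefficients = c(`(Intercept)` = 0, x1 = 2),
                      features = "x1", iterations = 1, score_norm = 0,
                      converged = TRUE, penalty_weight = 1, stratum = "FULL"),
                 class = "firth_model")
  p <- predict(f, matrix(seq(-2, 2, 0.5), ncol = 1))$probability
  expect_true(all(diff(p) > 0))
})

test_that("label and column mismatches are rejected", {
  expect_error(firth_fit(matrix(1:4, ncol = 1), c(0, 1, 2, 1)), "binary")
  f <- firth_fit(matrix(rnorm(10), ncol = 1), rep(c(0, 1), 5))
  df <- data.frame(nodule_id = "a", label = "benign", other = 1)
  expect_error(predict(f, df), "lacks model feature")
})
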