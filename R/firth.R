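#' Firth-penalized logistic regression
#'
#' Maximises the Jeffreys-penalized log-likelihood
#' \deqn{\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det(X^T W X)}
#' (W = diag(pi (1 - pi))) by iteratively reweighted least squares with
#' Firth's hat-diagonal-adjusted responses: the score contribution of case
#' i uses `y_i - pi_i + h_i (1/2 - pi_i)` where `h_i` is the i-th diagonal
#' of the weighted hat matrix. The penalty keeps all coefficients finite
#' even under complete separation. Iteration stops when the penalized score
#' norm falls below `tol` or after `max_iter` iterations (one IRLS update =
#' one epoch); step-halving guards against penalized-likelihood decreases.
#'
#' Collinear columns (detected by pivoted QR on the design matrix) are
#' dropped with a warning before fitting, keeping the earlier column of
#' each dependent set.
#'
#' @param x numeric matrix or feature table of covariates (an intercept
#'   column is added internally).
#' @param y binary outcome (0/1, logical, or `"benign"`/`"malignant"`).
#' @param max_iter maximum IRLS iterations (default 100).
#' @param tol convergence tolerance on the penalized score norm.
#' @param penalty_weight weight of the Jeffreys penalty; 1 is Firth's
#'   estimator, values near 0 approach the unpenalized MLE (diagnostic use).
#' @param stratum optional stratum label stored with the model
#'   (`"FULL"`, `"S"`, `"U"`, `"I"`, `"SI"`, `"SU"`, `"UI"`).
#' @return object of class `firth_model`: coefficients (named, incl.
#'   `(Intercept)`), the inverse-information variance-covariance matrix
#'   (`vcov`), convergence info (`iterations`, `score_norm`, `converged`),
#'   `features`, `stratum`.
#' @export
#' @examples
#' # balanced intercept-only fit: penalized estimate is exactly 0
#' f <- firth_fit(matrix(nrow = 10, ncol = 0), rep(c(0, 1), 5))
#' coef(f)
firth_fit <- function(x, y, max_iter = 100, tol = 1e-6, penalty_weight = 1,
                      stratum = "FULL") {
  if (is.data.frame(x)) x <- as.matrix(x[, feature_columns(x), drop = FALSE])
  if (is.null(x)) x <- matrix(nrow = length(y), ncol = 0)
  y <- as_binary_label(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  if (ncol(x) && is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }

  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- sort(qrX$pivot[seq_len(qrX$rank)])
    warning("dropping ", ncol(X) - qrX$rank, " collinear column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }

  beta <- numeric(ncol(X))
  pen_ll <- function(b) {
    eta <- drop(X %*% b)
    pi_ <- plogis(eta)
    w <- pmax(pi_ * (1 - pi_), 1e-12)
    ll <- sum(y * eta - log1p(exp(eta)))
    ll + 0.5 * penalty_weight *
      determinant(crossprod(X, X * w), logarithm = TRUE)$modulus
  }

  ll_old <- pen_ll(beta)
  iter <- 0L
  score_norm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    pi_ <- plogis(drop(X %*% beta))
    w <- pmax(pi_ * (1 - pi_), 1e-12)
    XtWX <- crossprod(X, X * w)
    # hat diagonals of the weighted hat matrix
    B <- X * sqrt(w)
    h <- rowSums((B %*% solve(XtWX)) * B)
    resid <- y - pi_ + penalty_weight * h * (0.5 - pi_)
    U <- drop(crossprod(X, resid))
    score_norm <- sqrt(sum(U^2))
    if (score_norm < tol) break
    delta <- solve(XtWX, U)
    # step-halving on the penalized likelihood
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_ll(cand)
      if (ll_new >= ll_old - 1e-10 || step < 1e-4) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll_old <- pen_ll(beta)
  }
  converged <- score_norm < tol
  if (!converged) {
    warning("Firth IRLS did not converge in ", max_iter,
            " iterations (score norm ", format(score_norm), ")")
  }
  names(beta) <- colnames(X)
  pi_ <- plogis(drop(X %*% beta))
  w <- pmax(pi_ * (1 - pi_), 1e-12)
  vcov <- solve(crossprod(X, X * w))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = vcov,
                 features = setdiff(colnames(X), "(Intercept)"),
                 iterations = iter, score_norm = score_norm,
                 converged = converged, penalty_weight = penalty_weight,
                 stratum = stratum),
            class = "firth_model")
}

#' @export
coef.firth_model <- function(object, ...) object$coefficients

#' @export
print.firth_model <- function(x, ...) {
  cat(sprintf("<firth_model> stratum %s, %d feature(s), %d iteration(s)%s\n",
              x$stratum, length(x$features), x$iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$coefficients)
  invisible(x)
}

#' Predict malignancy probabilities and hard labels
#'
#' Logistic probabilities from a fitted [firth_fit()] model; the hard label
#' is positive when the probability is at least 0.5 (the boundary counts as
#' positive, fixed for reproducible paired tests).
#'
#' @param object a `firth_model`.
#' @param newdata feature table or numeric matrix containing the model's
#'   feature columns.
#' @param threshold decision threshold (default 0.5, boundary inclusive).
#' @param ... unused.
#' @return data.frame with columns `probability` and `predicted` (0/1).
#' @export
predict.firth_model <- function(object, newdata, threshold = 0.5, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$features, colnames(newdata))
    extra <- character(0)
    if (length(missing)) {
      stop("newdata lacks model feature(s): ",
           paste(missing, collapse = ", "))
    }
    newdata <- as.matrix(newdata[, object$features, drop = FALSE])
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object$features)) {
      stop("newdata has ", ncol(newdata), " columns; model expects ",
           length(object$features))
    }
  }
  eta <- drop(cbind(1, newdata) %*% object$coefficients)
  p <- plogis(eta)
  data.frame(probability = p, predicted = as.integer(p >= threshold))
}
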