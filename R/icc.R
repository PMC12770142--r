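#' Single-rating absolute-agreement intraclass correlation, ICC(A,1)
#'
#' McGraw-Wong ICC(A,1) from the two-way ANOVA mean squares of a complete
#' subjects-by-raters matrix (here: nodules by acquisition settings):
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' with MSR, MSC, MSE the subject, rater and residual mean squares. Absolute
#' agreement penalises systematic per-rater offsets, not just rank
#' disagreement. The estimate is at most 1 and may be negative (bounded
#' below by -1/(k-1)); negative values are retained as computed.
#'
#' A matrix with zero total variance (or an otherwise vanishing
#' denominator) is degenerate: the estimate is undefined and flagged, and
#' [categorize_icc()] assigns such features to the unstable stratum, since
#' a feature constant across subjects carries no discriminative signal.
#'
#' @param ratings numeric matrix, subjects in rows (n >= 2), raters in
#'   columns (k >= 2), no missing cells.
#' @return list with `icc`, the mean squares `msr`/`msc`/`mse`, `n`, `k`
#'   and `degenerate` flag.
#' @export
#' @examples
#' m <- cbind(1:6, (1:6) + 0.5)  # constant offset: high but imperfect
#' icc_a1(m)$icc
icc_a1 <- function(ratings) {
  x <- as.matrix(ratings)
  if (anyNA(x)) stop("ratings matrix must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")

  gm <- mean(x)
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc

  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  degenerate <- sst <= 0 || abs(denom) < .Machine$double.eps * max(1, sst)
  icc <- if (degenerate) NA_real_ else (msr - mse) / denom
  list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k,
       degenerate = degenerate)
}

#' Stability category from an ICC value
#'
#' Thresholds are inclusive exactly as conventionally stated: ICC >= 0.8 is
#' stable, ICC <= 0.4 unstable, anything strictly between is intermediate.
#' Degenerate (undefined) ICCs are categorized unstable.
#'
#' @param icc numeric vector of ICC estimates (may contain `NA`).
#' @param stable,unstable category thresholds, `0 < unstable < stable < 1`.
#' @param degenerate logical vector flagging undefined estimates.
#' @return character vector: `"stable"`, `"intermediate"` or `"unstable"`.
#' @export
#' @examples
#' categorize_icc(c(0.8, 0.4, 0.6))
categorize_icc <- function(icc, stable = 0.8, unstable = 0.4,
                           degenerate = is.na(icc)) {
  if (!(unstable < stable) || unstable <= 0 || stable >= 1) {
    stop("thresholds must satisfy 0 < unstable < stable < 1")
  }
  out <- ifelse(degenerate | icc <= unstable, "unstable",
                ifelse(icc >= stable, "stable", "intermediate"))
  out[is.na(out)] <- "unstable"
  out
}
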