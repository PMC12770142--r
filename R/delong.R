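#' DeLong test for two correlated AUCs
#'
#' Paired z-test of the AUC difference of two score vectors computed on the
#' same labelled cases, using DeLong's structural components: per-positive
#' and per-negative placement values, whose empirical covariance yields the
#' variance of the AUC difference. Two-sided p-value.
#'
#' When the two score vectors induce identical placement values (e.g. equal
#' scores), the variance of the difference is zero and the p-value is 1
#' with `degenerate = TRUE`.
#'
#' @param scores_a,scores_b score vectors of the two models on the same cases.
#' @param labels binary labels containing both classes.
#' @return list with `auc_a`, `auc_b`, `delta`, `variance`, `z`, `p`,
#'   `degenerate`.
#' @export
#' @examples
#' y <- rep(c(0, 1), each = 10)
#' s <- seq_len(20)
#' delong_test(s, s, y)$p   # identical scores: p = 1
delong_test <- function(scores_a, scores_b, labels) {
  y <- as_binary_label(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("scores and labels differ in length")
  }
  if (length(unique(y)) != 2L) stop("labels must contain both classes")

  placements <- function(s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
    v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), 0)
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)

  n1 <- sum(y == 1); n0 <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc

  if (v <= .Machine$double.eps) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                variance = 0, z = NA_real_, p = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, variance = v,
       z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}
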