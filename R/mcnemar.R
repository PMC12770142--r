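#' McNemar test on paired correctness vectors
#'
#' Compares two classifiers on the same cases through their discordant
#' counts: `b` cases correct under A only, `c` correct under B only. For
#' sensitivity comparisons the vectors are computed on positive cases only,
#' for specificity on negative cases only. When `b + c < 25` an exact
#' two-sided binomial test is used; otherwise the chi-square statistic with
#' continuity correction `(|b - c| - 1)^2 / (b + c)`. `b + c = 0` returns
#' p = 1 with a flag.
#'
#' @param correct_a,correct_b logical vectors: was each case classified
#'   correctly by model A / model B?
#' @return list with `b`, `c`, `p`, `method`
#'   (`"exact"`, `"chisq"` or `"no-discordance"`), `degenerate`.
#' @export
#' @examples
#' mcnemar_paired(rep(c(TRUE, FALSE), 5), rep(c(TRUE, FALSE), 5))$p  # 1
mcnemar_paired <- function(correct_a, correct_b) {
  a <- as.logical(correct_a); b_ <- as.logical(correct_b)
  if (length(a) != length(b_)) stop("correctness vectors differ in length")
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  n <- b + cc
  if (n == 0L) {
    return(list(b = b, c = cc, p = 1, method = "no-discordance",
                degenerate = TRUE))
  }
  if (n < 25L) {
    p <- stats::binom.test(b, n, 0.5)$p.value
    method <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(b = b, c = cc, p = min(p, 1), method = method, degenerate = FALSE)
}
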