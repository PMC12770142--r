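#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection of up to `m` features. Relevance of a feature is
#' the one-way F statistic of the feature against the binary label,
#' normalised by the largest F among the candidates so that relevance and
#' redundancy are commensurable; redundancy is the mean absolute Pearson
#' correlation with the already-selected features; the selection criterion
#' is their difference. The first feature is the most relevant one. Ties are
#' broken by candidate column order, so the result is deterministic.
#'
#' Candidates with undefined relevance (constant features, missing values)
#' are excluded with a warning. Requesting more features than there are
#' candidates selects all of them with a warning.
#'
#' @param x feature table or numeric matrix of candidates (typically
#'   z-scored training data).
#' @param y binary labels (logical, 0/1, or `"benign"`/`"malignant"`).
#' @param m number of features to select (default 20).
#' @return object of class `mrmr_selection`: list with `features` (ordered
#'   character vector), `scores` (criterion value at selection) and
#'   `relevance` (normalised relevance of all candidates).
#' @export
mrmr_select <- function(x, y, m = 20) {
  if (m < 1) stop("m must be >= 1")
  if (is.data.frame(x)) {
    x <- as.matrix(x[, feature_columns(x), drop = FALSE])
  }
  y <- as_binary_label(y)
  if (length(unique(y)) != 2L) stop("labels must contain both classes")
  if (!ncol(x)) stop("no candidate features")

  keep <- apply(x, 2, function(col) all(is.finite(col)) && sd(col) > 0)
  if (any(!keep)) {
    warning("excluding ", sum(!keep), " constant/non-finite candidate(s)")
    x <- x[, keep, drop = FALSE]
  }
  p <- ncol(x)
  if (!p) stop("no usable candidate features")
  if (m > p) {
    warning("requested ", m, " features but only ", p, " candidates; selecting all")
    m <- p
  }

  f_stat <- apply(x, 2, function(col) {
    a <- col[y == 1]; b <- col[y == 0]
    msb <- length(a) * (mean(a) - mean(col))^2 +
      length(b) * (mean(b) - mean(col))^2
    msw <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(col) - 2)
    if (msw <= 0) Inf else msb / msw
  })
  rel <- f_stat / max(f_stat[is.finite(f_stat)], 1e-300)
  rel[!is.finite(rel)] <- 1  # perfectly separating, zero within-class spread

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  cors <- matrix(0, p, 0)
  while (length(selected) < m) {
    crit <- if (!length(selected)) rel[remaining] else {
      red <- rowMeans(abs(cors[remaining, , drop = FALSE]))
      rel[remaining] - red
    }
    pick <- remaining[which.max(crit)]   # ties: first (column order)
    scores <- c(scores, max(crit))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    cors <- cbind(cors, suppressWarnings(cor(x, x[, pick])))
    cors[is.na(cors)] <- 0
  }
  structure(list(features = colnames(x)[selected], scores = scores,
                 relevance = rel),
            class = "mrmr_selection")
}

as_binary_label <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    ok <- y %in% c("benign", "malignant")
    if (!all(ok)) stop("character labels must be 'benign'/'malignant'")
    as.numeric(y == "malignant")
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("labels must be binary")
    y
  }
}
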