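#' Grey-level co-occurrence matrix (GLCM) features
#'
#' For each of the 13 unique 3D voxel offsets at Chebyshev distance 1, a
#' symmetric co-occurrence matrix is accumulated over voxel pairs that both
#' lie inside the ROI, normalised, and 24 standard GLCM statistics are
#' computed; the reported value of each statistic is its mean over offsets
#' (offsets with no valid pair are skipped). Grey levels are the 1-based
#' discretization bin indices.
#'
#' The 24 statistics: Autocorrelation, JointAverage, ClusterProminence,
#' ClusterShade, ClusterTendency, Contrast, Correlation, DifferenceAverage,
#' DifferenceEntropy, DifferenceVariance, JointEnergy, JointEntropy, Imc1,
#' Imc2, Idm, Idmn, Id, Idn, InverseVariance, MaximumProbability,
#' SumAverage, SumEntropy, SumSquares, SumVariance. (SumVariance is kept in
#' place of the eigenvalue-based maximal correlation coefficient so every
#' statistic is a closed-form moment of the matrix.) A single-level ROI has
#' Contrast 0, JointEnergy 1 and `NA` sentinels for Correlation and Imc1.
#'
#' @param v a [volume_grid()] (preprocessed).
#' @param m a congruent nonempty [roi_mask()].
#' @param bin_width grey-level bin width for discretization.
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(v, m, bin_width = 25) {
  g <- array(NA_integer_, dim(v$data))
  g[m$voxels] <- discretize(v$data[m$voxels], bin_width)
  L <- max(g, na.rm = TRUE)

  stats_sum <- NULL
  n_used <- 0L
  for (o in seq_len(nrow(.glcm_offsets))) {
    P <- glcm_matrix(g, .glcm_offsets[o, ], L)
    if (is.null(P)) next
    st <- glcm_statistics(P)
    stats_sum <- if (is.null(stats_sum)) st else stats_sum + st
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("degenerate ROI: no co-occurring voxel pairs")
  stats_sum / n_used
}

# 13 unique offsets at distance 1 (half of the 26-neighbourhood).
.glcm_offsets <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)
)

# Symmetric normalised co-occurrence matrix for one offset, or NULL when no
# valid pair exists.
glcm_matrix <- function(g, off, L) {
  d <- dim(g)
  if (any(abs(off) >= d)) return(NULL)
  src <- lapply(1:3, function(ax) {
    if (off[ax] >= 0) seq_len(d[ax] - off[ax]) else (1 - off[ax]):d[ax]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] + off[ax])
  a <- g[src[[1]], src[[2]], src[[3]]]
  b <- g[dst[[1]], dst[[2]], dst[[3]]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NULL)
  counts <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
  C <- matrix(counts, L, L, byrow = TRUE)
  C <- C + t(C)
  C / sum(C)
}

glcm_statistics <- function(P) {
  L <- nrow(P)
  i <- seq_len(L)
  px <- rowSums(P)                       # == colSums by symmetry
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ii <- matrix(i, L, L); jj <- t(ii)

  # diagonal and cross-diagonal distributions (grouped accumulation)
  k_diff <- 0:(L - 1)
  p_diff <- unname(rowsum(as.vector(P), as.vector(abs(ii - jj)))[, 1])
  k_sum <- 2:(2 * L)
  p_sum <- unname(rowsum(as.vector(P), as.vector(ii + jj))[, 1])

  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hxy <- ent(P)
  hx <- ent(px)
  pq <- outer(px, px)
  pos <- P > 0 & pq > 0
  hxy1 <- -sum(P[pos] * log2(pq[pos]))
  hxy2 <- ent(pq)

  da <- sum(k_diff * p_diff)
  sa <- sum(k_sum * p_sum)
  corr <- if (sig2 > 0) (sum(ii * jj * P) - mu^2) / sig2 else NA_real_
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  offdiag <- abs(ii - jj) > 0

  c(Autocorrelation = sum(ii * jj * P),
    JointAverage = mu,
    ClusterProminence = sum((ii + jj - 2 * mu)^4 * P),
    ClusterShade = sum((ii + jj - 2 * mu)^3 * P),
    ClusterTendency = sum((ii + jj - 2 * mu)^2 * P),
    Contrast = sum((ii - jj)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = ent(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (ii - jj)^2)),
    Idmn = sum(P / (1 + ((ii - jj) / L)^2)),
    Id = sum(P / (1 + abs(ii - jj))),
    Idn = sum(P / (1 + abs(ii - jj) / L)),
    InverseVariance = sum(P[offdiag] / (ii - jj)[offdiag]^2),
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = ent(p_sum),
    SumSquares = sig2,
    SumVariance = sum((k_sum - sa)^2 * p_sum))
}
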