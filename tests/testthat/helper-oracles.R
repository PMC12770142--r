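# Independent oracles and fixture builders used across the test suite.
# Every oracle is a direct, naive computation kept deliberately separate
# from the package's implementation path.

# --- fixtures ---------------------------------------------------------------

# digitized sphere mask of the given radius (voxels) at 1 mm spacing
sphere_mask <- function(radius, n = 2 * ceiling(radius) + 7) {
  cx <- (1:n) - (n + 1) / 2
  array(outer(outer(cx^2, cx^2, "+"), cx^2, "+") <= radius^2, c(n, n, n))
}

random_roi_volume <- function(dims = c(6, 6, 4), n_roi = 60, levels = NULL,
                              seed = 1) {
  set.seed(seed)
  vox <- array(runif(prod(dims), 0, 2048), dims)
  if (!is.null(levels)) {
    vox <- array(sample(levels, prod(dims), replace = TRUE) * 25 - 12, dims)
  }
  mask <- array(FALSE, dims)
  mask[sample(prod(dims), n_roi)] <- TRUE
  list(volume = volume_grid(vox, c(1, 1, 1)), mask = roi_mask(mask))
}

# --- ICC oracle: two-way ANOVA mean squares via stats::aov ------------------

icc_a1_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(stats::aov(y ~ subj + rater, data = df))[["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
}

# --- first-order oracle: direct formulas ------------------------------------

first_order_oracle <- function(x, vox_vol, bin_width = 25) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  p10 <- quantile(x, 0.1, names = FALSE); p90 <- quantile(x, 0.9, names = FALSE)
  inner <- x[x >= p10 & x <= p90]
  counts <- table(floor(x / bin_width))
  pr <- as.numeric(counts) / n
  c(Mean = mu, Median = median(x), Minimum = min(x), Maximum = max(x),
    Range = max(x) - min(x), Variance = m2,
    Skewness = (sum((x - mu)^3) / n) / m2^1.5,
    Kurtosis = (sum((x - mu)^4) / n) / m2^2,
    Energy = sum(x^2), TotalEnergy = vox_vol * sum(x^2),
    Entropy = -sum(pr * log2(pr)), Uniformity = sum(pr^2),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    `10Percentile` = p10, `90Percentile` = p90,
    InterquartileRange = quantile(x, 0.75, names = FALSE) -
      quantile(x, 0.25, names = FALSE))
}

# --- GLCM oracle: brute-force voxel-pair enumeration ------------------------

glcm_offsets_oracle <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

glcm_oracle <- function(v, m, bin_width = 25) {
  g <- array(NA_integer_, dim(v$data))
  raw <- floor(v$data[m$voxels] / bin_width)
  g[m$voxels] <- as.integer(raw - min(raw) + 1)
  L <- max(g, na.rm = TRUE)
  d <- dim(g)
  acc <- NULL; used <- 0
  for (o in seq_len(nrow(glcm_offsets_oracle))) {
    off <- glcm_offsets_oracle[o, ]
    P <- matrix(0, L, L)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      a <- g[i, j, k]; b <- g[i2, j2, k2]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
    if (sum(P) == 0) next
    st <- glcm_stats_oracle(P / sum(P))
    acc <- if (is.null(acc)) st else acc + st
    used <- used + 1
  }
  acc / used
}

glcm_stats_oracle <- function(P) {
  L <- nrow(P)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  sig2 <- sum((seq_len(L) - mu)^2 * px)
  idx <- which(P > 0, arr.ind = TRUE)
  p <- P[idx]
  i <- idx[, 1]; j <- idx[, 2]
  pd <- vapply(0:(L - 1), function(k) sum(p[abs(i - j) == k]), 0)
  ps <- vapply(2:(2 * L), function(k) sum(p[i + j == k]), 0)
  da <- sum((0:(L - 1)) * pd)
  sa <- sum((2:(2 * L)) * ps)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  hxy <- ent(p); hx <- ent(px)
  hxy1 <- -sum(p * log2(px[i] * px[j]))
  pq <- outer(px, px); hxy2 <- ent(pq)
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterTendency = sum((i + j - 2 * mu)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else NA_real_,
    DifferenceAverage = da,
    DifferenceEntropy = ent(pd),
    DifferenceVariance = sum(((0:(L - 1)) - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    Imc1 = if (hx > 0) (hxy - hxy1) / hx else NA_real_,
    Imc2 = sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0)),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / L)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / L)),
    InverseVariance = sum((p / (i - j)^2)[i != j]),
    MaximumProbability = max(p),
    SumAverage = sa,
    SumEntropy = ent(ps),
    SumSquares = sig2,
    SumVariance = sum(((2:(2 * L)) - sa)^2 * ps))
}

# --- AUC oracle: all positive-negative pairs, ties one half -----------------

auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# --- Firth oracle: direct maximization of the penalized likelihood ----------

firth_penalized_ll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  sum(y * eta - log1p(exp(eta))) + 0.5 * log(det(crossprod(X, X * w)))
}

firth_oracle <- function(x, y) {
  X <- cbind(1, x)
  k <- ncol(X)
  # coarse grid then derivative-free local maximization
  grid <- as.matrix(expand.grid(rep(list(seq(-4, 4, 0.5)), k)))
  obj <- function(b) firth_penalized_ll(b, X, y)
  vals <- apply(grid, 1, obj)
  start <- grid[which.max(vals), ]
  opt <- optim(start, obj,
               control = list(fnscale = -1, reltol = 1e-14, maxit = 5000))
  opt$par
}

# --- DeLong oracle: stratified bootstrap of the AUC difference --------------

delong_bootstrap_p <- function(scores_a, scores_b, labels, n_boot = 1e4,
                               seed = 1) {
  set.seed(seed)
  pos <- which(labels == 1); neg <- which(labels == 0)
  delta <- replicate(n_boot, {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc_score(labels[idx], scores_a[idx]) -
      auc_score(labels[idx], scores_b[idx])
  })
  2 * min(mean(delta <= 0), mean(delta >= 0))
}
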