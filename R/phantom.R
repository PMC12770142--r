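#' Phantom nodule cohort specification
#'
#' Parameters of the synthetic lung-nodule cohort generator. Nodules are
#' blob-like regions (ellipsoids with optional smooth surface irregularity)
#' embedded in a noisy lung-window background, generated at the reference
#' acquisition geometry (1 mm slices, 0.5 mm in-plane spacing standing for a
#' 1024 matrix over the scan field). Equivalent-sphere diameters follow a
#' truncated normal: mean 9.31 mm, sd 4.90 mm, truncated to the 5-30 mm
#' inclusion window of the study design.
#'
#' @param n_nodules number of nodules (>= 0).
#' @param diameter_mean_mm,diameter_sd_mm untruncated normal parameters of
#'   the equivalent-sphere diameter (mm).
#' @param diameter_range_mm closed truncation interval (mm), min < max.
#' @param background_level,background_noise_sd background intensity (HU) and
#'   Gaussian noise sd.
#' @param nodule_level mean nodule intensity (HU).
#' @param malignant_fraction proportion of malignant nodules in [0, 1];
#'   the realised count is `round(n_nodules * malignant_fraction)`.
#' @param malignant_texture_effect dimensionless effect size scaling the
#'   smooth intensity-heterogeneity field added inside malignant nodules
#'   (amplitude `30 * effect` HU).
#' @param shape_irregularity surface irregularity in [0, 1]; 0 gives exact
#'   ellipsoids.
#' @param seed master seed; per-nodule child seeds are derived
#'   deterministically from it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_nodules,
                         diameter_mean_mm = 9.31,
                         diameter_sd_mm = 4.90,
                         diameter_range_mm = c(5, 30),
                         background_level = -800,
                         background_noise_sd = 25,
                         nodule_level = -50,
                         malignant_fraction = 0.5,
                         malignant_texture_effect = 1,
                         shape_irregularity = 0.3,
                         seed = 1L) {
  if (n_nodules < 0) stop("n_nodules must be >= 0")
  r <- as.numeric(diameter_range_mm)
  if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[1] >= r[2]) {
    stop("diameter_range_mm must be a finite positive interval with min < max")
  }
  if (malignant_fraction < 0 || malignant_fraction > 1) {
    stop("malignant_fraction must be in [0, 1]")
  }
  if (diameter_sd_mm <= 0) stop("diameter_sd_mm must be > 0")
  structure(list(
    n_nodules = as.integer(n_nodules),
    diameter_mean_mm = diameter_mean_mm, diameter_sd_mm = diameter_sd_mm,
    diameter_range_mm = r,
    background_level = background_level,
    background_noise_sd = background_noise_sd,
    nodule_level = nodule_level,
    malignant_fraction = malignant_fraction,
    malignant_texture_effect = malignant_texture_effect,
    shape_irregularity = shape_irregularity,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Sample equivalent-sphere diameters from the cohort's truncated normal
#'
#' Inverse-CDF sampling of N(mean, sd) truncated to `diameter_range_mm`.
#' Exposed so the diameter distribution can be examined without generating
#' voxel data.
#'
#' @param n number of draws.
#' @param spec a [phantom_spec()].
#' @return numeric vector of diameters (mm), all inside the range.
#' @export
sample_nodule_diameters <- function(n, spec) {
  a <- pnorm(spec$diameter_range_mm[1], spec$diameter_mean_mm, spec$diameter_sd_mm)
  b <- pnorm(spec$diameter_range_mm[2], spec$diameter_mean_mm, spec$diameter_sd_mm)
  qnorm(a + runif(n) * (b - a), spec$diameter_mean_mm, spec$diameter_sd_mm)
}

# Deterministic child seed derivation, kept inside 32-bit integer range.
child_seed <- function(master, index, salt = 0L) {
  as.integer((as.double(master) * 48271 + index * 9973 + salt * 7919) %%
               2147483647)
}

# Smooth standard-normal random field: coarse iid grid trilinearly
# interpolated up to `dims`.
smooth_field <- function(dims, n_coarse = 4L) {
  coarse <- array(rnorm(n_coarse^3), dim = rep(n_coarse, 3L))
  ax <- lapply(dims, function(n) seq(1, n_coarse, length.out = n))
  lo <- lapply(ax, function(x) pmin(floor(x), n_coarse - 1L))
  fr <- Map(function(x, l) x - l, ax, lo)
  out <- array(0, dim = dims)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    wz <- if (dz == 0) 1 - fr[[3]] else fr[[3]]
    wy <- if (dy == 0) 1 - fr[[2]] else fr[[2]]
    wx <- if (dx == 0) 1 - fr[[1]] else fr[[1]]
    sub <- coarse[lo[[1]] + dx, lo[[2]] + dy, lo[[3]] + dz, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + array(sub, dims) * w
  }
  out
}

#' Generate a phantom nodule cohort at reference geometry
#'
#' Draws nodule diameters from the truncated normal implied by `spec`,
#' embeds each nodule as an (optionally irregular) ellipsoid of intensity
#' `nodule_level` in a noisy background of `background_level`, and labels a
#' `malignant_fraction` of nodules malignant; malignant nodules additionally
#' receive a smooth intensity-heterogeneity field scaled by
#' `malignant_texture_effect`. All volumes are generated at the reference
#' geometry: spacing 0.5 x 0.5 x 1 mm.
#'
#' @param spec a [phantom_spec()].
#' @return list of [labeled_volume()] objects (empty list for
#'   `n_nodules = 0`); deterministic for a fixed `spec$seed`.
#' @export
#' @examples
#' cohort <- make_phantom_cohort(phantom_spec(2, seed = 7))
#' cohort[[1]]
make_phantom_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_nodules
  if (n == 0L) return(list())
  set.seed(spec$seed)
  diameters <- sample_nodule_diameters(n, spec)
  n_mal <- round(n * spec$malignant_fraction)
  labels <- sample(rep(c("malignant", "benign"), c(n_mal, n - n_mal)))
  lapply(seq_len(n), function(i) {
    set.seed(child_seed(spec$seed, i))
    generate_nodule(diameters[i], labels[i], sprintf("N%04d", i), spec)
  })
}

generate_nodule <- function(d, label, id, spec) {
  sp <- c(0.5, 0.5, 1)               # reference geometry (mm)
  margin_xy <- 6; margin_z <- 4
  nx <- 2L * ceiling((d + 2 * margin_xy) / sp[1] / 2)   # even for 2x pooling
  nz <- as.integer(ceiling((d + 2 * margin_z) / sp[3]))
  dims <- c(nx, nx, nz)

  # physical coordinates centred on the nodule
  cx <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
  cy <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp[2]
  cz <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * sp[3]

  # ellipsoid semi-axes with product r^3 (volume-preserving anisotropy)
  r <- d / 2
  u <- rnorm(2, 0, 0.12)
  a <- r * exp(u[1]); b <- r * exp(u[2]); cc <- r^3 / (a * b)

  rho <- sqrt(outer(outer((cx / a)^2, (cy / b)^2, "+"), (cz / cc)^2, "+"))
  irr <- if (spec$shape_irregularity > 0) {
    1 + 0.5 * spec$shape_irregularity * smooth_field(dims)
  } else 1
  inside <- rho <= irr

  vox <- array(rnorm(prod(dims), spec$background_level,
                     spec$background_noise_sd), dim = dims)
  n_in <- sum(inside)
  vox[inside] <- spec$nodule_level + rnorm(n_in, 0, 15)
  if (label == "malignant" && spec$malignant_texture_effect != 0) {
    tex <- smooth_field(dims, n_coarse = 6L)
    vox[inside] <- vox[inside] +
      30 * spec$malignant_texture_effect * tex[inside]
  }
  labeled_volume(volume_grid(vox, spacing = sp), roi_mask(inside),
                 label = label, nodule_id = id, diameter_mm = d)
}

#' Cohort manifest
#'
#' @param cohort list of [labeled_volume()]s.
#' @return data.frame with nodule_id, label and generated diameter.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    nodule_id = vapply(cohort, `[[`, "", "nodule_id"),
    label = vapply(cohort, `[[`, "", "label"),
    diameter_mm = vapply(cohort, `[[`, 0, "diameter_mm"),
    stringsAsFactors = FALSE
  )
}
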