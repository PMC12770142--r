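#' Simulate a CT acquisition setting on a reference-geometry volume
#'
#' Applies the deterministic image operators that emulate one reconstruction
#' variant to a nodule volume generated at the reference geometry
#' (1 mm slices, 0.5 mm in-plane spacing standing for the 1024 matrix):
#'
#' * convolution kernel: soft kernels are an in-plane Gaussian blur, sharp
#'   kernels unsharp masking, the reference kernel the identity
#'   (see [kernel_params()]);
#' * slice thickness `k` > 1 mm: non-overlapping `k`-slab averaging along
#'   the axial axis (partial-volume effect), axial spacing updated to `k` mm;
#'   a trailing partial slab is averaged over its remaining slices;
#' * matrix 512: in-plane 2x2 block-mean downsampling (linear information
#'   loss of the coarser grid), in-plane spacing doubled;
#' * PACS transmission: 12-bit quantization round-trip (rounding to integer
#'   HU clipped to \[-1024, 3071\]) -- a near-identity.
#'
#' The mask is carried along by nearest-neighbour rules: the central slice of
#' each axial slab, and the lower-index voxel of each 2x2 in-plane block.
#' The reference setting S2 returns the input unchanged.
#'
#' @param v a [labeled_volume()] at reference geometry.
#' @param s one row of [acquisition_settings()] (data.frame or list with
#'   fields `setting_id`, `slice_thickness_mm`, `matrix`, `kernel_id`,
#'   `transmission`), or a setting id string like `"S3"`.
#' @param kernels kernel parameter table, see [kernel_params()].
#' @return a [labeled_volume()] under the requested setting.
#' @export
#' @examples
#' lv <- make_phantom_cohort(phantom_spec(1, seed = 1))[[1]]
#' thick <- apply_setting(lv, "S4")
#' thick$volume$spacing
apply_setting <- function(v, s, kernels = kernel_params()) {
  stopifnot(inherits(v, "labeled_volume"))
  if (is.character(s)) {
    tab <- acquisition_settings()
    row <- match(s, tab$setting_id)
    if (is.na(row)) stop("unknown setting id: ", s)
    s <- tab[row, ]
  }
  if (identical(as.character(s$setting_id), reference_setting())) return(v)

  data <- v$volume$data
  mask <- v$mask$voxels
  spacing <- v$volume$spacing

  kp <- kernels[match(s$kernel_id, kernels$kernel_id), ]
  if (is.na(kp$op)) stop("unknown kernel id: ", s$kernel_id)
  if (kp$op == "blur") {
    data <- blur_inplane(data, spacing, kp$param)
  } else if (kp$op == "sharpen") {
    data <- data + kp$param * (data - blur_inplane(data, spacing, 0.8))
  }

  k <- as.integer(s$slice_thickness_mm)
  if (k > 1L) {
    sl <- slab_average(data, mask, k)
    data <- sl$data; mask <- sl$mask
    spacing[3] <- spacing[3] * k
  }

  if (as.integer(s$matrix) == 512L) {
    dn <- downsample_inplane(data, mask)
    data <- dn$data; mask <- dn$mask
    spacing[1:2] <- spacing[1:2] * 2
  }

  if (identical(as.character(s$transmission), "PACS")) {
    data <- pmin(pmax(round(data), -1024), 3071)
  }

  if (!any(mask)) stop("mask became empty under setting ", s$setting_id)
  labeled_volume(volume_grid(data, spacing = spacing), roi_mask(mask),
                 label = v$label, nodule_id = v$nodule_id,
                 diameter_mm = v$diameter_mm)
}

slab_average <- function(data, mask, k) {
  d <- dim(data)
  starts <- seq(1L, d[3], by = k)
  nz <- length(starts)
  out <- array(0, c(d[1], d[2], nz))
  mout <- array(FALSE, c(d[1], d[2], nz))
  for (si in seq_along(starts)) {
    idx <- starts[si]:min(starts[si] + k - 1L, d[3])
    m <- matrix(data[, , idx, drop = FALSE], nrow = d[1] * d[2])
    out[, , si] <- rowMeans(m)
    mid <- idx[ceiling(length(idx) / 2)]   # nearest-neighbour slice
    mout[, , si] <- mask[, , mid]
  }
  list(data = out, mask = mout)
}

downsample_inplane <- function(data, mask) {
  d <- dim(data)
  if (d[1] %% 2L || d[2] %% 2L) {
    stop("in-plane dimensions must be even for 2x downsampling")
  }
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  out <- (data[o1, o2, , drop = FALSE] + data[e1, o2, , drop = FALSE] +
          data[o1, e2, , drop = FALSE] + data[e1, e2, , drop = FALSE]) / 4
  list(data = out, mask = mask[o1, o2, , drop = FALSE])
}
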