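#' Preprocessing specification
#'
#' Extraction-time preprocessing: intensities min-max rescaled to
#' \[0, 2048\], volume resampled to 1 mm isotropic spacing by separable
#' cubic-spline interpolation, mask by nearest neighbour, and grey levels
#' discretized with a fixed bin width of 25 anchored at multiples of the
#' bin width from 0.
#'
#' @param intensity_range target rescale range.
#' @param bin_width grey-level bin width (> 0).
#' @param target_spacing_mm isotropic target spacing (mm).
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(intensity_range = c(0, 2048), bin_width = 25,
                            target_spacing_mm = c(1, 1, 1)) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (any(target_spacing_mm <= 0)) stop("target spacing must be > 0")
  if (diff(intensity_range) < 0) stop("intensity_range must be increasing")
  structure(list(intensity_range = as.numeric(intensity_range),
                 bin_width = bin_width,
                 target_spacing_mm = as.numeric(target_spacing_mm)),
            class = "preprocess_spec")
}

#' Rescale intensities to a fixed range
#'
#' Min-max rescale over the whole volume. A zero-range (constant) volume is
#' mapped to the lower bound.
#' @param data numeric array.
#' @param range length-2 target range.
#' @return rescaled array.
#' @export
rescale_intensity <- function(data, range = c(0, 2048)) {
  lo <- min(data); hi <- max(data)
  if (hi == lo) return(array(range[1], dim(data)))
  range[1] + (data - lo) / (hi - lo) * diff(range)
}

# Interpolation weight matrix mapping samples at `pos_old` to `pos_new`
# (natural cubic spline); built once per axis, applied to all lines.
spline_weights <- function(pos_old, pos_new) {
  n <- length(pos_old)
  if (n == 1L) return(matrix(1, length(pos_new), 1L))
  vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    stats::splinefun(pos_old, e, method = "natural")(pos_new)
  }, numeric(length(pos_new)))
}

resample_axis <- function(a, axis, pos_old, pos_new, method) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  out <- if (method == "nearest") {
    idx <- vapply(pos_new, function(p) which.min(abs(pos_old - p)), 0L)
    m[idx, , drop = FALSE]
  } else {
    spline_weights(pos_old, pos_new) %*% m
  }
  d2 <- d[perm]; d2[1] <- length(pos_new)
  aperm(array(out, dim = d2), order(perm))
}

#' Resample a volume or mask to a new spacing
#'
#' Separable interpolation along each axis: cubic splines for images,
#' nearest neighbour for masks. Voxel centres are placed at
#' `(i - 1) * spacing`; the new grid covers the same physical extent.
#'
#' @param data 3D array.
#' @param spacing current spacing (mm).
#' @param target_spacing new spacing (mm).
#' @param method `"spline"` or `"nearest"`.
#' @return list with `data` (resampled array) and `spacing`.
#' @export
resample_volume <- function(data, spacing, target_spacing,
                            method = c("spline", "nearest")) {
  method <- match.arg(method)
  d <- dim(data)
  for (ax in 1:3) {
    if (abs(spacing[ax] - target_spacing[ax]) < 1e-12) next
    pos_old <- (seq_len(dim(data)[ax]) - 1) * spacing[ax]
    extent <- pos_old[length(pos_old)]
    pos_new <- seq(0, extent, by = target_spacing[ax])
    data <- resample_axis(data, ax, pos_old, pos_new, method)
  }
  list(data = data, spacing = as.numeric(target_spacing))
}

#' Preprocess a volume/mask pair for feature extraction
#'
#' Rescales intensities to `spec$intensity_range`, resamples both volume
#' (cubic spline, clipped back to the range) and mask (nearest neighbour)
#' to the isotropic target spacing.
#'
#' @param v a [volume_grid()].
#' @param m a congruent [roi_mask()].
#' @param spec a [preprocess_spec()].
#' @return list with elements `volume` and `mask`.
#' @export
preprocess <- function(v, m, spec = preprocess_spec()) {
  stopifnot(inherits(v, "volume_grid"), inherits(m, "roi_mask"))
  if (!identical(dim(v$data), dim(m$voxels))) {
    stop("mask must be congruent with the volume")
  }
  data <- rescale_intensity(v$data, spec$intensity_range)
  rs <- resample_volume(data, v$spacing, spec$target_spacing_mm, "spline")
  data <- pmin(pmax(rs$data, spec$intensity_range[1]), spec$intensity_range[2])
  mk <- resample_volume(m$voxels * 1, v$spacing, spec$target_spacing_mm,
                        "nearest")
  mask <- mk$data > 0.5
  if (!any(mask)) stop("degenerate ROI: mask is empty after resampling")
  list(volume = volume_grid(data, spacing = rs$spacing, origin = v$origin),
       mask = roi_mask(mask))
}

#' Discretize intensities into grey-level bins
#'
#' Bin edges are anchored at multiples of `bin_width` from 0:
#' `floor(value / bin_width)`, shifted so the lowest occupied bin is 1.
#' Values in \[0, 2048\] with bin width 25 occupy at most 82 bins.
#'
#' @param values numeric vector.
#' @param bin_width bin width (> 0).
#' @return integer vector of 1-based bin indices; the number of grey levels
#'   is `max()` of the result.
#' @export
#' @examples
#' discretize(c(0, 25, 50))   # 1 2 3
discretize <- function(values, bin_width = 25) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  raw <- floor(values / bin_width)
  as.integer(raw - min(raw) + 1)
}
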