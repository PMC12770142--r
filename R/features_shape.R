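#' Morphological (shape) features
#'
#' The 14 standard shape descriptors of a binary ROI: MeshVolume and
#' SurfaceArea from a marching-tetrahedra isosurface of the binary mask
#' (iso-level 0.5, edge crossings at voxel-centre midpoints), VoxelVolume,
#' SurfaceVolumeRatio, Sphericity, Maximum3DDiameter and the three maximum
#' 2D diameters (largest pairwise distance between boundary-voxel centres,
#' overall and within planes orthogonal to each axis), principal-axis
#' lengths (4 sqrt(lambda) from the eigenvalues of the voxel-centre
#' covariance), Elongation and Flatness.
#'
#' Degenerate ROIs follow documented sentinels: a single-voxel mask has all
#' diameters 0 and `NA` Sphericity, Elongation and Flatness.
#'
#' @param m a nonempty [roi_mask()].
#' @param spacing voxel spacing (mm).
#' @return named numeric vector of length 14.
#' @export
shape_features <- function(m, spacing) {
  mask <- m$voxels
  if (!any(mask)) stop("shape features require a nonempty mask")
  nvox <- sum(mask)
  vox_vol <- prod(spacing)

  mesh <- mesh_surface(mask, spacing)
  bnd <- boundary_voxel_coords(mask, spacing)

  max3d <- max_pairwise(bnd)
  max2d <- vapply(1:3, function(ax) {
    slices <- split.data.frame(bnd[, -ax, drop = FALSE], bnd[, ax])
    max(vapply(slices, max_pairwise, 0))
  }, 0)

  coords <- voxel_coords(mask, spacing)
  if (nrow(coords) > 1L) {
    ev <- sort(pmax(eigen(stats::cov(coords), symmetric = TRUE,
                          only.values = TRUE)$values, 0), decreasing = TRUE)
  } else ev <- c(0, 0, 0)

  single <- nvox == 1L
  sph <- if (single || mesh$area <= 0) NA_real_ else {
    pi^(1 / 3) * (6 * mesh$volume)^(2 / 3) / mesh$area
  }

  c(MeshVolume = mesh$volume,
    VoxelVolume = nvox * vox_vol,
    SurfaceArea = mesh$area,
    SurfaceVolumeRatio = if (mesh$volume > 0) mesh$area / mesh$volume else NA_real_,
    Sphericity = sph,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = max2d[3],   # within axial (xy) planes
    Maximum2DDiameterColumn = max2d[2],  # within coronal (xz) planes
    Maximum2DDiameterRow = max2d[1],     # within sagittal (yz) planes
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_)
}

voxel_coords <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

# Voxels of the mask with at least one 6-neighbour outside (or on the border).
boundary_voxel_coords <- function(mask, spacing) {
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  i <- 2:(d[1] + 1); j <- 2:(d[2] + 1); k <- 2:(d[3] + 1)
  nb <- p[i - 1, j, k] & p[i + 1, j, k] &
        p[i, j - 1, k] & p[i, j + 1, k] &
        p[i, j, k - 1] & p[i, j, k + 1]
  voxel_coords(mask & !nb, spacing)
}

max_pairwise <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}

# The 6-tetrahedra cube decomposition sharing the main diagonal 0-7; cube
# vertices are numbered dx + 2*dy + 4*dz.
.tet_cycle <- c(1L, 3L, 2L, 6L, 4L, 5L)
.cube_offsets <- unname(as.matrix(expand.grid(0:1, 0:1, 0:1)))

# Marching tetrahedra at iso-level 0.5 on a mildly Gaussian-smoothed
# indicator field of the mask (sigma 0.8 voxels; anti-aliases the staircase
# so a digitized sphere's area and volume approach the analytic values).
# Edge crossings are linearly interpolated. Returns total triangle area and
# the enclosed (mesh) volume via the divergence theorem with
# outward-oriented triangles.
mesh_surface <- function(mask, spacing, sigma_vox = 0.8) {
  d <- dim(mask)
  pad <- as.integer(ceiling(3 * sigma_vox) + 2L)
  p <- array(0, d + 2L * pad)
  p[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- mask * 1
  kern <- gaussian_kernel(sigma_vox)
  for (ax in 1:3) p <- conv_axis(p, kern, ax)

  nd <- dim(p) - 1L  # cube grid dimensions
  vals <- lapply(1:8, function(v) {
    off <- .cube_offsets[v, ]
    p[off[1] + seq_len(nd[1]), off[2] + seq_len(nd[2]),
      off[3] + seq_len(nd[3]), drop = FALSE]
  })
  lo <- Reduce(pmin, vals); hi <- Reduce(pmax, vals)
  mixed <- which(lo < 0.5 & hi >= 0.5)
  if (!length(mixed)) return(list(area = 0, volume = 0))

  cube_idx <- arrayInd(mixed, nd)
  cube_vals <- vapply(1:8, function(v) vals[[v]][mixed],
                      numeric(length(mixed)))

  tets <- lapply(seq_along(.tet_cycle), function(t) {
    a <- .tet_cycle[t]
    b <- .tet_cycle[if (t == length(.tet_cycle)) 1L else t + 1L]
    c(1L, a + 1L, b + 1L, 8L)   # vertex numbers 0,a,b,7 -> 1-based rows
  })

  cross_pt <- function(pp, tv, i_in, i_out) {
    t <- (0.5 - tv[i_in]) / (tv[i_out] - tv[i_in])
    pp[i_in, ] + t * (pp[i_out, ] - pp[i_in, ])
  }

  area <- 0; volume <- 0
  for (ci in seq_along(mixed)) {
    # physical coordinates of the 8 cube corners (voxel centres)
    base <- cube_idx[ci, ] - 1L - pad  # padded -> original 0-based index
    pts8 <- sweep(sweep(.cube_offsets, 2, base, "+"), 2, spacing, "*")
    v8 <- cube_vals[ci, ]
    for (tet in tets) {
      tv <- v8[tet]
      inside <- tv >= 0.5
      nin <- sum(inside)
      if (nin == 0 || nin == 4) next
      pp <- pts8[tet, , drop = FALSE]
      ins <- which(inside); outs <- which(!inside)
      tri_list <- if (nin == 1L) {
        list(rbind(cross_pt(pp, tv, ins, outs[1]),
                   cross_pt(pp, tv, ins, outs[2]),
                   cross_pt(pp, tv, ins, outs[3])))
      } else if (nin == 3L) {
        list(rbind(cross_pt(pp, tv, ins[1], outs),
                   cross_pt(pp, tv, ins[2], outs),
                   cross_pt(pp, tv, ins[3], outs)))
      } else {
        mac <- cross_pt(pp, tv, ins[1], outs[1])
        mad_ <- cross_pt(pp, tv, ins[1], outs[2])
        mbd <- cross_pt(pp, tv, ins[2], outs[2])
        mbc <- cross_pt(pp, tv, ins[2], outs[1])
        list(rbind(mac, mad_, mbd), rbind(mac, mbd, mbc))
      }
      ref <- colMeans(pp[ins, , drop = FALSE])
      for (tri in tri_list) {
        e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
        nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
                 e1[3] * e2[1] - e1[1] * e2[3],
                 e1[1] * e2[2] - e1[2] * e2[1])
        if (sum(nrm * (colMeans(tri) - ref)) < 0) {
          tri <- tri[c(1, 3, 2), ]
          nrm <- -nrm
        }
        area <- area + sqrt(sum(nrm^2)) / 2
        volume <- volume +
          (tri[1, 1] * (tri[2, 2] * tri[3, 3] - tri[2, 3] * tri[3, 2]) -
           tri[1, 2] * (tri[2, 1] * tri[3, 3] - tri[2, 3] * tri[3, 1]) +
           tri[1, 3] * (tri[2, 1] * tri[3, 2] - tri[2, 2] * tri[3, 1])) / 6
      }
    }
  }
  list(area = unname(area), volume = abs(unname(volume)))
}
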