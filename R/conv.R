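# Separable 1D convolution along one axis of a 3D array, vectorised as a
# small number of row-indexed matrix additions. Used by the kernel
# simulators, the Gaussian/LoG filters and the wavelet transform.

wrap_index <- function(idx, n, boundary) {
  if (boundary == "periodic") return(((idx - 1L) %% n) + 1L)
  # symmetric (mirror) reflection; iterate for kernels wider than the axis
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}

conv_axis <- function(a, kern, axis, boundary = "symmetric",
                      center = (length(kern) + 1L) %/% 2L) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kern)) {
    idx <- wrap_index(seq_len(n) + (j - center), n, boundary)
    out <- out + kern[j] * m[idx, , drop = FALSE]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# In-plane (axes 1-2) Gaussian blur with sigma in millimetres.
blur_inplane <- function(data, spacing, sigma_mm) {
  for (ax in 1:2) {
    data <- conv_axis(data, gaussian_kernel(sigma_mm / spacing[ax]), ax)
  }
  data
}

# Full 3D Gaussian blur with sigma in millimetres.
blur_3d <- function(data, spacing, sigma_mm) {
  for (ax in 1:3) {
    data <- conv_axis(data, gaussian_kernel(sigma_mm / spacing[ax]), ax)
  }
  data
}
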