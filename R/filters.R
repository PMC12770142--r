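#' Filter bank specification
#'
#' The derived-image filter bank applied before recomputing intensity and
#' texture features: a single-level undecimated 3D wavelet decomposition
#' (8 sub-bands, low/high-pass per axis), Laplacian-of-Gaussian volumes at
#' the given sigmas, and the three algebraic maps (square, square root,
#' exponential) with range-preserving scalings.
#'
#' @param wavelet `"coif1"` (default) or `"haar"`.
#' @param log_sigmas_mm positive LoG scales (mm).
#' @param algebraic subset of `c("square", "squareroot", "exponential")`.
#' @return object of class `filter_bank_spec`.
#' @export
filter_bank_spec <- function(wavelet = "coif1",
                             log_sigmas_mm = c(1, 2, 3),
                             algebraic = c("square", "squareroot",
                                           "exponential")) {
  if (any(log_sigmas_mm <= 0)) stop("LoG sigma values must be positive")
  wavelet <- match.arg(wavelet, c("coif1", "haar"))
  algebraic <- match.arg(algebraic, several.ok = TRUE,
                         c("square", "squareroot", "exponential"))
  structure(list(wavelet = wavelet, log_sigmas_mm = log_sigmas_mm,
                 algebraic = algebraic),
            class = "filter_bank_spec")
}

# Analysis filter pairs (decomposition low/high-pass).
wavelet_filters <- function(name) {
  switch(name,
    haar = list(lo = c(1, 1) / sqrt(2), hi = c(-1, 1) / sqrt(2)),
    coif1 = list(
      lo = c(-0.015655728135791993, -0.07273261951252645,
             0.3848648468648578, 0.8525720202116004,
             0.3378976624574818, -0.07273261951252645),
      hi = c(0.07273261951252645, 0.3378976624574818,
             -0.8525720202116004, 0.3848648468648578,
             0.07273261951252645, -0.015655728135791993)),
    stop("unknown wavelet: ", name))
}

#' Compute the derived-image filter bank
#'
#' Returns the named derived volumes on which first-order and GLCM features
#' are recomputed: `wavelet.LLL` ... `wavelet.HHH` (letters give the
#' low/high-pass choice along axes 1, 2, 3; undecimated transform with
#' periodic boundary, so sub-bands stay congruent with the mask),
#' `log.sigma.<s>.mm` (scale-normalised Laplacian of Gaussian,
#' sigma^2 * Laplacian(G_sigma * v)), and the algebraic maps. With maximum
#' masked-volume intensity M: square is `x^2 / M`, squareroot is
#' `sqrt(x * M)` (sign-preserving), exponential is `exp(x * log(M) / M)`;
#' each maps the intensity range onto itself and the square root is
#' inverted exactly by the square map.
#'
#' @param v a preprocessed [volume_grid()] (intensities in \[0, 2048\]).
#' @param bank a [filter_bank_spec()].
#' @return named list of [volume_grid()] objects.
#' @export
filter_images <- function(v, bank = filter_bank_spec()) {
  stopifnot(inherits(v, "volume_grid"))
  out <- list()

  wf <- wavelet_filters(bank$wavelet)
  for (bits in 0:7) {
    hl <- c(bitwAnd(bits, 1L) > 0, bitwAnd(bits, 2L) > 0,
            bitwAnd(bits, 4L) > 0)
    data <- v$data
    for (ax in 1:3) {
      data <- conv_axis(data, if (hl[ax]) wf$hi else wf$lo, ax,
                        boundary = "periodic")
    }
    nm <- paste0("wavelet.", paste(ifelse(hl, "H", "L"), collapse = ""))
    out[[nm]] <- volume_grid(data, v$spacing, v$origin)
  }

  for (s in bank$log_sigmas_mm) {
    sm <- blur_3d(v$data, v$spacing, s)
    lap <- array(0, dim(sm))
    for (ax in 1:3) {
      lap <- lap + conv_axis(sm, c(1, -2, 1), ax) / v$spacing[ax]^2
    }
    nm <- sprintf("log.sigma.%s.mm", format(s, nsmall = 1))
    out[[nm]] <- volume_grid(s^2 * lap, v$spacing, v$origin)
  }

  M <- max(abs(v$data))
  alg <- list(
    square = function(x) if (M > 0) x^2 / M else x,
    squareroot = function(x) if (M > 0) sign(x) * sqrt(abs(x) * M) else x,
    exponential = function(x) if (M > 0) exp(x * log(M) / M) else exp(x)
  )
  for (nm in bank$algebraic) {
    out[[nm]] <- volume_grid(alg[[nm]](v$data), v$spacing, v$origin)
  }
  out
}
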