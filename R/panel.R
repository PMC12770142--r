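#' Feature-panel simulation specification
#'
#' Direct simulation of per-setting radiomic feature tables with a known
#' agreement structure, bypassing imaging. Feature `f` for subject `i`
#' under setting `s` is
#' \deqn{x_{isf} = t_{if} + c_f \, z_i + \delta_{sf} + \sigma_{wf}\, g_s\, e_{isf}}
#' with between-subject effect `t ~ N(0, sd_b^2)`, malignancy indicator
#' `z_i` and class effect `c_f`, fixed per-setting offsets `delta`, and iid
#' within-subject noise `e`. The within-subject sd `sigma_w` is chosen per
#' feature so that the population single-rating absolute-agreement ICC
#' equals `target_icc[f]`:
#' \deqn{\rho_f = sd_b^2 / (sd_b^2 + \theta_f^2 + \sigma_{wf}^2)}
#' where `theta^2` is the rater mean square of the offsets. Optional
#' per-setting noise scales `g_s` (normalised internally so that
#' `mean(g^2) = 1`, preserving the ICC target) let some settings degrade a
#' feature more than others, emulating e.g. thick-slice reconstructions.
#'
#' @param n_subjects number of subjects (nodules).
#' @param n_features number of simulated features.
#' @param target_icc population ICC per feature; scalar or length
#'   `n_features` vector, values in \[0, 1\].
#' @param between_subject_sd between-subject sd (scalar or per feature).
#' @param setting_offsets `NULL`, or a `n_settings x n_features` matrix of
#'   fixed per-setting shifts.
#' @param class_effect additive shift applied to malignant subjects
#'   (scalar or per feature).
#' @param malignant_fraction proportion malignant; realised count is
#'   `round(n_subjects * malignant_fraction)`.
#' @param settings character vector of setting ids (one output table each).
#' @param setting_noise_scale per-setting within-subject noise multipliers
#'   (scalar or length `length(settings)`); normalised to mean square 1.
#' @param seed integer seed.
#' @return object of class `panel_spec`.
#' @export
panel_spec <- function(n_subjects, n_features,
                       target_icc = 0.8,
                       between_subject_sd = 1,
                       setting_offsets = NULL,
                       class_effect = 0,
                       malignant_fraction = 0.5,
                       settings = acquisition_settings()$setting_id,
                       setting_noise_scale = 1,
                       seed = 1L) {
  k <- length(settings)
  target_icc <- rep_len(target_icc, n_features)
  if (any(target_icc < 0 | target_icc > 1)) {
    stop("target_icc must be in [0, 1]")
  }
  if (!is.null(setting_offsets)) {
    setting_offsets <- as.matrix(setting_offsets)
    if (!all(dim(setting_offsets) == c(k, n_features))) {
      stop("setting_offsets must be a n_settings x n_features matrix")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_features = as.integer(n_features),
    target_icc = target_icc,
    between_subject_sd = rep_len(between_subject_sd, n_features),
    setting_offsets = setting_offsets,
    class_effect = rep_len(class_effect, n_features),
    malignant_fraction = malignant_fraction,
    settings = as.character(settings),
    setting_noise_scale = rep_len(setting_noise_scale, k),
    seed = as.integer(seed)
  ), class = "panel_spec")
}

#' Simulate per-setting feature tables with controlled agreement
#'
#' Generates one feature table per acquisition setting under the
#' variance-component model documented in [panel_spec()]. With zero offsets
#' and unit noise scales, the empirical ICC(A,1) of feature `f` converges to
#' `target_icc[f]` as subjects grow.
#'
#' @param spec a [panel_spec()].
#' @return named list (by setting id) of data.frames with columns
#'   `nodule_id`, `setting_id`, `label`, then `n_features` feature columns
#'   `f0001`, `f0002`, ... Deterministic for fixed seed.
#' @export
#' @examples
#' tabs <- simulate_feature_panel(panel_spec(50, 4, target_icc = 0.9, seed = 2))
#' names(tabs)
simulate_feature_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects; p <- spec$n_features
  k <- length(spec$settings)
  rho <- spec$target_icc
  sdb <- spec$between_subject_sd

  # rater mean square of the fixed offsets (theta^2), per feature
  theta2 <- if (is.null(spec$setting_offsets) || k < 2) {
    numeric(p)
  } else {
    apply(spec$setting_offsets, 2, function(d) sum((d - mean(d))^2) / (k - 1))
  }

  sigw <- numeric(p)
  for (f in seq_len(p)) {
    if (rho[f] < 1e-12) {
      sdb[f] <- 0
      sigw[f] <- spec$between_subject_sd[f]
    } else {
      v <- sdb[f]^2 * (1 - rho[f]) / rho[f] - theta2[f]
      if (v < -1e-12) {
        stop("setting_offsets too large for target_icc of feature ", f)
      }
      sigw[f] <- sqrt(max(v, 0))
    }
  }

  g <- spec$setting_noise_scale
  g <- g / sqrt(mean(g^2))        # preserve the ICC target on average

  n_mal <- round(n * spec$malignant_fraction)
  label <- sample(rep(c("malignant", "benign"), c(n_mal, n - n_mal)))
  z <- as.numeric(label == "malignant")

  feat_names <- sprintf("f%04d", seq_len(p))
  subj <- matrix(rnorm(n * p), n, p) %*% diag(sdb, p) +
    outer(z, spec$class_effect)

  out <- vector("list", k)
  names(out) <- spec$settings
  for (s in seq_len(k)) {
    e <- matrix(rnorm(n * p), n, p) %*% diag(sigw * g[s], p)
    x <- subj + e
    if (!is.null(spec$setting_offsets)) {
      x <- sweep(x, 2, spec$setting_offsets[s, ], "+")
    }
    colnames(x) <- feat_names
    out[[s]] <- data.frame(
      nodule_id = sprintf("N%04d", seq_len(n)),
      setting_id = spec$settings[s],
      label = label,
      x,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  out
}
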