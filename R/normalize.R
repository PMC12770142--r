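#' Z-score normalization with training-derived parameters
#'
#' `zscore_fit()` learns per-feature means and standard deviations on the
#' training table; `zscore_apply()` standardises any table with those
#' parameters (validation and test data are always transformed with the
#' training parameters, never their own). Features that are constant on the
#' training data (sd = 0) or contain missing values are dropped with a
#' warning.
#'
#' @param train training feature table (data.frame with metadata columns
#'   `nodule_id`/`setting_id`/`label` and feature columns).
#' @param features feature names to normalise (default: all feature columns).
#' @return `zscore_fit()` returns an object of class `zscore_params` with
#'   fields `features`, `mean`, `sd` and `dropped`.
#' @export
zscore_fit <- function(train, features = feature_columns(train)) {
  if (!nrow(train)) stop("training table is empty")
  x <- as.matrix(train[, features, drop = FALSE])
  mu <- colMeans(x)
  sd_ <- apply(x, 2, sd)
  bad <- !is.finite(sd_) | sd_ == 0 | is.na(mu)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " constant or non-finite feature(s): ",
            paste(utils::head(features[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
  }
  structure(list(features = features[!bad], mean = mu[!bad], sd = sd_[!bad],
                 dropped = features[bad]),
            class = "zscore_params")
}

#' @param params a `zscore_params` object.
#' @param table feature table to transform.
#' @rdname zscore_fit
#' @return `zscore_apply()` returns `table` with the retained feature
#'   columns standardised (dropped features removed).
#' @export
zscore_apply <- function(params, table) {
  stopifnot(inherits(params, "zscore_params"))
  missing <- setdiff(params$features, colnames(table))
  if (length(missing)) {
    stop("table lacks feature(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  meta <- intersect(c("nodule_id", "setting_id", "label"), colnames(table))
  x <- as.matrix(table[, params$features, drop = FALSE])
  x <- sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
  cbind(table[, meta, drop = FALSE],
        as.data.frame(x, check.names = FALSE))
}
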