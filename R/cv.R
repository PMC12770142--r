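#' Stratified fivefold cross-validation over the seven stability models
#'
#' In each fold the training part is used to fit, per feature stratum,
#' the normalization parameters ([zscore_fit()]), the MRMR selection
#' ([mrmr_select()], inside the fold, leakage-safe) and the Firth model
#' ([firth_fit()]); the model is then evaluated on the fold's training and
#' validation parts and on every per-setting test table (always transformed
#' with the fold's training parameters). The seven models are FULL (all
#' features), S / U / I (stable, unstable, intermediate strata) and the
#' ablation combinations SI, SU, UI. Strata with no usable features are
#' skipped with an explicit report entry.
#'
#' @param train training-validation feature table (columns `nodule_id`,
#'   `label`, features); the fold split is stratified by label.
#' @param test_tables named list of per-setting feature tables evaluated as
#'   external test sets (same feature columns as `train`).
#' @param partition a [stability_partition()] over the feature universe.
#' @param n_folds number of folds (default 5).
#' @param n_select MRMR selection size (default 20).
#' @param seed fold-assignment seed.
#' @param reference test-setting id on which pairwise model comparisons
#'   (DeLong on AUC; McNemar on sensitivity and specificity) are run per
#'   fold.
#' @param models character vector of strata to fit.
#' @return object of class `cv_report`: list with `per_fold` (data.frame of
#'   metrics per fold x model x dataset), `means` (fivefold means),
#'   `comparisons` (pairwise tests), `skipped`, `folds`, `seed`.
#' @export
run_cv <- function(train, test_tables, partition,
                   n_folds = 5, n_select = 20, seed = 1L,
                   reference = reference_setting(),
                   models = c("FULL", "S", "U", "I", "SI", "SU", "UI")) {
  stopifnot(inherits(partition, "stability_partition"))
  y <- as_binary_label(train$label)
  feats <- feature_columns(train)
  for (nm in names(test_tables)) {
    if (!all(feats %in% colnames(test_tables[[nm]]))) {
      stop("test table ", nm, " lacks training feature columns")
    }
  }

  strata_features <- list(
    FULL = feats,
    S = intersect(feats, partition$stable),
    U = intersect(feats, partition$unstable),
    I = intersect(feats, partition$intermediate),
    SI = intersect(feats, c(partition$stable, partition$intermediate)),
    SU = intersect(feats, c(partition$stable, partition$unstable)),
    UI = intersect(feats, c(partition$unstable, partition$intermediate))
  )[models]

  set.seed(seed)
  folds <- stratified_folds(y, n_folds)

  rows <- list(); comps <- list(); skipped <- character(0)
  for (fold in seq_len(n_folds)) {
    tr <- train[folds != fold, , drop = FALSE]
    va <- train[folds == fold, , drop = FALSE]
    fold_scores <- list()   # per model: scores+predictions on reference set

    for (mod in names(strata_features)) {
      cand <- strata_features[[mod]]
      if (!length(cand)) {
        skipped <- c(skipped, sprintf("fold %d: stratum %s has no features",
                                      fold, mod))
        next
      }
      zs <- suppressWarnings(zscore_fit(tr, cand))
      if (!length(zs$features)) {
        skipped <- c(skipped, sprintf("fold %d: stratum %s all-constant",
                                      fold, mod))
        next
      }
      tr_z <- zscore_apply(zs, tr)
      sel <- suppressWarnings(
        mrmr_select(tr_z[, zs$features, drop = FALSE], tr$label,
                    m = min(n_select, length(zs$features))))
      fit <- suppressWarnings(
        firth_fit(tr_z[, sel$features, drop = FALSE], tr$label,
                  stratum = mod))

      eval_on <- function(tab, dataset) {
        tz <- zscore_apply(zs, tab)
        pr <- predict(fit, tz[, fit$features, drop = FALSE])
        cbind(data.frame(fold = fold, model = mod, dataset = dataset,
                         stringsAsFactors = FALSE),
              classification_metrics(tab$label, scores = pr$probability,
                                     predicted = pr$predicted))
      }
      rows[[length(rows) + 1L]] <- eval_on(tr, "train")
      rows[[length(rows) + 1L]] <- eval_on(va, "valid")
      for (nm in names(test_tables)) {
        rows[[length(rows) + 1L]] <-
          eval_on(test_tables[[nm]], paste0("test_", nm))
      }
      if (reference %in% names(test_tables)) {
        ref_tab <- test_tables[[reference]]
        tz <- zscore_apply(zs, ref_tab)
        pr <- predict(fit, tz[, fit$features, drop = FALSE])
        fold_scores[[mod]] <- list(scores = pr$probability,
                                   predicted = pr$predicted,
                                   y = as_binary_label(ref_tab$label))
      }
    }

    mods <- names(fold_scores)
    if (length(mods) > 1L) {
      for (i in seq_len(length(mods) - 1L)) for (j in (i + 1):length(mods)) {
        a <- fold_scores[[mods[i]]]; b <- fold_scores[[mods[j]]]
        dl <- delong_test(a$scores, b$scores, a$y)
        pos <- a$y == 1; neg <- !pos
        mc_se <- mcnemar_paired(a$predicted[pos] == 1, b$predicted[pos] == 1)
        mc_sp <- mcnemar_paired(a$predicted[neg] == 0, b$predicted[neg] == 0)
        comps[[length(comps) + 1L]] <- data.frame(
          fold = fold, model_a = mods[i], model_b = mods[j],
          dataset = paste0("test_", reference),
          delong_p = dl$p, auc_a = dl$auc_a, auc_b = dl$auc_b,
          mcnemar_sens_p = mc_se$p, mcnemar_spec_p = mc_sp$p,
          significant = dl$p < 0.05, stringsAsFactors = FALSE)
      }
    }
  }

  per_fold <- do.call(rbind, rows)
  rownames(per_fold) <- NULL
  means <- stats::aggregate(
    per_fold[, c("auc", "accuracy", "sensitivity", "specificity",
                 "gmean", "f1")],
    by = per_fold[, c("model", "dataset")], FUN = mean)
  structure(list(per_fold = per_fold, means = means,
                 comparisons = if (length(comps)) do.call(rbind, comps) else NULL,
                 skipped = skipped, folds = folds, seed = seed),
            class = "cv_report")
}

# Label-stratified fold assignment: each class is dealt round-robin after a
# random shuffle, so per-fold class ratios differ from the global ratio by
# at most one case.
stratified_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, %d models, %d dataset evaluations\n",
              max(x$per_fold$fold), length(unique(x$per_fold$model)),
              nrow(x$per_fold)))
  invisible(x)
}

#' Cross-setting generalizability summary
#'
#' Min, max and range of the fivefold-mean AUC of each model across the
#' per-setting external test sets; the model with the smallest range is the
#' most consistent under acquisition-parameter variation.
#'
#' @param report a [run_cv()] report.
#' @return data.frame with `model`, `auc_min`, `auc_max`, `auc_range`,
#'   `most_consistent`; invariant to test-set ordering.
#' @export
generalizability_summary <- function(report) {
  m <- report$means
  m <- m[grepl("^test_", m$dataset), ]
  if (!nrow(m)) stop("report contains no test-setting evaluations")
  out <- do.call(rbind, lapply(split(m, m$model), function(r) {
    data.frame(model = r$model[1], auc_min = min(r$auc),
               auc_max = max(r$auc), auc_range = max(r$auc) - min(r$auc),
               stringsAsFactors = FALSE)
  }))
  out$most_consistent <- out$auc_range == min(out$auc_range)
  rownames(out) <- NULL
  out
}
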