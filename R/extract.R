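#' Extraction configuration
#'
#' Bundles the preprocessing and filter-bank settings of the feature
#' extractor. With the defaults the extractor emits 644 features:
#' 14 shape + 18 first-order + 24 GLCM on the original image, plus
#' (18 + 24) on each of the 14 derived images (8 wavelet sub-bands, 3 LoG
#' scales, 3 algebraic maps). Shape is computed once, on the original mask.
#'
#' @param preprocess a [preprocess_spec()].
#' @param bank a [filter_bank_spec()], or `NULL` to skip derived images.
#' @return object of class `extract_config`.
#' @export
extract_config <- function(preprocess = preprocess_spec(),
                           bank = filter_bank_spec()) {
  structure(list(preprocess = preprocess, bank = bank),
            class = "extract_config")
}

#' Extract the full radiomic feature vector of one nodule
#'
#' Preprocesses the volume/mask pair (see [preprocess()]), computes shape,
#' first-order and GLCM features on the original image, then recomputes
#' first-order and GLCM features on every derived image of the filter bank.
#' Feature names follow the `<imagetype>_<class>_<feature>` convention,
#' e.g. `original_shape_Maximum3DDiameter`, `wavelet.LLH_glcm_Contrast`.
#'
#' @param v a [volume_grid()].
#' @param m a congruent [roi_mask()].
#' @param config an [extract_config()].
#' @return named numeric vector with a deterministic column order (644
#'   entries under the default configuration).
#' @export
extract_all <- function(v, m, config = extract_config()) {
  pp <- preprocess(v, m, config$preprocess)
  bw <- config$preprocess$bin_width

  out <- c(
    named_block("original_shape",
                shape_features(pp$mask, pp$volume$spacing)),
    named_block("original_firstorder",
                first_order_features(pp$volume, pp$mask, bw)),
    named_block("original_glcm",
                glcm_features(pp$volume, pp$mask, bw))
  )

  if (!is.null(config$bank)) {
    derived <- filter_images(pp$volume, config$bank)
    for (nm in names(derived)) {
      out <- c(out,
        named_block(paste0(nm, "_firstorder"),
                    first_order_features(derived[[nm]], pp$mask, bw)),
        named_block(paste0(nm, "_glcm"),
                    glcm_features(derived[[nm]], pp$mask, bw)))
    }
  }
  out
}

named_block <- function(prefix, x) {
  names(x) <- paste(prefix, names(x), sep = "_")
  x
}

#' Extract per-setting feature tables for a cohort
#'
#' Applies each acquisition setting to every nodule of a reference-geometry
#' cohort and extracts the full feature vector, yielding one feature table
#' per setting (the unit that flows into stability analysis and modelling).
#'
#' @param cohort list of [labeled_volume()]s at reference geometry.
#' @param settings data.frame of settings (default all ten, see
#'   [acquisition_settings()]).
#' @param config an [extract_config()].
#' @return named list (by setting id) of data.frames with columns
#'   `nodule_id`, `setting_id`, `label`, then the feature columns; identical
#'   column sets and row order across settings.
#' @export
extract_cohort <- function(cohort, settings = acquisition_settings(),
                           config = extract_config()) {
  out <- vector("list", nrow(settings))
  names(out) <- settings$setting_id
  for (s in seq_len(nrow(settings))) {
    rows <- lapply(cohort, function(lv) {
      lvs <- apply_setting(lv, settings[s, ])
      feats <- extract_all(lvs$volume, lvs$mask, config)
      cbind(data.frame(nodule_id = lv$nodule_id,
                       setting_id = settings$setting_id[s],
                       label = lv$label, stringsAsFactors = FALSE),
            as.data.frame(as.list(feats), check.names = FALSE))
    })
    out[[s]] <- do.call(rbind, rows)
    rownames(out[[s]]) <- NULL
  }
  out
}

#' Read/write feature tables
#'
#' CSV with UTF-8 encoding, `.` decimal separator and deterministic column
#' order: `nodule_id`, `setting_id`, `label`, then feature columns.
#'
#' @param table feature table data.frame.
#' @param path file path.
#' @return `read_feature_table()` returns the data.frame.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}

# Names of the feature columns of a feature table (everything after the
# metadata columns).
feature_columns <- function(table) {
  setdiff(colnames(table), c("nodule_id", "setting_id", "label"))
}
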