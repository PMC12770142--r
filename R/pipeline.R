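#' Validate and normalise a pipeline configuration
#'
#' Accepts a JSON file path or a list, checks it against the configuration
#' schema, fills defaults and returns a normalized `pipeline_config`.
#' Defaults: ICC thresholds 0.8 / 0.4, MRMR selection size 20, 5 folds,
#' panel mode, seed 1.
#'
#' @param config path to a JSON configuration file, or a named list.
#' @return object of class `pipeline_config`.
#' @export
#' @examples
#' validate_config(list(out_dir = tempdir(), n_train = 100))
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("configuration file does not exist: ", config)
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")

  defaults <- list(
    mode = "panel", seed = 1L,
    n_train = 400L, n_test = 200L, n_stability = 200L,
    n_nodules = 20L,
    icc_thresholds = list(stable = 0.8, unstable = 0.4),
    n_select = 20L, n_folds = 5L,
    settings = acquisition_settings()$setting_id,
    out_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)

  cfg$mode <- match.arg(cfg$mode, c("panel", "image"))
  thr <- cfg$icc_thresholds
  if (is.null(thr$stable) || is.null(thr$unstable) ||
      !(0 < thr$unstable && thr$unstable < thr$stable && thr$stable < 1)) {
    stop("icc_thresholds must satisfy 0 < unstable < stable < 1")
  }
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  if (!all(cfg$settings %in% acquisition_settings()$setting_id)) {
    stop("settings must be a subset of S1..S10")
  }
  if (!reference_setting() %in% cfg$settings) {
    stop("settings must include the reference ", reference_setting())
  }
  for (k in c("seed", "n_train", "n_test", "n_stability", "n_nodules",
              "n_select", "n_folds")) {
    cfg[[k]] <- as.integer(cfg[[k]])
    if (is.na(cfg[[k]]) || cfg[[k]] < (if (k == "seed") -2^31 else 1)) {
      stop("invalid value for ", k)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full stability-stratified modelling pipeline
#'
#' Executes simulation, (in image mode) feature extraction, ICC stability
#' stratification, per-group stability summaries with Venn intersections,
#' stratified model training under fivefold cross-validation, and
#' cross-setting generalizability reporting. All artifacts are written to
#' `config$out_dir` and checksummed in a run manifest; re-running with an
#' identical configuration reproduces identical checksums.
#'
#' Modes: `"panel"` simulates per-setting feature tables directly with a
#' known agreement structure ([simulate_stability_scenario()]); `"image"`
#' generates phantom nodule cohorts, applies the acquisition settings as
#' image operators and extracts radiomic features.
#'
#' @param config a [validate_config()] input (path, list or
#'   `pipeline_config`).
#' @return the run manifest (invisibly): list with `config`, `outputs`
#'   (file name to md5 checksum), `n_features`, `skipped`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) {
    message(sprintf("[radstab] %s: %s", stage, sprintf(...)))
  }

  thr <- cfg$icc_thresholds
  settings <- acquisition_settings()
  settings <- settings[settings$setting_id %in% cfg$settings, ]

  if (cfg$mode == "panel") {
    log_stage("simulate", "panel scenario (train %d, test %d, stability %d)",
              cfg$n_train, cfg$n_test, cfg$n_stability)
    sc <- simulate_stability_scenario(cfg$n_train, cfg$n_test,
                                      cfg$n_stability, seed = cfg$seed)
    train <- sc$train
    test_tables <- sc$test_tables[cfg$settings]
    stab_tables <- sc$stability_tables[cfg$settings]
  } else {
    log_stage("simulate", "phantom cohorts (%d nodules each)", cfg$n_nodules)
    cohorts <- lapply(1:3, function(i) {
      make_phantom_cohort(phantom_spec(cfg$n_nodules,
                                       seed = child_seed(cfg$seed, i, 31L)))
    })
    log_stage("extract", "features under %d settings", nrow(settings))
    ref_row <- settings[settings$setting_id == reference_setting(), ]
    train <- extract_cohort(cohorts[[1]], ref_row)[[1]]
    test_tables <- extract_cohort(cohorts[[2]], settings)
    stab_tables <- extract_cohort(cohorts[[3]], settings)
  }

  log_stage("stability", "ICC over %d features", length(feature_columns(train)))
  plan <- setting_group_plan()
  plan <- plan[vapply(plan, function(s) all(s %in% cfg$settings), TRUE)]
  records <- if (length(plan)) {
    stability_by_group(stab_tables, plan, thr$stable, thr$unstable)
  } else NULL
  partition <- stability_partition(stab_tables, thr$stable, thr$unstable)

  log_stage("model", "fivefold CV, %d-feature MRMR, Firth logistic",
            cfg$n_select)
  report <- run_cv(train, test_tables, partition,
                   n_folds = cfg$n_folds, n_select = cfg$n_select,
                   seed = child_seed(cfg$seed, 17L, 5L))
  gen <- generalizability_summary(report)

  # final per-stratum models refit on the full training cohort
  strata <- list(FULL = feature_columns(train),
                 S = partition$stable, U = partition$unstable,
                 I = partition$intermediate,
                 SI = c(partition$stable, partition$intermediate),
                 SU = c(partition$stable, partition$unstable),
                 UI = c(partition$unstable, partition$intermediate))
  outputs <- character(0)
  for (mod in names(strata)) {
    cand <- intersect(feature_columns(train), strata[[mod]])
    if (!length(cand)) next
    zs <- suppressWarnings(zscore_fit(train, cand))
    if (!length(zs$features)) next
    tz <- zscore_apply(zs, train)
    sel <- suppressWarnings(mrmr_select(tz[, zs$features, drop = FALSE],
                                        train$label,
                                        m = min(cfg$n_select, length(zs$features))))
    fit <- suppressWarnings(firth_fit(tz[, sel$features, drop = FALSE],
                                      train$label, stratum = mod))
    f <- file.path(cfg$out_dir, sprintf("model_%s.json", mod))
    write_firth_model(fit, f, normalization = zs)
    outputs <- c(outputs, f)
  }

  log_stage("report", "writing artifacts to %s", cfg$out_dir)
  wr <- function(obj, name, writer) {
    f <- file.path(cfg$out_dir, name)
    writer(obj, f)
    outputs <<- c(outputs, f)
  }
  wcsv <- function(obj, f) utils::write.csv(obj, f, row.names = FALSE)
  wjson <- function(obj, f) jsonlite::write_json(obj, f, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE)
  if (!is.null(records)) {
    wr(records, "icc_records.csv", wcsv)
    wr(stability_summary(records), "stability_summary.csv", wcsv)
    venn <- lapply(c(stable = "stable", unstable = "unstable"),
                   function(cat) as.list(intersect_categories(records, cat)$venn))
    wr(venn, "venn_counts.json", wjson)
  }
  wr(partition$records, "icc_partition.csv", wcsv)
  wr(report$per_fold, "cv_report.csv", wcsv)
  wr(report$means, "cv_means.csv", wcsv)
  if (!is.null(report$comparisons)) {
    wr(report$comparisons, "comparisons.csv", wcsv)
  }
  wr(gen, "generalizability.json", wjson)

  checksums <- tools::md5sum(outputs)
  names(checksums) <- basename(outputs)
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   n_features = length(feature_columns(train)),
                   skipped = report$skipped,
                   outputs = as.list(checksums))
  wjson(manifest, file.path(cfg$out_dir, "manifest.json"))
  log_stage("done", "%d artifacts", length(outputs) + 1L)
  invisible(manifest)
}

#' Serialize a Firth model (with its normalization) to JSON
#'
#' @param model a [firth_fit()] model.
#' @param path output JSON path.
#' @param normalization optional `zscore_params` stored with the model.
#' @return `read_firth_model()` returns the `firth_model`, with the
#'   normalization (if stored) in `$normalization`.
#' @export
write_firth_model <- function(model, path, normalization = NULL) {
  stopifnot(inherits(model, "firth_model"))
  obj <- list(
    stratum = model$stratum,
    features = model$features,
    coefficients = as.list(model$coefficients),
    convergence = list(iterations = model$iterations,
                       score_norm = model$score_norm,
                       converged = model$converged)
  )
  if (!is.null(normalization)) {
    obj$normalization <- list(features = normalization$features,
                              mean = as.list(normalization$mean),
                              sd = as.list(normalization$sd))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_firth_model
#' @export
read_firth_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(list(
    coefficients = unlist(obj$coefficients),
    features = obj$features,
    iterations = obj$convergence$iterations,
    score_norm = obj$convergence$score_norm,
    converged = obj$convergence$converged,
    penalty_weight = 1,
    stratum = obj$stratum
  ), class = "firth_model")
  if (!is.null(obj$normalization)) {
    model$normalization <- structure(list(
      features = obj$normalization$features,
      mean = unlist(obj$normalization$mean),
      sd = unlist(obj$normalization$sd),
      dropped = character(0)
    ), class = "zscore_params")
  }
  model
}
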