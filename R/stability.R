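#' Per-feature ICC stability records across setting groups
#'
#' For each named group of settings in `plan`, assembles the
#' subjects-by-settings ratings matrix of every feature from the
#' per-setting feature tables and computes ICC(A,1) plus its stability
#' category. Subjects are matched across settings by `nodule_id`; subjects
#' missing from any table of a group are removed (complete-case policy,
#' with the count recorded in the `n_dropped` attribute).
#'
#' @param tables named list of feature tables (one per setting id), sharing
#'   the same feature columns.
#' @param plan named list mapping group names to setting-id vectors, e.g.
#'   [setting_group_plan()].
#' @param stable,unstable category thresholds (see [categorize_icc()]).
#' @return data.frame with columns `feature`, `group`, `icc`, `category`,
#'   `degenerate`.
#' @export
stability_by_group <- function(tables, plan = setting_group_plan(),
                               stable = 0.8, unstable = 0.4) {
  feats <- feature_columns(tables[[1]])
  records <- list()
  dropped <- 0L
  for (g in names(plan)) {
    ids <- plan[[g]]
    missing <- setdiff(ids, names(tables))
    if (length(missing)) {
      stop("no feature table for setting(s): ", paste(missing, collapse = ", "))
    }
    sub <- tables[ids]
    common <- Reduce(intersect, lapply(sub, function(t) t$nodule_id))
    dropped <- dropped + (max(vapply(sub, nrow, 0L)) - length(common))
    aligned <- lapply(sub, function(t) t[match(common, t$nodule_id), feats])
    rec <- lapply(feats, function(f) {
      m <- do.call(cbind, lapply(aligned, `[[`, f))
      r <- icc_a1(m)
      data.frame(feature = f, group = g, icc = r$icc,
                 category = categorize_icc(r$icc, stable, unstable,
                                           r$degenerate),
                 degenerate = r$degenerate, stringsAsFactors = FALSE)
    })
    records[[g]] <- do.call(rbind, rec)
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Summarise category counts and fractions per group
#'
#' @param records output of [stability_by_group()].
#' @return data.frame with `group`, `category`, `count`, `fraction`.
#' @export
stability_summary <- function(records) {
  out <- do.call(rbind, lapply(split(records, records$group), function(r) {
    counts <- table(factor(r$category,
                           levels = c("stable", "intermediate", "unstable")))
    data.frame(group = r$group[1], category = names(counts),
               count = as.integer(counts),
               fraction = as.numeric(counts) / nrow(r),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-group intersection of a stability category (Venn analysis)
#'
#' Features falling in `category` under every group, plus the counts of all
#' `2^G - 1` Venn regions (features in exactly that combination of groups).
#' Region counts sum to the size of the union.
#'
#' @param records output of [stability_by_group()] covering all groups over
#'   the same feature universe.
#' @param category `"stable"`, `"intermediate"` or `"unstable"`.
#' @return list with `features` (character vector in the category under all
#'   groups) and `venn` (named integer vector; names are `+`-joined group
#'   combinations).
#' @export
intersect_categories <- function(records, category = "stable") {
  groups <- unique(records$group)
  sets <- lapply(groups, function(g) {
    r <- records[records$group == g, ]
    r$feature[r$category == category]
  })
  names(sets) <- groups
  universe <- lapply(groups, function(g) sort(records$feature[records$group == g]))
  if (length(unique(universe)) != 1L) {
    stop("groups do not cover the same feature universe")
  }

  membership <- vapply(sets, function(s) records$feature[!duplicated(records$feature)] %in% s,
                       logical(length(unique(records$feature))))
  feats <- records$feature[!duplicated(records$feature)]

  venn <- integer(0)
  for (mask in seq_len(2^length(groups) - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(seq_along(groups) - 1)))
    region <- rowSums(membership[, inc, drop = FALSE]) == sum(inc) &
      rowSums(membership[, !inc, drop = FALSE]) == 0
    venn[paste(groups[inc], collapse = "+")] <- sum(region)
  }
  list(features = feats[rowSums(membership) == length(groups)], venn = venn)
}

#' Stability partition for model strata
#'
#' Computes ICC(A,1) for every feature across all supplied settings jointly
#' and partitions the feature universe into the stable / intermediate /
#' unstable strata used to build the stability-stratified classifiers.
#'
#' @param tables named list of per-setting feature tables.
#' @param stable,unstable category thresholds.
#' @return object of class `stability_partition`: list with character
#'   vectors `stable`, `intermediate`, `unstable` (pairwise disjoint, union
#'   = all features) and the per-feature `records`.
#' @export
stability_partition <- function(tables, stable = 0.8, unstable = 0.4) {
  plan <- list(all = names(tables))
  # joint ICC over all settings: bypass the reference-containment check
  feats <- feature_columns(tables[[1]])
  common <- Reduce(intersect, lapply(tables, function(t) t$nodule_id))
  aligned <- lapply(tables, function(t) t[match(common, t$nodule_id), feats])
  rec <- do.call(rbind, lapply(feats, function(f) {
    m <- do.call(cbind, lapply(aligned, `[[`, f))
    r <- icc_a1(m)
    data.frame(feature = f, icc = r$icc,
               category = categorize_icc(r$icc, stable, unstable,
                                         r$degenerate),
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  }))
  structure(list(
    stable = rec$feature[rec$category == "stable"],
    intermediate = rec$feature[rec$category == "intermediate"],
    unstable = rec$feature[rec$category == "unstable"],
    records = rec
  ), class = "stability_partition")
}

#' @export
print.stability_partition <- function(x, ...) {
  cat(sprintf("<stability_partition> stable %d | intermediate %d | unstable %d\n",
              length(x$stable), length(x$intermediate), length(x$unstable)))
  invisible(x)
}
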