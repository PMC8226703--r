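#' Evaluate one top-k feature subset under cross-validation
#'
#' Restricts the matrix to the top `k` mRMR-ranked domains, trains the
#' random forest on each training fold, predicts the held-out fold, and
#' pools the confusion counts over all folds before computing SN, SP,
#' ACC and MCC once ("pooled" mode, the default). With
#' `pooling = "average"` the four measures are instead computed per
#' fold and averaged (folds with a degenerate denominator contribute 0
#' for that measure).
#'
#' @param matrix a [domain_matrix()].
#' @param ranking a `FeatureRanking` from [mrmr_rank()].
#' @param k subset size (uses ranking rows `1..k`).
#' @param cspec a [classifier_spec()].
#' @param vspec a [cv_spec()].
#' @param pooling `"pooled"` or `"average"`.
#' @return A `MetricSet` (see [compute_metrics()]).
#' @export
evaluate_subset <- function(matrix, ranking, k, cspec = classifier_spec(),
                            vspec = cv_spec(), pooling = c("pooled", "average")) {
  pooling <- match.arg(pooling)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(ranking)) stop("k exceeds ranking length (", nrow(ranking), ")", call. = FALSE)
  x <- as.matrix(matrix$incidence[, ranking$index[seq_len(k)], drop = FALSE])
  colnames(x) <- ranking$domain[seq_len(k)]
  folds <- make_folds(matrix$labels, vspec)
  seeds <- expand_seed(cspec$seed, vspec$k)
  cv_metrics(x, matrix$labels, folds, cspec, seeds, pooling)
}

# Cross-validate one feature view; returns a MetricSet.
cv_metrics <- function(x, y, folds, cspec, seeds, pooling = "pooled") {
  k_folds <- max(folds)
  counts <- list(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    forest <- fit_forest(x[!test, , drop = FALSE], y[!test], cspec, seeds[f])
    pred <- forest_predict(forest, x[test, , drop = FALSE])
    cc <- confusion_counts(y[test], pred)
    per_fold[[f]] <- cc
    counts <- Map(`+`, counts, cc)
  }
  if (pooling == "pooled") {
    compute_metrics(structure(counts, class = "ConfusionCounts"))
  } else {
    ms <- lapply(per_fold, compute_metrics)
    avg <- function(field) mean(vapply(ms, `[[`, 0, field))
    structure(list(SN = avg("SN"), SP = avg("SP"), ACC = avg("ACC"),
                   MCC = avg("MCC"),
                   degenerate = any(vapply(ms, `[[`, TRUE, "degenerate")),
                   counts = structure(counts, class = "ConfusionCounts")),
              class = "MetricSet")
  }
}

#' Incremental feature selection over nested top-k subsets
#'
#' Evaluates the nested subsets F1 = \{f1\}, F2 = \{f1, f2\}, ...,
#' F_Kmax of the mRMR feature list, each with the random-forest
#' classifier under k-fold cross-validation, and selects the optimum
#' subset size at the maximum MCC (smallest k on ties, for parsimony).
#' The same fold partition is reused for every subset size so the curve
#' reflects feature-set changes only.
#'
#' @inheritParams evaluate_subset
#' @param K_max largest subset size to evaluate (default 500).
#' @param verbose print progress every 10 subset sizes.
#' @return An object of class `IFSResult`: `curve` (data.frame with
#'   columns `k`, `SN`, `SP`, `ACC`, `MCC`), `optimum_k`,
#'   `optimum_features` (the ranking rows `1..optimum_k`),
#'   `optimum_metrics` (a `MetricSet`).
#' @export
ifs_search <- function(matrix, ranking, K_max = 500L, cspec = classifier_spec(),
                       vspec = cv_spec(), pooling = c("pooled", "average"),
                       verbose = FALSE) {
  pooling <- match.arg(pooling)
  K_max <- as.integer(K_max)
  if (is.na(K_max) || K_max < 1L) stop("K_max must be >= 1", call. = FALSE)
  if (K_max > nrow(ranking)) {
    stop("K_max exceeds ranking length (", nrow(ranking), ")", call. = FALSE)
  }
  x_all <- as.matrix(matrix$incidence[, ranking$index[seq_len(K_max)], drop = FALSE])
  colnames(x_all) <- ranking$domain[seq_len(K_max)]
  folds <- make_folds(matrix$labels, vspec)
  seeds <- base::matrix(expand_seed(cspec$seed, K_max * vspec$k),
                        nrow = K_max, ncol = vspec$k)

  curve <- data.frame(k = seq_len(K_max), SN = NA_real_, SP = NA_real_,
                      ACC = NA_real_, MCC = NA_real_)
  for (k in seq_len(K_max)) {
    ms <- cv_metrics(x_all[, seq_len(k), drop = FALSE], matrix$labels,
                     folds, cspec, seeds[k, ], pooling)
    curve$SN[k] <- ms$SN; curve$SP[k] <- ms$SP
    curve$ACC[k] <- ms$ACC; curve$MCC[k] <- ms$MCC
    if (verbose && k %% 10L == 0L) {
      message("IFS k = ", k, "/", K_max, "  MCC = ", sprintf("%.4f", ms$MCC))
    }
  }
  optimum_k <- which.max(curve$MCC)   # first maximum = smallest k on ties
  opt <- evaluate_optimum(curve, ranking, optimum_k)
  structure(c(opt, list(curve = curve, cspec = cspec, vspec = vspec)),
            class = "IFSResult")
}

evaluate_optimum <- function(curve, ranking, optimum_k) {
  row <- curve[optimum_k, ]
  list(
    optimum_k = optimum_k,
    optimum_features = ranking[seq_len(optimum_k), , drop = FALSE],
    optimum_metrics = structure(
      list(SN = row$SN, SP = row$SP, ACC = row$ACC, MCC = row$MCC,
           degenerate = FALSE, counts = NULL),
      class = "MetricSet")
  )
}

#' @export
print.IFSResult <- function(x, ...) {
  cat("IFS over k = 1..", nrow(x$curve), " (", x$vspec$k,
      "-fold CV, ", x$cspec$trees, " trees)\n", sep = "")
  cat("optimum k = ", x$optimum_k, "\n", sep = "")
  print(x$optimum_metrics)
  invisible(x)
}

#' Write an IFS curve / optimum subset as TSV
#'
#' `write_ifs_curve()` writes `k<TAB>SN<TAB>SP<TAB>ACC<TAB>MCC` with a
#' header; `write_optimum_features()` writes `rank<TAB>domain_id`.
#'
#' @param result an `IFSResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(result, path) {
  utils::write.table(result$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ifs_curve
#' @export
write_optimum_features <- function(result, path) {
  utils::write.table(result$optimum_features[, c("rank", "domain")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
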