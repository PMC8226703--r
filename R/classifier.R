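#' Random-forest classifier specification
#'
#' Configuration for the ensemble used inside [evaluate_subset()],
#' [ifs_search()] and [train_final()]: B decision trees, each grown on
#' a bootstrap sample of size n drawn with replacement, splitting on a
#' random candidate-feature subset at each node. Prediction is by
#' majority vote over the B trees, with vote ties broken toward the
#' negative class.
#'
#' @param trees B, the number of trees (default 100).
#' @param mtry per-node candidate-feature count; `NULL` (default)
#'   applies the rule `floor(log2(m)) + 1` for m features, capped to
#'   `[1, m]`.
#' @param seed integer seed for bootstrap and feature subsampling.
#' @return A list of class `ClassifierSpec`.
#' @export
classifier_spec <- function(trees = 100L, mtry = NULL, seed = 1L) {
  trees <- as.integer(trees)
  if (is.na(trees) || trees < 1L) stop("trees must be >= 1", call. = FALSE)
  structure(list(algorithm = "random_forest", trees = trees,
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 seed = as.integer(seed)),
            class = "ClassifierSpec")
}

resolve_mtry <- function(cspec, m) {
  mtry <- cspec$mtry %||% (floor(log2(m)) + 1L)
  max(1L, min(as.integer(mtry), m))
}

# Fit one probability forest on a dense 0/1 feature matrix.
fit_forest <- function(x, y, cspec, seed) {
  ranger::ranger(
    x = x, y = factor(y, levels = c(1L, 2L)),
    num.trees = cspec$trees,
    mtry = resolve_mtry(cspec, ncol(x)),
    probability = TRUE,
    replace = TRUE, sample.fraction = 1,
    num.threads = 1L,
    seed = seed
  )
}

# Majority vote: positive iff the fraction of trees voting for class 1
# exceeds 1/2; exact ties go to the negative class.
forest_predict <- function(forest, x) {
  prob <- stats::predict(forest, data = x, num.threads = 1L)$predictions
  ifelse(prob[, "1"] > 0.5, 1L, 2L)
}

#' Train the final classifier on selected domains
#'
#' Fits the random forest on the full matrix restricted to the given
#' domain features — typically the optimum subset identified by
#' [ifs_search()].
#'
#' @param matrix a [domain_matrix()].
#' @param features character vector of domain accessions (or a
#'   `FeatureRanking`, whose `domain` column is used) defining the
#'   model's feature space, in order.
#' @param cspec a [classifier_spec()].
#' @return An object of class `afp_model` holding the fitted forest,
#'   the ordered feature accessions and the specification. Serialize
#'   with [save_model()] / [load_model()].
#' @export
train_final <- function(matrix, features, cspec = classifier_spec()) {
  stopifnot(inherits(matrix, "DomainMatrix"))
  if (inherits(features, "FeatureRanking")) features <- features$domain
  features <- as.character(features)
  x <- dense_feature_view(matrix, features)
  forest <- fit_forest(x, matrix$labels, cspec, seed = expand_seed(cspec$seed, 1L))
  structure(list(format_version = 1L, features = features, cspec = cspec,
                 forest = forest),
            class = "afp_model")
}

# Dense n x length(features) view of a DomainMatrix, columns aligned by
# domain accession. Errors listing any accession the matrix lacks.
dense_feature_view <- function(matrix, features) {
  j <- match(features, colnames(matrix$incidence))
  if (anyNA(j)) {
    stop("matrix is missing model feature(s): ",
         paste(features[is.na(j)], collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(matrix$incidence[, j, drop = FALSE])
  colnames(x) <- features
  x
}

#' Predict AFP class for new proteins
#'
#' @param object an `afp_model` from [train_final()] or [load_model()].
#' @param matrix a [domain_matrix()] whose columns include every model
#'   feature (align by accession; a protein carrying none of the model
#'   domains is simply an all-zero feature vector). A missing feature
#'   column is an error naming the absent accessions.
#' @param ... unused.
#' @return Integer vector of predicted classes (1 = AFP, 2 = non-AFP),
#'   named by protein id. Deterministic for a given saved model.
#' @export
predict.afp_model <- function(object, matrix, ...) {
  stopifnot(inherits(matrix, "DomainMatrix"))
  x <- dense_feature_view(matrix, object$features)
  stats::setNames(forest_predict(object$forest, x), rownames(x))
}

#' Save / load a fitted model artifact
#'
#' The artifact is a versioned RDS serialization of the `afp_model`
#' (format version 1). Loading restores a model whose predictions are
#' bit-identical to the pre-save model.
#'
#' @param model an `afp_model`.
#' @param path file path for the artifact.
#' @return `path` (save) or the restored `afp_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "afp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "afp_model") || is.null(model$format_version)) {
    stop("not an afpdomains model artifact: ", path, call. = FALSE)
  }
  model
}
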