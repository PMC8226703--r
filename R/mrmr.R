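#' Rank domains by minimum redundancy, maximum relevance
#'
#' Greedy mRMR ranking (MID, the difference variant). At each step the
#' selected feature maximizes
#'
#'   score(f) = I(f, labels) - (1/|S|) * sum over s in S of I(f, s)
#'
#' where S is the already-selected set, I(.,.) is discrete plug-in
#' mutual information in bits, and the redundancy term is 0 while S is
#' empty (so the first selected feature is simply the most
#' label-relevant one). Ties — scores equal within 1e-9 — are broken by
#' lowest column index, making the ranking deterministic.
#'
#' Because every feature is binary, each MI evaluation reduces to a 2x2
#' contingency table whose counts come from sparse column sums and
#' column-column intersections, so ranking `top_n` features costs
#' O(ncol * top_n) MI evaluations rather than a full quadratic pass.
#'
#' @param matrix a [domain_matrix()].
#' @param top_n number of features to rank (default 500, the search
#'   depth used downstream by [ifs_search()]). Set to `ncol(matrix)`
#'   for a full-length ranking.
#' @return A `data.frame` of class `FeatureRanking` with columns
#'   `rank`, `index` (original column index), `domain` (accession),
#'   `score`, `relevance`, `redundancy` (all in bits; `score =
#'   relevance - redundancy` at the step the feature was picked).
#' @export
mrmr_rank <- function(matrix, top_n = 500L) {
  stopifnot(inherits(matrix, "DomainMatrix"))
  X <- matrix$incidence
  n <- nrow(X)
  m <- ncol(X)
  if (n < 1L || m < 1L) stop("matrix must have >= 1 row and >= 1 column", call. = FALSE)
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L || top_n > m) {
    stop("top_n must be in [1, ", m, "]", call. = FALSE)
  }
  y <- matrix$labels
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; relevance to the class is undefined",
         call. = FALSE)
  }

  nx1 <- Matrix::colSums(X)                       # per-domain presence count
  npos <- sum(y == 1L)
  n11 <- Matrix::colSums(X[y == 1L, , drop = FALSE])  # presence among positives
  relevance <- mi2x2_bits(n11, nx1, npos, n)

  selected <- integer(top_n)
  redsum <- numeric(m)       # sum of MI with already-selected features
  red_at_pick <- numeric(top_n)
  score_at_pick <- numeric(top_n)
  candidate <- rep(TRUE, m)

  for (t in seq_len(top_n)) {
    red <- if (t == 1L) 0 else redsum / (t - 1L)
    score <- relevance - red
    score[!candidate] <- -Inf
    best <- max(score)
    pick <- which(candidate & score >= best - 1e-9)[1L]
    selected[t] <- pick
    red_at_pick[t] <- if (t == 1L) 0 else redsum[pick] / (t - 1L)
    score_at_pick[t] <- relevance[pick] - red_at_pick[t]
    candidate[pick] <- FALSE
    if (t < top_n) {
      cooc <- as.numeric(Matrix::crossprod(X, X[, pick, drop = FALSE]))
      redsum <- redsum + mi2x2_bits(cooc, nx1, nx1[pick], n)
    }
  }

  out <- data.frame(
    rank = seq_len(top_n),
    index = selected,
    domain = colnames(X)[selected] %||% as.character(selected),
    score = score_at_pick,
    relevance = relevance[selected],
    redundancy = red_at_pick,
    stringsAsFactors = FALSE
  )
  class(out) <- c("FeatureRanking", "data.frame")
  out
}

#' Write / read an mRMR feature ranking as TSV
#'
#' The on-disk form is `rank<TAB>column_index<TAB>domain_id<TAB>score
#' <TAB>relevance<TAB>redundancy` with a header row — the artifact
#' analogue of a published mRMR feature list.
#'
#' @param ranking a `FeatureRanking` from [mrmr_rank()].
#' @param path output path.
#' @return `path` (write) or the `FeatureRanking` (read).
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("integer", "integer", "character",
                                          "numeric", "numeric", "numeric"),
                           stringsAsFactors = FALSE)
  class(out) <- c("FeatureRanking", "data.frame")
  out
}
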