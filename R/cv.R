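#' Cross-validation specification
#'
#' @param k number of folds (default 10).
#' @param stratified preserve class proportions within each fold
#'   (default `TRUE`; with ~4.5% positives, unstratified folds can end
#'   up with no positive sample at all).
#' @param seed integer seed for the fold assignment.
#' @return A list of class `CVSpec`.
#' @export
cv_spec <- function(k = 10L, stratified = TRUE, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  structure(list(k = k, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "CVSpec")
}

#' Assign samples to cross-validation folds
#'
#' Produces a partition of the samples into `spec$k` folds, a function
#' of the label vector and the seed only. Under stratification, each
#' class is shuffled separately and dealt round-robin, so per-fold
#' class proportions match the overall proportions within one sample.
#'
#' @param labels integer class vector (1 = positive, 2 = negative).
#' @param spec a [cv_spec()].
#' @return Integer vector of fold ids in `1..k`, one per sample; every
#'   sample appears in exactly one fold.
#' @export
make_folds <- function(labels, spec = cv_spec()) {
  n <- length(labels)
  k <- spec$k
  if (n < k) stop("need at least k samples (n = ", n, ", k = ", k, ")", call. = FALSE)
  fold <- integer(n)
  local_seed(spec$seed, {
    if (spec$stratified) {
      # deal fold ids round-robin, continuing the sequence across the
      # classes so overall fold sizes stay within one sample of equal
      deal <- rep_len(seq_len(k), n)
      start <- 0L
      for (cls in c(1L, 2L)) {
        idx <- which(labels == cls)
        if (length(idx) == 0L) {
          stop("stratified folds require >= 1 sample of class ", cls, call. = FALSE)
        }
        ids <- deal[start + seq_along(idx)]
        fold[idx] <- ids[sample.int(length(idx))]
        start <- start + length(idx)
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
  })
  fold
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  env <- parent.frame()
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval(substitute(code), envir = env)
}

# Deterministically expand one master seed into `n` sub-seeds (< 2^31),
# so fold assignment, bootstrap and feature subsampling draw from
# independent streams.
expand_seed <- function(seed, n) {
  out <- NULL
  local_seed(seed, out <- sample.int(.Machine$integer.max - 1L, n))
  out
}
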