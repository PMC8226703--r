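#' Specification for a synthetic planted-truth domain matrix
#'
#' Defines a class-conditional independent-Bernoulli generative model
#' that emulates the shape of a real protein-by-domain incidence
#' matrix — large, very sparse, with a small positive class — while
#' planting known structure for testing:
#'
#' * `d_inf` informative domains, present with probability `p_pos` in
#'   AFPs and `p_neg` in non-AFPs;
#' * `d_red` redundant domains, each a copy of one informative domain
#'   (assigned round-robin) with each entry flipped independently with
#'   probability `flip_prob`;
#' * `d_noise` label-independent noise domains, present with
#'   probability `q` in every protein.
#'
#' The defaults (200 positives, 4000 negatives, 10 informative + 20
#' redundant + 1000 noise domains) mirror a ~4.5%-positive, ~3%-dense
#' matrix at roughly quarter the row count and a thirteenth of the
#' column count of a genome-scale annotation set.
#'
#' @param n_pos,n_neg class sample counts.
#' @param d_inf number of informative domains.
#' @param p_pos,p_neg informative-domain presence probability in the
#'   positive / negative class (must differ).
#' @param d_red number of redundant domains.
#' @param flip_prob per-entry probability that a redundant domain
#'   disagrees with its source.
#' @param d_noise number of noise domains.
#' @param q noise-domain presence probability.
#' @param seed integer seed; generation is bit-reproducible under it.
#' @return A list of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 4000L,
                           d_inf = 10L, p_pos = 0.6, p_neg = 0.02,
                           d_red = 20L, flip_prob = 0.05,
                           d_noise = 1000L, q = 0.03, seed = 1L) {
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               d_inf = as.integer(d_inf), p_pos = p_pos, p_neg = p_neg,
               d_red = as.integer(d_red), flip_prob = flip_prob,
               d_noise = as.integer(d_noise), q = q, seed = as.integer(seed))
  probs <- c(p_pos, p_neg, flip_prob, q)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (spec$d_inf > 0L && p_pos == p_neg) {
    stop("p_pos must differ from p_neg for informative domains", call. = FALSE)
  }
  if (spec$n_pos < 1L || spec$n_neg < 1L) stop("need samples in both classes", call. = FALSE)
  if (spec$d_inf + spec$d_red + spec$d_noise < 1L) stop("need >= 1 domain", call. = FALSE)
  if (spec$d_red > 0L && spec$d_inf == 0L) {
    stop("redundant domains require >= 1 informative source", call. = FALSE)
  }
  structure(spec, class = "SyntheticSpec")
}

#' Generate a synthetic domain matrix with planted ground truth
#'
#' Draws a binary matrix under the model described in
#' [synthetic_spec()]. Rows that come out all-zero are redrawn (bounded
#' attempts) rather than removed, so the class counts stay exactly
#' `n_pos` / `n_neg`; an all-zero row violates the `DomainMatrix`
#' invariant. Column order is informative, then redundant, then noise;
#' accessions are `DINF####`, `DRED####`, `DNOI####` and rows
#' `P#####` (positives first).
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `matrix` (a [domain_matrix()]) and
#'   `truth` (class `SyntheticTruth`: column indices `informative`,
#'   `noise`, and a data.frame `redundant` with columns `column`,
#'   `source`) — the three index sets partition all columns.
#' @export
generate_matrix <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  n <- spec$n_pos + spec$n_neg
  m <- spec$d_inf + spec$d_red + spec$d_noise
  pos <- seq_len(spec$n_pos)
  inf_idx <- seq_len(spec$d_inf)
  red_idx <- spec$d_inf + seq_len(spec$d_red)
  noise_idx <- spec$d_inf + spec$d_red + seq_len(spec$d_noise)
  red_src <- if (spec$d_red > 0L) rep_len(inf_idx, spec$d_red) else integer()

  draw_rows <- function(rows) {
    # class-conditional draw of the full domain vector for given rows
    nr <- length(rows)
    block <- base::matrix(0L, nr, m)
    npos_r <- sum(rows <= spec$n_pos)
    if (spec$d_inf > 0L) {
      block[rows <= spec$n_pos, inf_idx] <-
        rbinom(npos_r * spec$d_inf, 1L, spec$p_pos)
      block[rows > spec$n_pos, inf_idx] <-
        rbinom((nr - npos_r) * spec$d_inf, 1L, spec$p_neg)
    }
    if (spec$d_red > 0L) {
      src <- block[, red_src, drop = FALSE]
      flip <- base::matrix(rbinom(nr * spec$d_red, 1L, spec$flip_prob), nr)
      block[, red_idx] <- abs(src - flip)
    }
    if (spec$d_noise > 0L) {
      block[, noise_idx] <- rbinom(nr * spec$d_noise, 1L, spec$q)
    }
    block
  }

  mat <- NULL
  local_seed(spec$seed, {
    mat <- draw_rows(seq_len(n))
    for (attempt in seq_len(100L)) {
      zero <- which(rowSums(mat) == 0L)
      if (length(zero) == 0L) break
      mat[zero, ] <- draw_rows(zero)
    }
    if (any(rowSums(mat) == 0L)) {
      stop("degenerate spec: could not produce all-nonzero rows after ",
           "bounded regeneration", call. = FALSE)
    }
  })

  dimnames(mat) <- list(
    sprintf("P%05d", seq_len(n)),
    c(sprintf("DINF%04d", inf_idx),
      if (spec$d_red > 0L) sprintf("DRED%04d", seq_len(spec$d_red)),
      if (spec$d_noise > 0L) sprintf("DNOI%04d", seq_len(spec$d_noise)))
  )
  labels <- c(rep(1L, spec$n_pos), rep(2L, spec$n_neg))
  truth <- structure(
    list(informative = inf_idx,
         redundant = data.frame(column = red_idx, source = red_src),
         noise = noise_idx),
    class = "SyntheticTruth")
  list(matrix = domain_matrix(mat, labels), truth = truth)
}
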