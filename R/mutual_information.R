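#' Plug-in mutual information between two discrete vectors
#'
#' Estimates I(x; y) = sum over level pairs of
#' p(a,b) * log2( p(a,b) / (p(a) p(b)) ) with the empirical ("plug-in")
#' probabilities count/n and the convention 0 * log(0) = 0. Values are
#' treated as categorical levels; the result is in bits, nonnegative up
#' to rounding, and symmetric in its arguments.
#'
#' @param x,y equal-length vectors of discrete values.
#' @return Mutual information in bits.
#' @export
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1)) # = H(x) = 1 bit
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) == 0L) stop("zero-length input", call. = FALSE)
  mi_from_counts(table(x, y))
}

# MI in bits from a joint contingency table of counts.
mi_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  pxy <- outer(px, py)
  keep <- counts > 0
  sum(p[keep] * log2(p[keep] / pxy[keep]))
}

# Vectorized MI (bits) for pairs of binary {0,1} vectors given their
# sufficient counts: n11 = #(x=1 & y=1), nx1 = #(x=1), ny1 = #(y=1),
# total n. Same plug-in estimator as mi_from_counts on the 2x2 table.
mi2x2_bits <- function(n11, nx1, ny1, n) {
  k <- max(length(n11), length(nx1), length(ny1))
  n11 <- rep_len(as.numeric(n11), k)
  nx1 <- rep_len(as.numeric(nx1), k)
  ny1 <- rep_len(as.numeric(ny1), k)
  n10 <- nx1 - n11
  n01 <- ny1 - n11
  n00 <- n - nx1 - n01
  nx0 <- n - nx1
  ny0 <- n - ny1
  term <- function(nab, na, nb) {
    out <- numeric(k)
    ok <- nab > 0
    out[ok] <- (nab[ok] / n) * log2((nab[ok] * n) / (na[ok] * nb[ok]))
    out
  }
  term(n11, nx1, ny1) + term(n10, nx1, ny0) +
    term(n01, nx0, ny1) + term(n00, nx0, ny0)
}

# Shannon entropy (bits) of a discrete vector, plug-in estimate.
entropy_bits <- function(x) {
  p <- tabulate(as.integer(factor(x)))
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}
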