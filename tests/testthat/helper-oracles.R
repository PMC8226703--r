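# Independent oracles used to cross-check the package implementations.
# These are deliberately written the "slow obvious way" and share no
# code with the package internals.

# MI in bits via the entropy identity I(x;y) = H(x) + H(y) - H(x,y).
oracle_mi <- function(x, y) {
  H <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log2(p))
  }
  H(x) + H(y) - H(paste(x, y, sep = "\r"))
}

# MI in bits from a joint count table, direct double loop.
oracle_mi_counts <- function(tab) {
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  acc <- 0
  for (a in seq_len(nrow(tab))) {
    for (b in seq_len(ncol(tab))) {
      if (tab[a, b] > 0) {
        pab <- tab[a, b] / n
        acc <- acc + pab * log2(pab / (px[a] * py[b]))
      }
    }
  }
  acc
}

# Naive quadratic greedy mRMR (MID variant) on a dense 0/1 matrix.
# Ties within 1e-9 resolved by lowest column index, as documented.
oracle_mrmr <- function(X, y, top_n) {
  m <- ncol(X)
  relevance <- vapply(seq_len(m), function(j) oracle_mi(X[, j], y), 0)
  selected <- integer(0)
  for (t in seq_len(top_n)) {
    cand <- setdiff(seq_len(m), selected)
    score <- vapply(cand, function(j) {
      red <- if (length(selected) == 0L) 0 else {
        mean(vapply(selected, function(s) oracle_mi(X[, j], X[, s]), 0))
      }
      relevance[j] - red
    }, 0)
    best <- max(score)
    selected <- c(selected, cand[score >= best - 1e-9][1L])
  }
  selected
}

# Direct evaluation of the four measures from a 2x2 confusion table.
oracle_metrics <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  div0 <- function(num, den) if (den == 0) 0 else num / den
  list(
    SN = div0(tp, tp + fn),
    SP = div0(tn, tn + fp),
    ACC = (tp + tn) / (tp + fp + fn + tn),
    MCC = div0(tp * tn - fp * fn,
               sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
  )
}

# Random DomainMatrix with both classes present and no all-zero row.
random_dm <- function(n, m, density = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * m, 1, density), n, m,
              dimnames = list(sprintf("P%03d", 1:n), sprintf("IPR%06d", 1:m)))
  X[rowSums(X) == 0, sample(m, 1)] <- 1L
  y <- sample(c(1L, 2L), n, replace = TRUE, prob = c(0.3, 0.7))
  if (length(unique(y)) < 2L) y[1:2] <- c(1L, 2L)
  domain_matrix(X, y)
}

# Tiny strongly-separable matrix: column 1 equals the class indicator,
# remaining columns are noise.
separable_dm <- function(n_pos = 12, n_neg = 28, m_noise = 5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(1L, n_pos), rep(2L, n_neg))
  X <- cbind(as.integer(y == 1L),
             matrix(rbinom(n * m_noise, 1, 0.3), n, m_noise))
  X[rowSums(X) == 0, 2] <- 1L
  dimnames(X) <- list(sprintf("P%03d", 1:n), sprintf("IPR%06d", 1:(m_noise + 1)))
  domain_matrix(X, y)
}
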