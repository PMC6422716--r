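# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra route (negated scaled inverse precision) so
# agreement is evidence, not tautology.

# Partial correlation of each pair given all remaining variables, computed
# from regression residuals.
oracle_partial_correlations <- function(X) {
  p <- ncol(X)
  P <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others) == 0) {
        r <- stats::cor(X[, i], X[, j])
      } else {
        Z <- cbind(1, X[, others, drop = FALSE])
        ri <- stats::lm.fit(Z, X[, i])$residuals
        rj <- stats::lm.fit(Z, X[, j])$residuals
        r <- stats::cor(ri, rj)
      }
      P[i, j] <- P[j, i] <- r
    }
  }
  P
}

# Kruskal-Wallis H by the textbook rank formula (no ties assumed).
oracle_kw_h <- function(values, groups) {
  N <- length(values)
  R <- rank(values)
  sizes <- table(groups)
  sums <- tapply(R, groups, sum)
  12 / (N * (N + 1)) * sum(sums^2 / sizes) - 3 * (N + 1)
}

# small planted two-block model shared by several tests
two_block_model <- function(strength = 0.3) {
  make_planted_precision(
    paste0("v", 1:9),
    list(paste0("v", 1:4), paste0("v", 5:9)),
    within_strength = strength
  )
}

# random signed weighted graph on p nodes (symmetric, zero diagonal)
random_signed_graph <- function(p, seed, density = 0.6) {
  withr::with_seed(seed, {
    A <- matrix(0, p, p)
    m <- p * (p - 1) / 2
    A[upper.tri(A)] <- stats::runif(m, -1, 1) * stats::rbinom(m, 1, density)
    A + t(A)
  })
}
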