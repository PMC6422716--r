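#' Solve the graphical LASSO at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_(i!=j) |Theta_ij|`
#' by block coordinate descent; the L1 penalty is applied to off-diagonal
#' entries only, so partial-correlation magnitudes are not distorted by
#' diagonal shrinkage. Zeros in the returned precision estimate are exact
#' (soft-thresholding), which is what makes the selected network sparse.
#'
#' @param S p x p sample correlation (or covariance) matrix: symmetric, unit
#'   diagonal expected for correlation input, positive semi-definite.
#' @param lambda penalty strength, `>= 0`; either a scalar or a full p x p
#'   matrix of per-entry penalties. A 0/`Inf` penalty matrix yields the
#'   maximum-likelihood estimate constrained to a zero pattern (used to
#'   refit a selected support without shrinkage).
#' @param warm_start optional list with `w` and `beta` from a previous solve
#'   at a nearby penalty (used internally along the penalty path).
#' @param tol convergence tolerance on the maximum absolute change of the
#'   working covariance, relative to the mean absolute off-diagonal of `S`.
#' @param max_iter maximum outer sweeps.
#' @return List with `theta` (precision estimate, exact zero pattern,
#'   symmetric), `w` (estimated covariance), `beta` (regression coefficients,
#'   used for warm starts), `iterations`, `converged`.
#' @export
glasso_solve <- function(S, lambda, warm_start = NULL, tol = 1e-6,
                         max_iter = 500) {
  check_square(S, "S")
  p <- nrow(S)
  if (length(lambda) == 1) {
    if (lambda < 0) abort("`lambda` must be >= 0.")
    Lambda <- matrix(lambda, p, p)
  } else {
    if (!is.matrix(lambda) || any(dim(lambda) != p) || any(lambda < 0)) {
      abort("`lambda` must be a scalar or a nonnegative p x p matrix.")
    }
    Lambda <- lambda
  }
  warm <- !is.null(warm_start)
  W0 <- if (warm) warm_start$w else matrix(0, p, p)
  B0 <- if (warm) warm_start$beta else matrix(0, p, p)
  fit <- .glasso_cd(S, Lambda, W0, B0, warm, tol, max_iter, max_iter)
  if (!fit$converged) {
    abort(sprintf(
      "Graphical LASSO did not converge at lambda = %.6g within %d sweeps.",
      max(Lambda), max_iter
    ))
  }
  Theta <- fit$theta
  # symmetrize: zero only where both directions thresholded to zero
  zero <- Theta == 0 & t(Theta) == 0
  Theta <- (Theta + t(Theta)) / 2
  Theta[zero] <- 0
  dimnames(Theta) <- dimnames(S)
  fit$theta <- Theta
  fit
}

#' Convert a precision matrix to partial correlations
#'
#' `rho_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` for `i != j`, diagonal
#' set to 0; the zero pattern of the precision matrix is preserved, so the
#' sparse precision estimate and the reported network have the same edges.
#'
#' @param Theta symmetric precision matrix with strictly positive diagonal.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
#' @examples
#' precision_to_partial(matrix(c(2, -1, -1, 2), 2)) # off-diagonal 0.5
precision_to_partial <- function(Theta) {
  check_square(Theta, "Theta")
  d <- diag(Theta)
  if (any(d <= 0)) abort("`Theta` must have a strictly positive diagonal.")
  W <- -Theta / sqrt(outer(d, d))
  diag(W) <- 0
  dimnames(W) <- dimnames(Theta)
  W
}

#' Bayesian Information Criterion for a Gaussian graphical model
#'
#' `BIC = -2 * l + E * log(n)` with Gaussian log-likelihood
#' `l = (n/2) * (log det Theta - tr(S Theta))` (additive constant omitted:
#' only BIC differences matter for selection) and model size `E` = number of
#' nonzero off-diagonal entries in the upper triangle of `Theta` (edges).
#' This is the extended BIC with gamma = 0.
#'
#' @param Theta precision estimate (positive definite).
#' @param S sample correlation matrix.
#' @param n sample size (must exceed p).
#' @param gamma extended-BIC tuning; 0 (the default) is plain BIC. Positive
#'   values add `4 * gamma * E * log(p)`.
#' @return Scalar BIC value.
#' @export
bic_score <- function(Theta, S, n, gamma = 0) {
  p <- nrow(S)
  if (n <= p) abort("`n` must exceed the number of variables.")
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) abort("`Theta` must be positive definite.")
  loglik <- (n / 2) * (as.numeric(ld$modulus) - sum(S * Theta))
  E <- sum(Theta[upper.tri(Theta)] != 0)
  -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
}

#' Logarithmic penalty grid for the graphical LASSO path
#'
#' `n_lambda` log-spaced penalties descending from
#' `lambda_max = max_(i!=j) |S_ij|` (the smallest penalty giving an empty
#' network) down to `ratio * lambda_max`.
#'
#' @param S sample correlation matrix.
#' @param n_lambda number of grid points (default 100).
#' @param ratio smallest penalty as a fraction of `lambda_max` (default 0.01).
#' @return Numeric vector of strictly decreasing penalties. If all
#'   off-diagonals of `S` are zero the grid degenerates to `0` with a
#'   warning.
#' @export
lambda_grid <- function(S, n_lambda = 100, ratio = 0.01) {
  check_square(S, "S")
  off <- abs(S[upper.tri(S)])
  lambda_max <- if (length(off) > 0) max(off) else 0
  if (lambda_max == 0) {
    warn("All off-diagonal correlations are zero; penalty grid is {0}.")
    return(0)
  }
  if (n_lambda == 1) return(lambda_max)
  exp(seq(log(lambda_max), log(ratio * lambda_max), length.out = n_lambda))
}

#' Estimate a sparse partial-correlation network
#'
#' Fits the graphical LASSO over a descending penalty grid (warm starts
#' along the path), scores every candidate model with [bic_score()], selects
#' the minimizer (ties within 1e-9 broken toward the larger penalty, i.e.
#' the sparser model) and returns its partial-correlation matrix.
#' Estimation always runs on the Pearson correlation matrix, so the network
#' is invariant to rescaling of the raw scores.
#'
#' Two refinements, both on by default, sharpen the selected model:
#' `threshold = TRUE` zeroes selected edges whose penalized partial
#' correlation falls below the sparsity-consistency bound
#' `sqrt(log(p * (p - 1) / 2) / n)` — without it the BIC-selected penalty
#' admits spurious small edges at large n, because un-shrinking true edges
#' keeps improving the penalized likelihood and drags the selected penalty
#' below the noise level. `refit = TRUE` then replaces the shrunk edge
#' weights by the maximum-likelihood fit constrained to the surviving edge
#' set, removing the L1 bias from the reported partial correlations (the
#' bootstrap intervals inherit the de-biased scale). Setting both to
#' `FALSE` gives the raw penalized convention.
#'
#' @param scores a `score_matrix` (from [split_complete_cases()] or
#'   [as_score_matrix()]), or a plain numeric matrix/data frame of complete
#'   scores.
#' @param n_lambda,lambda_min_ratio penalty-grid controls, see
#'   [lambda_grid()].
#' @param gamma extended-BIC tuning passed to [bic_score()]; default 0 (BIC).
#' @param threshold zero selected edges below the consistency bound
#'   (default `TRUE`).
#' @param refit report the support-constrained MLE instead of the shrunk
#'   fit (default `TRUE`).
#' @param lambdas optional explicit penalty grid overriding the automatic
#'   one (values in descending order; a single value pins the penalty, e.g.
#'   `lambdas = 0` for the unpenalized fit).
#' @param tol convergence tolerance for [glasso_solve()].
#' @return An object of class `ggm_fit`: list with `W` (p x p partial
#'   correlations, zero diagonal, exact zeros off the selected support),
#'   `theta`, `labels`, `lambda_selected`, `n`, `group_name` and `path` (a
#'   tibble with one row per penalty: `lambda`, `loglik`, `edges`, `bic`,
#'   `selected`).
#' @export
estimate_network <- function(scores, n_lambda = 100, lambda_min_ratio = 0.01,
                             gamma = 0, threshold = TRUE, refit = TRUE,
                             lambdas = NULL, tol = 1e-6) {
  if (!inherits(scores, "score_matrix")) scores <- as_score_matrix(scores)
  S <- scores$correlation
  n <- scores$n
  if (is.null(lambdas)) lambdas <- lambda_grid(S, n_lambda, lambda_min_ratio)
  p <- nrow(S)
  loglik <- bics <- numeric(length(lambdas))
  edges <- integer(length(lambdas))
  thetas <- vector("list", length(lambdas))
  warm <- NULL
  for (i in seq_along(lambdas)) {
    fit <- glasso_solve(S, lambdas[i], warm_start = warm, tol = tol)
    warm <- fit
    Theta <- fit$theta
    thetas[[i]] <- Theta
    ld <- determinant(Theta, logarithm = TRUE)
    loglik[i] <- (n / 2) * (as.numeric(ld$modulus) - sum(S * Theta))
    edges[i] <- sum(Theta[upper.tri(Theta)] != 0)
    bics[i] <- -2 * loglik[i] + edges[i] * log(n) +
      4 * gamma * edges[i] * log(p)
  }
  if (is.unsorted(edges)) {
    warn("Edge count is not monotone along the penalty path (harmless path nonmonotonicity).",
         class = "cognet_path_warning")
  }
  # first strict improvement wins: grid is descending, so ties (within 1e-9)
  # resolve toward the larger penalty / sparser model
  best <- 1
  for (i in seq_along(bics)) {
    if (bics[i] < bics[best] - 1e-9) best <- i
  }
  Theta <- thetas[[best]]
  W <- precision_to_partial(Theta)
  if (threshold) {
    tau <- sqrt(log(p * (p - 1) / 2) / n)
    W[abs(W) < tau] <- 0
  }
  if (refit) {
    support <- W != 0
    diag(support) <- TRUE
    if (!all(support)) {
      Lam <- matrix(Inf, p, p)
      Lam[support] <- 0
      Theta <- glasso_solve(S, Lam, tol = tol)$theta
    } else {
      Theta <- glasso_solve(S, 0, tol = tol)$theta
    }
    W <- precision_to_partial(Theta)
  } else if (threshold) {
    # keep the penalized weights but impose the thresholded zero pattern
    Theta[W == 0 & row(Theta) != col(Theta)] <- 0
  }
  dimnames(W) <- list(scores$labels, scores$labels)
  structure(
    list(
      W = W,
      theta = Theta,
      labels = scores$labels,
      lambda_selected = lambdas[best],
      n = n,
      group_name = scores$group_name,
      path = tibble::tibble(
        lambda = lambdas, loglik = loglik, edges = edges,
        bic = bics, selected = seq_along(lambdas) == best
      )
    ),
    class = "ggm_fit"
  )
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf(
    "<ggm_fit> %s: %d nodes, %d edges, lambda = %.4g (BIC-selected), n = %d\n",
    x$group_name, length(x$labels),
    sum(x$W[upper.tri(x$W)] != 0), x$lambda_selected, x$n
  ))
  invisible(x)
}

#' Tidy the edges of a fitted network
#'
#' @param x a `ggm_fit`.
#' @param all if `FALSE` (default) only nonzero edges are returned.
#' @param ... unused.
#' @return Tibble with `from`, `to`, `weight` (penalized partial
#'   correlation) and `group`.
#' @export
tidy.ggm_fit <- function(x, all = FALSE, ...) {
  out <- edge_table(x$W, x$labels)
  if (!all) out <- out[out$weight != 0, ]
  out$group <- x$group_name
  out
}

#' One-row summary of a fitted network
#'
#' @param x a `ggm_fit`.
#' @param ... unused.
#' @return Tibble with group, n, p, selected penalty, edge count and BIC.
#' @export
glance.ggm_fit <- function(x, ...) {
  sel <- x$path[x$path$selected, ]
  tibble::tibble(
    group = x$group_name,
    n = x$n,
    p = length(x$labels),
    lambda = x$lambda_selected,
    edges = sum(x$W[upper.tri(x$W)] != 0),
    bic = sel$bic
  )
}

#' Export a network as a labeled CSV matrix
#'
#' @param fit a `ggm_fit` (or bare weighted matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(fit, path) {
  W <- if (inherits(fit, "ggm_fit")) fit$W else fit
  df <- tibble::as_tibble(as.data.frame(W, check.names = FALSE))
  df <- dplyr::bind_cols(tibble::tibble(node = matrix_labels(W)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Export a network as GraphML (weighted, undirected)
#'
#' @inheritParams write_network_csv
#' @export
write_network_graphml <- function(fit, path) {
  W <- if (inherits(fit, "ggm_fit")) fit$W else fit
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a penalty path as CSV
#'
#' @param fit a `ggm_fit`.
#' @param path output file.
#' @export
write_path_csv <- function(fit, path) {
  readr::write_csv(fit$path, path)
  invisible(path)
}
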