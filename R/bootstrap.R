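#' Bootstrap the full network-estimation pipeline
#'
#' Draws `B` n-out-of-n resamples (rows with replacement), re-runs the whole
#' estimation on each — correlation matrix, graphical-LASSO path, BIC
#' penalty re-selection, and (optionally) best-of-restarts Louvain community
#' detection — and returns the ensemble of networks and partitions. Each
#' bootstrap replicate uses an RNG seed derived deterministically from
#' `(seed, b)`, so runs are reproducible and order-independent.
#'
#' Degenerate resamples (any constant column, under which the correlation
#' matrix is undefined) are redrawn with a logged count; more than 5%
#' redraws aborts, since that signals data unsuited to the bootstrap.
#'
#' @param scores a `score_matrix`.
#' @param B number of bootstrap samples (default 1000).
#' @param restarts Louvain restarts inside each replicate (default 100).
#' @param seed integer seed.
#' @param communities if `FALSE`, skip community detection (edge/centrality
#'   intervals only).
#' @param mode modularity mode for community detection, see [louvain()].
#' @param n_lambda,lambda_min_ratio,gamma,threshold,refit passed to [estimate_network()].
#' @return A `boot_ensemble`: list with `group_name`, `B`, `networks`
#'   (p x p x B array of partial-correlation matrices), `memberships`
#'   (B x p integer matrix or `NULL`), `Q` (per-replicate modularity or
#'   `NULL`), `labels`, `seed`, `redraws`.
#' @export
bootstrap_pipeline <- function(scores, B = 1000L, restarts = 100L, seed = 1L,
                               communities = TRUE,
                               mode = c("signed", "absolute"),
                               n_lambda = 100, lambda_min_ratio = 0.01,
                               gamma = 0, threshold = TRUE, refit = TRUE) {
  stopifnot(inherits(scores, "score_matrix"), B >= 1)
  mode <- match.arg(mode)
  n <- scores$n
  p <- length(scores$labels)
  networks <- array(0, dim = c(p, p, B),
                    dimnames = list(scores$labels, scores$labels, NULL))
  memberships <- if (communities) {
    matrix(NA_integer_, B, p, dimnames = list(NULL, scores$labels))
  } else NULL
  Qs <- if (communities) numeric(B) else NULL
  redraws <- 0L
  max_redraws <- max(1, ceiling(0.05 * B))
  for (b in seq_len(B)) {
    attempt <- 0L
    repeat {
      idx <- withr::with_seed(
        derive_seed(seed, b * 131L + attempt),
        sample.int(n, n, replace = TRUE)
      )
      Xb <- scores$X[idx, , drop = FALSE]
      if (all(apply(Xb, 2, function(col) length(unique(col)) > 1))) break
      redraws <- redraws + 1L
      attempt <- attempt + 1L
      if (redraws > max_redraws) {
        abort(sprintf(
          "More than 5%% of bootstrap resamples were degenerate (%d redraws).",
          redraws
        ))
      }
    }
    # path nonmonotonicity warnings are per-fit diagnostics; across
    # thousands of resamples they are noise, so they are muffled here
    fit <- withCallingHandlers(
      estimate_network(
        new_score_matrix(Xb, scores$labels, scores$group_name),
        n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
        gamma = gamma, threshold = threshold, refit = refit
      ),
      cognet_path_warning = function(w) invokeRestart("muffleWarning")
    )
    networks[, , b] <- fit$W
    if (communities) {
      part <- best_partition(fit$W, restarts = restarts,
                             seed = derive_seed(seed, b * 131L + 97L),
                             mode = mode)
      memberships[b, ] <- unname(part$assignment[scores$labels])
      Qs[b] <- part$Q
    }
  }
  if (redraws > 0) {
    inform(sprintf("Bootstrap: %d degenerate resample(s) redrawn.", redraws))
  }
  structure(
    list(group_name = scores$group_name, B = as.integer(B),
         networks = networks, memberships = memberships, Q = Qs,
         labels = scores$labels, seed = as.integer(seed),
         redraws = redraws),
    class = "boot_ensemble"
  )
}

#' @export
print.boot_ensemble <- function(x, ...) {
  cat(sprintf("<boot_ensemble> %s: B = %d, %d nodes%s\n",
              x$group_name, x$B, length(x$labels),
              if (is.null(x$memberships)) "" else ", with partitions"))
  invisible(x)
}

#' Percentile confidence interval from bootstrap statistics
#'
#' Empirical 2.5th and 97.5th percentiles (for the default 95% level) with
#' linear interpolation between order statistics (R quantile type 7). A
#' warning is issued below 40 replicates, where the tails are poorly
#' resolved.
#'
#' @param values numeric vector of bootstrap statistics.
#' @param point optional full-sample point estimate carried alongside.
#' @param level confidence level (default 0.95).
#' @return Tibble with `point`, `lo`, `hi`.
#' @export
percentile_interval <- function(values, point = NA_real_, level = 0.95) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (length(values) < 40) {
    warn("Fewer than 40 bootstrap values; percentile interval is unstable.")
  }
  a <- (1 - level) / 2
  q <- unname(quantile(values, c(a, 1 - a), type = 7, names = FALSE))
  tibble::tibble(point = point, lo = q[1], hi = q[2])
}

#' Confidence-interval nonoverlap rule
#'
#' `TRUE` iff the two closed intervals are disjoint (`a.hi < b.lo` or
#' `b.hi < a.lo`); touching endpoints count as overlap. Vectorized over
#' rows when given tibbles with `lo`/`hi` columns.
#'
#' @param a,b intervals: tibbles/lists with elements `lo` and `hi`.
#' @return Logical vector.
#' @export
ci_nonoverlap <- function(a, b) {
  if (any(a$lo > a$hi) || any(b$lo > b$hi)) {
    abort("Intervals must satisfy lo <= hi.")
  }
  a$hi < b$lo | b$hi < a$lo
}

#' Edge-weight confidence intervals from a bootstrap ensemble
#'
#' @param ensemble a `boot_ensemble`.
#' @param fit optional full-sample `ggm_fit` supplying the point estimates.
#' @param level confidence level.
#' @return Tidy tibble: `from`, `to`, `point`, `lo`, `hi`, `group`.
#' @export
edge_ci <- function(ensemble, fit = NULL, level = 0.95) {
  labels <- ensemble$labels
  p <- length(labels)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    vals <- ensemble$networks[i, j, ]
    point <- if (is.null(fit)) NA_real_ else fit$W[i, j]
    ci <- suppressWarnings(percentile_interval(vals, point, level))
    dplyr::mutate(ci, from = labels[i], to = labels[j],
                  group = ensemble$group_name, .before = 1)
  })
}

#' Node-strength confidence intervals from a bootstrap ensemble
#'
#' @inheritParams edge_ci
#' @return Tidy tibble: `node`, `point`, `lo`, `hi`, `group`.
#' @export
strength_ci <- function(ensemble, fit = NULL, level = 0.95) {
  labels <- ensemble$labels
  strengths <- apply(abs(ensemble$networks), 3, rowSums)
  # strengths: p x B
  purrr::map_dfr(seq_along(labels), function(i) {
    point <- if (is.null(fit)) {
      NA_real_
    } else {
      node_strength(fit)$strength[i]
    }
    ci <- suppressWarnings(
      percentile_interval(strengths[i, ], point, level)
    )
    dplyr::mutate(ci, node = labels[i], group = ensemble$group_name,
                  .before = 1)
  })
}

#' Co-assignment matrix of a bootstrap ensemble
#'
#' @param ensemble a `boot_ensemble` run with `communities = TRUE`.
#' @return A `coassignment` object, see [coassignment()].
#' @export
ensemble_coassignment <- function(ensemble) {
  if (is.null(ensemble$memberships)) {
    abort("Ensemble was run with communities = FALSE.")
  }
  coassignment(ensemble$memberships)
}

#' Persist a bootstrap ensemble as CSVs plus a JSON manifest
#'
#' Writes one CSV per bootstrap network into `dir/networks/`, the membership
#' matrix, and `manifest.json` (group, B, seed, redraw count).
#'
#' @param ensemble a `boot_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(file.path(dir, "networks"), recursive = TRUE,
             showWarnings = FALSE)
  for (b in seq_len(ensemble$B)) {
    write_network_csv(
      ensemble$networks[, , b],
      file.path(dir, "networks", sprintf("network_%04d.csv", b))
    )
  }
  if (!is.null(ensemble$memberships)) {
    readr::write_csv(
      tibble::as_tibble(as.data.frame(ensemble$memberships,
                                      check.names = FALSE)),
      file.path(dir, "memberships.csv")
    )
  }
  jsonlite::write_json(
    list(group = ensemble$group_name, B = ensemble$B, seed = ensemble$seed,
         redraws = ensemble$redraws, labels = ensemble$labels),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
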