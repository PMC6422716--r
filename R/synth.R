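#' Canonical node labels of the executive-function / behavior battery
#'
#' The nine analysis variables: verbal list-learning total and delayed recall
#' (`15T`, `15R`), Digit-Span backwards (`DSB`), letter fluency (`FLU`), the
#' Stroop interference ratio (`STR`), the Trail-Making B/A ratio (`TMT`), and
#' the three FrSBe behavioral subscales Apathy (`FAP`), Disinhibition (`FID`)
#' and Executive Dysfunction (`FEF`).
#'
#' @return Character vector of length 9.
#' @export
cognitive_nodes <- function() {
  c("15T", "15R", "DSB", "FLU", "STR", "TMT", "FAP", "FID", "FEF")
}

# internal: normalize a blocks argument (list of label vectors, or a named
# node -> block vector) into a named character node -> block map
normalize_blocks <- function(labels, blocks) {
  if (is.list(blocks)) {
    nm <- names(blocks) %||% paste0("B", seq_along(blocks))
    nm[nm == ""] <- paste0("B", which(nm == ""))
    map <- setNames(rep(nm, lengths(blocks)), unlist(blocks))
  } else {
    map <- setNames(as.character(blocks), names(blocks))
  }
  missing <- setdiff(labels, names(map))
  if (length(missing) > 0) {
    abort(paste0("`blocks` must cover all labels; missing: ",
                 paste(missing, collapse = ", ")))
  }
  map[labels]
}

# internal: ring (size >= 3), single edge (size 2) or nothing (size 1)
# within a block; keeps each row diagonally dominant for strengths < 0.5
block_ring_edges <- function(members, strength) {
  k <- length(members)
  if (k < 2 || strength == 0) {
    return(tibble::tibble(from = character(), to = character(),
                          partial = double()))
  }
  if (k == 2) {
    return(tibble::tibble(from = members[1], to = members[2],
                          partial = strength))
  }
  tibble::tibble(
    from = members,
    to = members[c(2:k, 1)],
    partial = strength
  )
}

# internal: build a unit-diagonal precision matrix whose implied partial
# correlations equal `edges$partial` exactly. Positive definiteness is
# attempted by diagonal loading (add eps*I with doubling eps, re-imposing the
# target partials); if the target pattern/strengths are infeasible the
# construction fails loudly.
precision_from_edges <- function(labels, edges, max_load_iter = 30L) {
  p <- length(labels)
  Theta <- diag(p)
  dimnames(Theta) <- list(labels, labels)
  if (nrow(edges) > 0) {
    if (any(abs(edges$partial) >= 1)) {
      abort("Planted partial correlations must have |value| < 1.")
    }
    for (r in seq_len(nrow(edges))) {
      i <- match(edges$from[r], labels)
      j <- match(edges$to[r], labels)
      if (is.na(i) || is.na(j) || i == j) {
        abort("Edge endpoints must be two distinct labels.")
      }
      Theta[i, j] <- Theta[j, i] <- -edges$partial[r]
    }
  }
  target <- Theta # unit-diagonal pattern; off-diagonal = -partial
  eps <- 1e-8
  for (iter in seq_len(max_load_iter)) {
    ev <- eigen(Theta, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-8) {
      d <- diag(Theta)
      Dinv <- diag(1 / sqrt(d), p)
      Theta <- Dinv %*% Theta %*% Dinv # partials invariant to this rescale
      dimnames(Theta) <- list(labels, labels)
      Theta <- (Theta + t(Theta)) / 2
      return(Theta)
    }
    # load the diagonal, then restore the planted partial correlations
    diag(Theta) <- diag(Theta) + eps
    eps <- eps * 2
    d <- diag(Theta)
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        rho <- -target[i, j] # planted partial correlation
        Theta[i, j] <- Theta[j, i] <- -rho * sqrt(d[i] * d[j])
      }
    }
  }
  abort(paste0(
    "Planted precision matrix is not positive definite after diagonal ",
    "loading; the requested block pattern/strengths are infeasible."
  ))
}

#' Construct a planted sparse precision model
#'
#' Builds the ground-truth Gaussian graphical model that the synthetic cohorts
#' are drawn from: a unit-diagonal precision matrix whose nonzero off-diagonal
#' pattern places each block's members on a ring (a single edge for 2-node
#' blocks), with the implied partial correlation of every planted edge exactly
#' `within_strength`. Optional bridges at `between_strength` connect the first
#' members of consecutive blocks.
#'
#' Ring topology keeps every row diagonally dominant whenever
#' `within_strength < 0.5`, which guarantees positive definiteness without
#' distorting the planted partial correlations. Infeasible requests (e.g. a
#' triangle at strength 0.5, which is exactly singular) fail with an explicit
#' construction error.
#'
#' @param labels character vector of node names.
#' @param blocks either a list of character vectors (one per block) or a named
#'   vector mapping node to block id; must cover all labels.
#' @param within_strength planted partial correlation of within-block edges,
#'   `|value| < 1`.
#' @param between_strength planted partial correlation of the optional bridge
#'   edges between consecutive blocks (default 0: disconnected blocks).
#' @param group_name label attached to the model.
#' @return An object of class `planted_model`: list with `labels`,
#'   `precision`, `partial` (implied partial-correlation matrix),
#'   `communities` (node -> block map) and `group_name`.
#' @export
#' @examples
#' m <- make_planted_precision(letters[1:4], list(c("a", "b"), c("c", "d")), 0.4)
#' m$partial["a", "b"] # 0.4
make_planted_precision <- function(labels, blocks, within_strength,
                                   between_strength = 0,
                                   group_name = "synthetic") {
  stopifnot(abs(within_strength) < 1, abs(between_strength) < 1)
  map <- normalize_blocks(labels, blocks)
  block_ids <- unique(map)
  edges <- purrr::map_dfr(block_ids, function(b) {
    block_ring_edges(labels[map == b], within_strength)
  })
  if (between_strength != 0 && length(block_ids) > 1) {
    firsts <- purrr::map_chr(block_ids, function(b) labels[map == b][1])
    edges <- dplyr::bind_rows(edges, tibble::tibble(
      from = firsts[-length(firsts)],
      to = firsts[-1],
      partial = between_strength
    ))
  }
  new_planted_model(labels, edges, map, group_name)
}

# internal constructor shared by make_planted_precision and study_models
new_planted_model <- function(labels, edges, communities, group_name) {
  Theta <- precision_from_edges(labels, edges)
  structure(
    list(
      labels = labels,
      precision = Theta,
      partial = precision_to_partial(Theta),
      communities = communities,
      group_name = group_name
    ),
    class = "planted_model"
  )
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("<planted_model> %s: %d nodes, %d planted edges, %d blocks\n",
              x$group_name, length(x$labels),
              sum(x$partial[upper.tri(x$partial)] != 0),
              length(unique(x$communities))))
  invisible(x)
}

#' @export
tidy.planted_model <- function(x, ...) {
  dplyr::filter(edge_table(x$partial, x$labels), .data$weight != 0)
}

#' Default score scales for the nine-node battery
#'
#' Plausible raw-score means and standard deviations (e.g. list-learning total
#' around 45 words, ratio scores near 2). They only set the location/scale of
#' the synthetic scores: network estimation standardizes, so they exercise the
#' preprocessing path without affecting the estimated networks.
#'
#' @return A list with numeric vectors `mean` and `sd`, named by node.
#' @export
default_score_scales <- function() {
  nodes <- cognitive_nodes()
  list(
    mean = setNames(c(45, 9, 6, 35, 1.8, 2.2, 35, 30, 40), nodes),
    sd = setNames(c(10, 3, 2, 10, 0.4, 0.6, 8, 8, 9), nodes)
  )
}

#' Specify a multi-group synthetic cohort
#'
#' @param models named list of [planted models][make_planted_precision], one
#'   per group; all must share the same node labels.
#' @param n named integer vector of group sizes (same names as `models`);
#'   each must be at least p + 1.
#' @param seed integer RNG seed; sampling is fully deterministic given it.
#' @param mean_vector,sd_vector per-node means and standard deviations in
#'   score units (defaults from [default_score_scales()] where labels match,
#'   otherwise 0/1). Identical across groups, mirroring a design with no group
#'   mean differences.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(models, n, seed, mean_vector = NULL, sd_vector = NULL) {
  stopifnot(is.list(models), length(models) >= 1)
  nm <- names(models)
  if (is.null(nm) || any(nm == "")) abort("`models` must be a named list.")
  labels <- models[[1]]$labels
  for (m in models) {
    if (!identical(m$labels, labels)) {
      abort("All group models must share the same node labels.")
    }
  }
  if (is.null(names(n))) names(n) <- nm
  n <- n[nm]
  if (any(is.na(n)) || any(n < length(labels) + 1)) {
    abort("Each group needs n >= p + 1 subjects.")
  }
  scales <- default_score_scales()
  if (is.null(mean_vector)) {
    mean_vector <- ifelse(labels %in% names(scales$mean),
                          scales$mean[labels], 0)
    names(mean_vector) <- labels
  }
  if (is.null(sd_vector)) {
    sd_vector <- ifelse(labels %in% names(scales$sd), scales$sd[labels], 1)
    names(sd_vector) <- labels
  }
  if (any(sd_vector <= 0)) abort("All sd_vector entries must be > 0.")
  structure(
    list(models = models, n = n, seed = as.integer(seed),
         mean_vector = mean_vector[labels], sd_vector = sd_vector[labels],
         labels = labels),
    class = "cohort_spec"
  )
}

#' Sample a synthetic cohort from planted Gaussian models
#'
#' Draws, for each group, `n` subjects from the multivariate Gaussian whose
#' covariance is the inverse of the group's planted precision matrix
#' (standardized to a correlation matrix), rescaled to the per-node standard
#' deviations and shifted by the per-node means. Group means are identical by
#' construction. Deterministic under `spec$seed`; each group uses its own
#' derived RNG stream.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group` (factor with the
#'   groups in spec order) and one column per node.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- spec$labels
  groups <- names(spec$models)
  rows <- purrr::imap(spec$models, function(model, g) {
    gi <- match(g, groups)
    Sigma <- solve(model$precision)
    Sigma <- stats::cov2cor(Sigma)
    D <- diag(spec$sd_vector, length(labels))
    Sigma <- D %*% Sigma %*% D
    n <- spec$n[[g]]
    X <- withr::with_seed(
      derive_seed(spec$seed, gi),
      MASS::mvrnorm(n, mu = spec$mean_vector, Sigma = Sigma)
    )
    colnames(X) <- labels
    out <- tibble::as_tibble(as.data.frame(X, check.names = FALSE))
    dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g
      ),
      out
    )
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = groups)
  out
}

#' Planted models emulating the three study groups
#'
#' Three nine-node Gaussian graphical models sharing a strong verbal-memory
#' edge (15T-15R, partial correlation 0.6) and a working-memory/fluency edge
#' (DSB-FLU, 0.4) but differing in block structure:
#' * `control`: blocks \{15T,15R\}, \{DSB,FLU\}, and a five-node
#'   attention/behavior ring \{STR,TMT,FAP,FID,FEF\} at 0.3;
#' * `nonfrontal`: memory and executive pairs as above, \{STR,TMT\} at 0.3 and
#'   a behavioral triangle \{FAP,FID,FEF\} at 0.3;
#' * `frontal`: one ring merging memory with working memory and fluency
#'   (15R-15T 0.6, 15T-DSB 0.3, DSB-FLU 0.4, FLU-15R 0.3) plus the five-node
#'   ring at 0.3 — the "dysexecutive" coupling of memory and executive nodes.
#'
#' @return Named list of three `planted_model` objects.
#' @export
study_models <- function() {
  nodes <- cognitive_nodes()
  ring5 <- block_ring_edges(c("STR", "TMT", "FAP", "FID", "FEF"), 0.3)
  memory <- tibble::tibble(from = "15T", to = "15R", partial = 0.6)
  exec <- tibble::tibble(from = "DSB", to = "FLU", partial = 0.4)

  control_edges <- dplyr::bind_rows(memory, exec, ring5)
  control_comm <- setNames(
    c("M", "M", "E", "E", "A", "A", "A", "A", "A"), nodes)

  nonfrontal_edges <- dplyr::bind_rows(
    memory, exec,
    tibble::tibble(from = "STR", to = "TMT", partial = 0.3),
    block_ring_edges(c("FAP", "FID", "FEF"), 0.3)
  )
  nonfrontal_comm <- setNames(
    c("M", "M", "E", "E", "S", "S", "B", "B", "B"), nodes)

  frontal_edges <- dplyr::bind_rows(
    tibble::tibble(
      from = c("15R", "15T", "DSB", "FLU"),
      to = c("15T", "DSB", "FLU", "15R"),
      partial = c(0.6, 0.3, 0.4, 0.3)
    ),
    ring5
  )
  frontal_comm <- setNames(
    c("ME", "ME", "ME", "ME", "A", "A", "A", "A", "A"), nodes)

  list(
    control = new_planted_model(nodes, control_edges, control_comm, "control"),
    nonfrontal = new_planted_model(nodes, nonfrontal_edges, nonfrontal_comm,
                                   "nonfrontal"),
    frontal = new_planted_model(nodes, frontal_edges, frontal_comm, "frontal")
  )
}

#' Synthetic cohort emulating the three-group study
#'
#' Samples a cohort from [study_models()] with the study's group sizes
#' (controls 67, non-frontal lesions 66, frontal lesions 61) and identical
#' score means across groups, so between-group mean tests are null by
#' construction while the conditional-dependence structure differs.
#'
#' @param seed integer RNG seed.
#' @param n named group sizes; defaults to the study sizes. Override to
#'   inflate n for consistency checks.
#' @return A tibble as returned by [sample_cohort()].
#' @export
make_study_fixture <- function(seed,
                               n = c(control = 67, nonfrontal = 66,
                                     frontal = 61)) {
  sample_cohort(cohort_spec(study_models(), n = n, seed = seed))
}

#' Write a cohort table to CSV
#'
#' One row per subject, columns `subject_id, group, <nodes>`.
#'
#' @param cohort tibble from [sample_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Write planted ground truth to JSON
#'
#' Persists, per group, the precision matrix, implied partial correlations
#' and block map, together with the sampling seed — everything needed to
#' score structure recovery later.
#'
#' @param spec a [cohort_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(spec, path) {
  payload <- list(
    seed = spec$seed,
    n = as.list(spec$n),
    labels = spec$labels,
    groups = purrr::map(spec$models, function(m) {
      list(
        precision = m$precision,
        partial = m$partial,
        communities = as.list(m$communities)
      )
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
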