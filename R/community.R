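#' Node strength (weighted degree centrality)
#'
#' Strength of a node is the sum of the absolute weights of its incident
#' edges — how strongly the node is connected to the rest of the network,
#' regardless of edge sign.
#'
#' @param x a `ggm_fit` or a symmetric weighted adjacency matrix with zero
#'   diagonal.
#' @return Tibble with `node` and `strength` (and `group` for a `ggm_fit`).
#' @export
node_strength <- function(x) {
  W <- if (inherits(x, "ggm_fit")) x$W else x
  check_square(W, "W")
  labels <- matrix_labels(W)
  A <- abs(W)
  diag(A) <- 0
  out <- tibble::tibble(node = labels, strength = unname(rowSums(A)))
  if (inherits(x, "ggm_fit")) out$group <- x$group_name
  out
}

# internal: split a signed weighted matrix into positive/negative parts
split_signs <- function(W) {
  diagless <- W
  list(pos = pmax(diagless, 0), neg = pmax(-diagless, 0))
}

# internal: Newman weighted modularity of one nonnegative matrix,
# ordered-pair convention (self-loop pairs included in the null model)
newman_q <- function(A, comm) {
  s <- sum(A)
  if (s == 0) return(0)
  k <- rowSums(A)
  same <- outer(comm, comm, "==")
  sum(((A - outer(k, k) / s) / s)[same])
}

# internal: align an assignment (named or positional) to matrix labels,
# returning an integer community vector
align_assignment <- function(assignment, labels) {
  if (inherits(assignment, "community_partition")) {
    assignment <- assignment$assignment
  }
  if (!is.null(names(assignment))) {
    missing <- setdiff(labels, names(assignment))
    if (length(missing) > 0) {
      abort(paste0("Assignment missing nodes: ", paste(missing, collapse = ", ")))
    }
    assignment <- assignment[labels]
  } else if (length(assignment) != length(labels)) {
    abort("Assignment length must match the number of nodes.")
  }
  as.integer(factor(assignment, levels = unique(assignment)))
}

#' Signed weighted modularity Q
#'
#' For a signed network with positive part `W+` and (absolute) negative part
#' `W-`, `Q = Q+ - (s- / (s+ + s-)) * Q-`, where `Q+` and `Q-` are Newman
#' weighted modularities of the two subnetworks and `s+`, `s-` their total
#' weights (asymmetric signed modularity of Rubinov & Sporns: positive
#' within-community weight is rewarded at full rate, negative within-community
#' weight penalized proportionally to its share). With no negative edges this
#' is exactly the plain Newman weighted Q. An all-zero network has Q = 0.
#'
#' @param W symmetric weighted adjacency matrix (zero diagonal at the top
#'   level; aggregated self-loops are handled internally).
#' @param assignment node -> community map: named vector, positional vector
#'   or a `community_partition`.
#' @return Scalar modularity.
#' @export
modularity_q <- function(W, assignment) {
  check_square(W, "W")
  labels <- matrix_labels(W)
  comm <- align_assignment(assignment, labels)
  parts <- split_signs(W)
  sp <- sum(parts$pos)
  sn <- sum(parts$neg)
  if (sp + sn == 0) return(0)
  qp <- newman_q(parts$pos, comm)
  qn <- newman_q(parts$neg, comm)
  qp - (sn / (sp + sn)) * qn
}

# internal: one Louvain local-moving pass + aggregation loop on the
# positive/negative parts of the current (possibly aggregated) graph.
# Returns the membership of the current meta-nodes.
louvain_level <- function(Wp, Wn, sp, sn, order) {
  m <- nrow(Wp)
  comm <- seq_len(m)
  kp <- rowSums(Wp)
  kn <- rowSums(Wn)
  alpha <- if (sp + sn > 0) sn / (sp + sn) else 0
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- comm[i]
      comm[i] <- NA_integer_
      # candidates are all current communities: in the signed objective a
      # profitable move may target a community the node has no edge to
      # (the negative-part null model rewards it)
      cands <- unique(comm[!is.na(comm)])
      # gain of joining community c (relative to staying as a singleton)
      best_gain <- 0
      best_c <- 0L # 0 = stay alone
      for (cc in cands) {
        members <- which(comm == cc)
        gain <- 0
        if (sp > 0) {
          gain <- gain +
            2 * (sum(Wp[i, members]) - kp[i] * sum(kp[members]) / sp) / sp
        }
        if (sn > 0) {
          gain <- gain -
            alpha * 2 * (sum(Wn[i, members]) - kn[i] * sum(kn[members]) / sn) / sn
        }
        if (gain > best_gain + 1e-12) {
          best_gain <- gain
          best_c <- cc
        }
      }
      new_c <- if (best_c == 0L) {
        # stay (or become) a singleton; reuse the old id when it is free so
        # an unchanged singleton is not counted as a move
        if (!ci %in% comm[-i]) ci else
          setdiff(seq_len(m), comm[-i][!is.na(comm[-i])])[1]
      } else best_c
      comm[i] <- new_c
      if (!identical(new_c, ci)) {
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(comm = as.integer(factor(comm, levels = unique(comm))),
       moved = moved_any)
}

# internal: aggregate a weighted matrix by community (self-loops keep the
# within-community weight so modularity is preserved across levels)
aggregate_by <- function(A, comm) {
  Bm <- outer(comm, sort(unique(comm)), "==") * 1
  t(Bm) %*% A %*% Bm
}

#' Louvain community detection on a weighted signed graph
#'
#' Greedy two-phase Louvain maximizing [modularity_q()]: local moving of
#' nodes (visit order shuffled by `seed`) followed by graph aggregation,
#' repeated until no move improves Q. Negative edges enter through the
#' asymmetric signed objective; with `mode = "absolute"` detection runs on
#' `|W|` instead. Isolated nodes end as singletons.
#'
#' @param W symmetric weighted adjacency matrix, zero diagonal.
#' @param seed integer seed for the node visit order.
#' @param mode `"signed"` (default) or `"absolute"`.
#' @return A `community_partition`: list with `assignment` (named integer
#'   vector, communities numbered by first node appearance), `Q`, `labels`.
#' @export
louvain <- function(W, seed = 1L, mode = c("signed", "absolute")) {
  check_square(W, "W")
  mode <- match.arg(mode)
  labels <- matrix_labels(W)
  W0 <- if (mode == "absolute") abs(W) else W
  p <- nrow(W0)
  parts <- split_signs(W0)
  sp <- sum(parts$pos)
  sn <- sum(parts$neg)
  membership <- seq_len(p)
  if (sp + sn > 0) {
    Wp <- parts$pos
    Wn <- parts$neg
    level <- 0L
    repeat {
      level <- level + 1L
      order <- withr::with_seed(derive_seed(seed, level),
                                sample.int(nrow(Wp)))
      res <- louvain_level(Wp, Wn, sp, sn, order)
      if (!res$moved) break
      # every completed level strictly increases Q, so this terminates
      membership <- res$comm[membership]
      Wp <- aggregate_by(Wp, res$comm)
      Wn <- aggregate_by(Wn, res$comm)
    }
  }
  new_community_partition(membership, labels, W0)
}

# internal: canonicalize + package a partition
new_community_partition <- function(membership, labels, W_for_q) {
  canon <- as.integer(factor(membership, levels = unique(membership)))
  names(canon) <- labels
  structure(
    list(assignment = canon,
         Q = modularity_q(W_for_q, canon),
         labels = labels),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes in %d communities, Q = %.4f\n",
              length(x$assignment), length(unique(x$assignment)), x$Q))
  invisible(x)
}

#' @export
tidy.community_partition <- function(x, ...) {
  tibble::tibble(node = x$labels,
                 community = unname(x$assignment),
                 Q = x$Q)
}

#' Best-of-restarts Louvain partition
#'
#' Runs [louvain()] `restarts` times with restart-specific derived seeds and
#' returns the solution with the highest modularity Q; exact Q ties are
#' broken by the lexicographically smallest canonical assignment so the
#' result is deterministic.
#'
#' @inheritParams louvain
#' @param restarts number of restarts (default 100).
#' @return A `community_partition`.
#' @export
best_partition <- function(W, restarts = 100L, seed = 1L,
                           mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  if (restarts < 1) abort("`restarts` must be >= 1.")
  best <- NULL
  for (r in seq_len(restarts)) {
    cand <- louvain(W, seed = derive_seed(seed, r), mode = mode)
    if (is.null(best) || cand$Q > best$Q + 1e-12 ||
        (abs(cand$Q - best$Q) <= 1e-12 &&
         paste(cand$assignment, collapse = ",") <
         paste(best$assignment, collapse = ","))) {
      best <- cand
    }
  }
  best
}

# internal: all set partitions of n items as membership vectors
# (restricted growth strings); Bell(6) = 203, Bell(8) = 4140
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(m + 1)) {
      recurse(c(prefix, v), max(m, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

#' Exhaustive modularity optimum (oracle for small graphs)
#'
#' Enumerates every set partition of the nodes (feasible up to ~9 nodes) and
#' returns the partition maximizing [modularity_q()]. Intended as the ground
#' truth against which the Louvain heuristic is validated.
#'
#' @inheritParams louvain
#' @return A `community_partition` attaining the global maximum Q.
#' @export
modularity_optimum <- function(W, mode = c("signed", "absolute")) {
  check_square(W, "W")
  mode <- match.arg(mode)
  p <- nrow(W)
  if (p > 9) abort("Exhaustive search is limited to 9 nodes.")
  W0 <- if (mode == "absolute") abs(W) else W
  labels <- matrix_labels(W0)
  parts <- set_partitions(p)
  qs <- vapply(parts, function(cm) modularity_q(W0, cm), numeric(1))
  new_community_partition(parts[[which.max(qs)]], labels, W0)
}

#' Bootstrap co-assignment matrix
#'
#' For every pair of nodes, the proportion of bootstrap partitions in which
#' the two nodes fall in the same community; the diagonal is 1 by
#' definition. Invariant to community relabeling within each partition.
#'
#' @param partitions list of `community_partition` objects (or a B x p
#'   integer membership matrix with node labels as column names), all over
#'   the same node set.
#' @return A `coassignment` object: list with `labels`, `P` (p x p
#'   proportion matrix) and `B_effective`.
#' @export
coassignment <- function(partitions) {
  if (is.matrix(partitions)) {
    M <- partitions
    labels <- colnames(M) %||% paste0("V", seq_len(ncol(M)))
  } else {
    if (length(partitions) < 1) abort("Need at least one partition.")
    labels <- partitions[[1]]$labels
    M <- t(vapply(partitions, function(pt) {
      if (!identical(pt$labels, labels)) {
        abort("All partitions must cover the same node set.")
      }
      unname(pt$assignment[labels])
    }, integer(length(labels))))
  }
  B <- nrow(M)
  p <- ncol(M)
  P <- matrix(0, p, p, dimnames = list(labels, labels))
  for (b in seq_len(B)) {
    P <- P + outer(M[b, ], M[b, ], "==")
  }
  P <- P / B
  diag(P) <- 1
  structure(list(labels = labels, P = P, B_effective = B),
            class = "coassignment")
}

#' @export
print.coassignment <- function(x, ...) {
  cat(sprintf("<coassignment> %d nodes over %d bootstrap partitions\n",
              length(x$labels), x$B_effective))
  invisible(x)
}

#' @export
tidy.coassignment <- function(x, ...) {
  out <- edge_table(x$P, x$labels)
  names(out)[names(out) == "weight"] <- "proportion"
  out
}

#' Export a partition as CSV (node, community, Q)
#'
#' @param partition a `community_partition`.
#' @param path output file.
#' @export
write_partition_csv <- function(partition, path) {
  readr::write_csv(tidy(partition), path)
  invisible(path)
}

#' Export a co-assignment matrix as labeled CSV
#'
#' @param x a `coassignment`.
#' @param path output file.
#' @export
write_coassignment_csv <- function(x, path) {
  df <- tibble::as_tibble(as.data.frame(x$P, check.names = FALSE))
  df <- dplyr::bind_cols(tibble::tibble(node = x$labels), df)
  readr::write_csv(df, path)
  invisible(path)
}
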