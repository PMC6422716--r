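#' Derive a reproducible child seed from a parent seed and an index
#'
#' Bootstrap replicates, Louvain restarts and simulation replicates each draw
#' their own RNG seed as a deterministic function of (parent seed, index), so
#' results are reproducible regardless of evaluation order and safe to
#' parallelize. A Lehmer-style multiplicative mix keeps the result a valid
#' 32-bit integer seed.
#'
#' @param seed integer parent seed.
#' @param index non-negative integer stream index.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index))
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (abs(as.double(seed)) %% m)
  # two mixing rounds; all intermediates stay below 2^53 so doubles are exact
  y <- (x * 48271 + as.double(index) * 16807 + 1) %% m
  y <- (y * 69621 + 7) %% m
  as.integer(y)
}

# internal: check a square symmetric numeric matrix with optional labels
check_square <- function(W, what = "W") {
  if (!is.matrix(W) || !is.numeric(W) || nrow(W) != ncol(W)) {
    abort(sprintf("`%s` must be a square numeric matrix.", what))
  }
  if (max(abs(W - t(W))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", what))
  }
  invisible(W)
}

# internal: node labels of a matrix, defaulting to V1..Vp
matrix_labels <- function(W) {
  labs <- rownames(W) %||% colnames(W)
  if (is.null(labs)) labs <- paste0("V", seq_len(nrow(W)))
  labs
}

# internal: upper-triangle edge tibble of a symmetric weighted matrix
edge_table <- function(W, labels = matrix_labels(W)) {
  p <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  tibble::tibble(
    from = labels[idx[, 1]],
    to = labels[idx[, 2]],
    weight = W[idx]
  )
}
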