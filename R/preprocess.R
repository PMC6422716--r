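#' Stroop interference ratio
#'
#' Time on the color-word interference card (Stroop III) divided by time on
#' the color-naming card (Stroop II). Higher ratios reflect greater
#' interference, i.e. weaker suppression of the automatic reading response.
#'
#' @param time_III,time_II card completion times in seconds; both must be
#'   strictly positive.
#' @param subject optional subject identifiers used in error messages.
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' stroop_ratio(60, 30) # 2
stroop_ratio <- function(time_III, time_II, subject = NULL) {
  check_positive_times(time_III, time_II, subject,
                       c("stroop_III_s", "stroop_II_s"))
  time_III / time_II
}

#' Trail-Making flexibility ratio
#'
#' Time on Part B divided by time on Part A (Trails B/A), removing the
#' visual-scanning and motor-speed component shared by the two parts. Higher
#' ratios reflect more cognitive inflexibility.
#'
#' @param time_B,time_A part completion times in seconds; both must be
#'   strictly positive.
#' @inheritParams stroop_ratio
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' tmt_ratio(90, 30) # 3
tmt_ratio <- function(time_B, time_A, subject = NULL) {
  check_positive_times(time_B, time_A, subject, c("tmt_B_s", "tmt_A_s"))
  time_B / time_A
}

# internal: both ratio scores demand strictly positive times; errors name
# the offending subject so data problems are traceable
check_positive_times <- function(num, den, subject, cols) {
  bad <- which(!is.na(num) & num <= 0 | !is.na(den) & den <= 0)
  if (length(bad) > 0) {
    who <- if (is.null(subject)) paste0("row ", bad[1]) else subject[bad[1]]
    abort(sprintf(
      "Nonpositive time in %s/%s for subject %s; times must be > 0 seconds.",
      cols[1], cols[2], who
    ))
  }
  invisible(TRUE)
}

#' Derive the ratio scores from raw subtest times
#'
#' If the raw time columns (`stroop_II_s`, `stroop_III_s`, `tmt_A_s`,
#' `tmt_B_s`) are present, computes `STR = stroop_III_s / stroop_II_s` and
#' `TMT = tmt_B_s / tmt_A_s`. When both raw times and precomputed ratio
#' columns exist, the raw times win and a warning is issued.
#'
#' @param data cohort tibble.
#' @return The tibble with `STR`/`TMT` filled in and raw time columns
#'   retained.
#' @export
derive_ratio_scores <- function(data) {
  subj <- if ("subject_id" %in% names(data)) data$subject_id else NULL
  if (all(c("stroop_II_s", "stroop_III_s") %in% names(data))) {
    if ("STR" %in% names(data) && any(!is.na(data$STR))) {
      warn("Both raw Stroop times and an STR column found; recomputing STR from raw times.")
    }
    data$STR <- stroop_ratio(data$stroop_III_s, data$stroop_II_s, subj)
  }
  if (all(c("tmt_A_s", "tmt_B_s") %in% names(data))) {
    if ("TMT" %in% names(data) && any(!is.na(data$TMT))) {
      warn("Both raw TMT times and a TMT column found; recomputing TMT from raw times.")
    }
    data$TMT <- tmt_ratio(data$tmt_B_s, data$tmt_A_s, subj)
  }
  data
}

#' Split a cohort into per-group complete-case score matrices
#'
#' Applies listwise (complete-case) deletion within each group across the
#' analysis variables, reports how many subjects were dropped, and computes
#' the Pearson correlation matrix each group network is estimated from.
#' Groups left with fewer than p + 1 complete rows are rejected with an
#' explicit error: a correlation matrix from fewer rows than variables cannot
#' support the penalized likelihood, and the bootstrap requires one fixed n
#' per group.
#'
#' @param data cohort tibble (after [derive_ratio_scores()] if raw times are
#'   used).
#' @param node_columns character vector of analysis variables; defaults to
#'   [cognitive_nodes()] intersected with the columns present.
#' @param group_column name of the group label column.
#' @param group_levels optional subset/order of group levels to keep;
#'   defaults to the observed levels.
#' @return Named list of `score_matrix` objects (one per group), each with
#'   `group_name`, `labels`, `X` (n x p complete-case matrix), `n`,
#'   `n_dropped` and `correlation`.
#' @export
split_complete_cases <- function(data, node_columns = NULL,
                                 group_column = "group",
                                 group_levels = NULL) {
  if (!group_column %in% names(data)) {
    abort(sprintf("Group column `%s` not found.", group_column))
  }
  if (is.null(node_columns)) {
    node_columns <- intersect(cognitive_nodes(), names(data))
  }
  missing_cols <- setdiff(node_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing score columns: ", paste(missing_cols, collapse = ", ")))
  }
  g <- data[[group_column]]
  if (is.null(group_levels)) {
    group_levels <- if (is.factor(g)) levels(g) else unique(as.character(g))
  }
  unknown <- setdiff(unique(as.character(g)), group_levels)
  if (length(unknown) > 0) {
    abort(paste0("Unknown group labels: ", paste(unknown, collapse = ", ")))
  }
  p <- length(node_columns)
  out <- lapply(group_levels, function(gl) {
    rows <- data[as.character(g) == gl, node_columns, drop = FALSE]
    X <- as.matrix(rows)
    if (!is.numeric(X)) abort("Score columns must be numeric.")
    keep <- complete.cases(X)
    n_dropped <- sum(!keep)
    X <- X[keep, , drop = FALSE]
    if (nrow(X) < p + 1) {
      abort(sprintf(
        "Group `%s` has only %d complete rows; at least %d (p + 1) required.",
        gl, nrow(X), p + 1
      ))
    }
    if (n_dropped > 0) {
      inform(sprintf("Group `%s`: dropped %d incomplete row(s), %d retained.",
                     gl, n_dropped, nrow(X)))
    }
    new_score_matrix(X, node_columns, gl, n_dropped)
  })
  names(out) <- group_levels
  out
}

# internal score_matrix constructor
new_score_matrix <- function(X, labels, group_name, n_dropped = 0L) {
  colnames(X) <- labels
  structure(
    list(
      group_name = group_name,
      labels = labels,
      X = X,
      n = nrow(X),
      n_dropped = n_dropped,
      correlation = stats::cor(X)
    ),
    class = "score_matrix"
  )
}

#' Build a score matrix from a numeric matrix or data frame
#'
#' Convenience wrapper when the data are already complete: constructs the
#' `score_matrix` container (scores + Pearson correlation) that
#' [estimate_network()] and [bootstrap_pipeline()] consume.
#'
#' @param X numeric matrix or data frame of complete scores (rows = subjects).
#' @param group_name group label (default "all").
#' @return A `score_matrix`.
#' @export
as_score_matrix <- function(X, group_name = "all") {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort("`X` must be numeric.")
  if (any(!is.finite(X))) abort("`X` must be complete; use split_complete_cases().")
  labels <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  new_score_matrix(X, labels, group_name)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s: n = %d subjects, p = %d variables (%d dropped)\n",
              x$group_name, x$n, length(x$labels), x$n_dropped))
  invisible(x)
}
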