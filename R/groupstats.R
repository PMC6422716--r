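#' Levene's test for homogeneity of variance (Brown-Forsythe)
#'
#' Robust Levene test with median centering (the Brown-Forsythe variant),
#' computed via [car::leveneTest()]. `ranks = TRUE` gives a nonparametric
#' flavor: the test is run on the rank-transformed values.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor), at least 2 groups with at
#'   least 2 observations each.
#' @param ranks run the test on ranks instead of raw values.
#' @return Tibble with `statistic` (W), `df1`, `df2`, `p_value`.
#' @export
levene_test <- function(values, groups, ranks = FALSE) {
  groups <- droplevels(as.factor(groups))
  check_group_input(values, groups)
  if (all(tapply(values, groups, function(v) length(unique(v)) == 1))) {
    abort("Levene statistic is undefined: all groups are constant (0/0).")
  }
  y <- if (ranks) rank(values) else values
  lt <- car::leveneTest(y ~ groups, center = median)
  tibble::tibble(
    statistic = lt$`F value`[1],
    df1 = lt$Df[1],
    df2 = lt$Df[2],
    p_value = lt$`Pr(>F)`[1]
  )
}

# internal: shared validation for the group tests
check_group_input <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length.")
  }
  sizes <- table(groups)
  if (length(sizes) < 2) abort("Need at least 2 groups.")
  if (any(sizes < 2)) abort("Each group needs at least 2 observations.")
  invisible(TRUE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Classical one-way F test with (k - 1, N - k) degrees of freedom. When the
#' omnibus test is significant at `alpha`, Tukey HSD pairwise comparisons
#' are attached (Tukey-Kramer adjustment handles unequal group sizes). A
#' Brown-Forsythe Levene p-value accompanies the result as the homogeneity
#' check.
#'
#' @inheritParams levene_test
#' @param variable name attached to the result row.
#' @param alpha significance level gating the post-hoc stage (default 0.05).
#' @return A `group_comparison`: tibble with `variable`, `test`,
#'   `statistic`, `df1`, `df2`, `p_value`, `levene_p` and a list-column
#'   `posthoc` of pairwise rows (`group_a`, `group_b`, `mean_diff`,
#'   `adjusted_p`), empty unless the omnibus test rejects.
#' @export
oneway_anova <- function(values, groups, variable = "y", alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  check_group_input(values, groups)
  fit <- aov(values ~ groups)
  tab <- anova(fit)
  p_val <- tab$`Pr(>F)`[1]
  posthoc <- empty_posthoc()
  if (!is.na(p_val) && p_val < alpha) {
    tk <- TukeyHSD(fit)$groups
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    posthoc <- tibble::tibble(
      group_a = vapply(pairs, `[`, "", 1),
      group_b = vapply(pairs, `[`, "", 2),
      mean_diff = unname(tk[, "diff"]),
      adjusted_p = unname(tk[, "p adj"])
    )
  }
  lev <- levene_test(values, groups)
  tibble::tibble(
    variable = variable,
    test = "anova",
    statistic = tab$`F value`[1],
    df1 = tab$Df[1],
    df2 = tab$Df[2],
    p_value = p_val,
    levene_p = lev$p_value,
    posthoc = list(posthoc)
  )
}

empty_posthoc <- function() {
  tibble::tibble(group_a = character(), group_b = character(),
                 mean_diff = double(), adjusted_p = double())
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with tie correction, referred to a chi-square
#' distribution on k - 1 degrees of freedom. With all observations
#' identical the tie correction makes H 0/0; this degenerate case is
#' reported as H = 0, p = 1 with a warning. The accompanying homogeneity
#' check is Levene's test on ranks.
#'
#' @inheritParams oneway_anova
#' @return A `group_comparison` tibble (see [oneway_anova()]); `df2` is `NA`
#'   for the chi-square reference.
#' @export
kruskal_wallis <- function(values, groups, variable = "y", alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  check_group_input(values, groups)
  if (length(unique(values)) == 1) {
    warn("All observations identical; Kruskal-Wallis H reported as 0.")
    stat <- 0
    df <- nlevels(groups) - 1
    p_val <- 1
    lev_p <- NA_real_
  } else {
    kt <- kruskal.test(values, groups)
    stat <- unname(kt$statistic)
    df <- unname(kt$parameter)
    p_val <- kt$p.value
    lev_p <- levene_test(values, groups, ranks = TRUE)$p_value
  }
  tibble::tibble(
    variable = variable,
    test = "kruskal_wallis",
    statistic = stat,
    df1 = df,
    df2 = NA_integer_,
    p_value = p_val,
    levene_p = lev_p,
    posthoc = list(empty_posthoc())
  )
}

#' Between-group comparison of every analysis variable
#'
#' The "standard analysis" stage: for each variable, a one-way ANOVA across
#' the groups, or a Kruskal-Wallis test where normality is untenable.
#' `test = "auto"` (default) picks Kruskal-Wallis when a Shapiro-Wilk test
#' on the pooled within-group residuals rejects at 0.05, mirroring the
#' common practice of reserving the rank test for nonnormal scores.
#'
#' @param data cohort tibble.
#' @param variables character vector of score columns; defaults to the
#'   canonical nodes present in `data`.
#' @param group_column group label column.
#' @param test `"auto"`, `"anova"` or `"kruskal"`.
#' @param alpha significance level for the post-hoc gate.
#' @return Tibble with one `group_comparison` row per variable.
#' @export
compare_groups <- function(data, variables = NULL, group_column = "group",
                           test = c("auto", "anova", "kruskal"),
                           alpha = 0.05) {
  test <- match.arg(test)
  if (is.null(variables)) {
    variables <- intersect(cognitive_nodes(), names(data))
  }
  g <- data[[group_column]]
  purrr::map_dfr(variables, function(v) {
    y <- data[[v]]
    keep <- !is.na(y) & !is.na(g)
    yv <- y[keep]
    gv <- g[keep]
    use <- test
    if (test == "auto") {
      resid <- yv - stats::ave(yv, gv)
      sw <- tryCatch(stats::shapiro.test(resid)$p.value,
                     error = function(e) NA_real_)
      use <- if (!is.na(sw) && sw < 0.05) "kruskal" else "anova"
    }
    if (use == "kruskal") {
      kruskal_wallis(yv, gv, variable = v, alpha = alpha)
    } else {
      oneway_anova(yv, gv, variable = v, alpha = alpha)
    }
  })
}

#' Export group comparisons as a tidy CSV
#'
#' Post-hoc rows are unnested so the file is flat: one row per variable for
#' the omnibus test plus one row per significant pairwise comparison.
#'
#' @param comparisons tibble from [compare_groups()].
#' @param path output file.
#' @export
write_groupstats_csv <- function(comparisons, path) {
  flat <- tidyr::unnest(comparisons, "posthoc", keep_empty = TRUE)
  readr::write_csv(flat, path)
  invisible(path)
}
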