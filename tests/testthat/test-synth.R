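test_that("planted precision encodes exact partial correlations on the block pattern", {
  m <- make_planted_precision(letters[1:4], list(c("a", "b"), c("c", "d")), 0.4)
  expect_identical(m$labels, letters[1:4])
  expect_equal(m$precision, t(m$precision))
  expect_gt(min(eigen(m$precision, symmetric = TRUE)$values), 0)
  expect_equal(m$partial["a", "b"], 0.4, tolerance = 1e-6)
  expect_equal(m$partial["c", "d"], 0.4, tolerance = 1e-6)
  expect_equal(m$partial["a", "c"], 0)
  expect_equal(m$partial["a", "d"], 0)
  expect_equal(m$partial["b", "c"], 0)

  # inversion oracle: implied marginal correlations from the standardized
  # inverse precision (single feasible 3-node block)
  m3 <- make_planted_precision(c("x", "y", "z"), list(c("x", "y", "z")), 0.45)
  Sigma <- stats::cov2cor(solve(m3$precision))
  # triangle at equal partials: every marginal correlation identical and
  # larger than the partial (shared paths add up)
  expect_equal(Sigma["x", "y"], Sigma["y", "z"], tolerance = 1e-10)
  expect_gt(Sigma["x", "y"], 0.45)
  # re-deriving partials from the inverted covariance closes the loop
  P <- -stats::cov2cor(solve(Sigma))
  diag(P) <- 0
  expect_equal(max(abs(P - m3$partial)), 0, tolerance = 1e-8)
})

test_that("zero within-strength gives an identity-pattern precision", {
  m <- make_planted_precision(letters[1:5], list(letters[1:3], letters[4:5]), 0)
  expect_equal(unname(m$precision), diag(5))
  expect_true(all(m$partial == 0))
})

test_that("infeasible strengths fail with a construction error, not silently", {
  # triangle at 0.5 is exactly singular under any unit-diagonal uniform
  # construction; diagonal loading cannot restore exact partials
  expect_error(
    make_planted_precision(c("x", "y", "z"), list(c("x", "y", "z")), 0.5),
    "not positive definite"
  )
  expect_error(
    make_planted_precision(c("x", "y"), list(c("x", "y")), 1.0),
    "< 1"
  )
})

test_that("sampling is seed-deterministic and honors the planted structure", {
  m <- two_block_model(0.4)
  spec <- cohort_spec(list(g = m), c(g = 40), seed = 7)
  a <- sample_cohort(spec)
  b <- sample_cohort(spec)
  expect_identical(a, b)
  c <- sample_cohort(cohort_spec(list(g = m), c(g = 40), seed = 8))
  expect_false(identical(a, c))

  # identity precision: all pairwise sample correlations near zero
  m0 <- make_planted_precision(paste0("x", 1:6), list(paste0("x", 1:6)), 0)
  big <- sample_cohort(cohort_spec(list(g = m0), c(g = 10000), seed = 3))
  S <- stats::cor(as.matrix(big[, m0$labels]))
  expect_lt(max(abs(S[upper.tri(S)])), 0.03)

  # planted partial correlation recovered by the regression-residual oracle
  big2 <- sample_cohort(cohort_spec(list(g = m), c(g = 10000), seed = 4))
  P <- oracle_partial_correlations(as.matrix(big2[, m$labels]))
  expect_lt(abs(P["v1", "v2"] - 0.4), 0.03)
  expect_lt(abs(P["v5", "v6"] - 0.4), 0.03)
  expect_lt(abs(P["v1", "v5"]), 0.03)
})

test_that("sampling accuracy improves with n roughly as 1/sqrt(n)", {
  m <- two_block_model(0.3)
  dev_at <- function(n, seed) {
    X <- as.matrix(
      sample_cohort(cohort_spec(list(g = m), c(g = n), seed = seed))[, m$labels]
    )
    P <- oracle_partial_correlations(X)
    abs(P["v1", "v2"] - 0.3)
  }
  small <- mean(vapply(1:6, function(s) dev_at(500, s), numeric(1)))
  large <- mean(vapply(1:6, function(s) dev_at(8000, s), numeric(1)))
  expect_lt(large, small) # 4x the sample, ~4x less deviation on average
})

test_that("study fixture reproduces the three-group design", {
  coh <- make_study_fixture(seed = 42)
  expect_identical(
    as.integer(table(coh$group)[c("control", "nonfrontal", "frontal")]),
    c(67L, 66L, 61L)
  )
  expect_identical(levels(coh$group), c("control", "nonfrontal", "frontal"))
  expect_true(all(cognitive_nodes() %in% names(coh)))
  expect_equal(nrow(coh), 194)

  # identical planted means across groups: large-n sample means agree
  big <- make_study_fixture(seed = 9, n = c(control = 4000, nonfrontal = 4000,
                                            frontal = 4000))
  scales <- default_score_scales()
  for (v in c("15T", "STR", "FEF")) {
    mus <- tapply(big[[v]], big$group, mean)
    expect_lt(max(mus) - min(mus), 0.12 * scales$sd[[v]])
  }
})

test_that("frontal group couples memory and executive nodes; control does not", {
  mods <- study_models()
  n <- c(control = 10000, nonfrontal = 10000, frontal = 10000)
  big <- make_study_fixture(seed = 5, n = n)
  Xf <- as.matrix(big[big$group == "frontal", cognitive_nodes()])
  Xc <- as.matrix(big[big$group == "control", cognitive_nodes()])
  Pf <- oracle_partial_correlations(Xf)
  Pc <- oracle_partial_correlations(Xc)
  expect_gt(Pf["15T", "DSB"], 0.25)   # planted 0.3 in the frontal ring
  expect_lt(abs(Pc["15T", "DSB"]), 0.03)
  # shared edges present everywhere
  expect_gt(Pf["15T", "15R"], 0.5)
  expect_gt(Pc["15T", "15R"], 0.5)
  expect_gt(Pc["DSB", "FLU"], 0.3)
  # planted communities match the declared blocks
  expect_identical(unname(mods$frontal$communities[c("15T", "15R", "DSB", "FLU")]),
                   rep("ME", 4))
  expect_false(mods$control$communities[["15T"]] ==
                 mods$control$communities[["DSB"]])
})

test_that("cohort CSV and ground-truth JSON round-trip", {
  m <- two_block_model(0.3)
  spec <- cohort_spec(list(g1 = m, g2 = m), c(g1 = 15, g2 = 12), seed = 2)
  coh <- sample_cohort(spec)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cohort_csv(coh, csv)
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 27)
  expect_identical(names(back), names(coh))
  expect_equal(back$v1, coh$v1, tolerance = 1e-12)

  write_ground_truth_json(spec, js)
  gt <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(gt$seed, 2)
  expect_equal(unlist(gt$n), c(g1 = 15, g2 = 12))
  expect_equal(matrix(unlist(gt$groups$g1$precision), 9, 9, byrow = TRUE),
               unname(m$precision), tolerance = 1e-12)
})
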