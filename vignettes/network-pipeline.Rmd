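---
title: "Group-wise partial-correlation networks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-wise partial-correlation networks: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cognet models a battery of nine executive-function and behavior scores —
verbal list-learning total and delayed recall (15T, 15R), Digit-Span
backwards (DSB), letter fluency (FLU), the Stroop III/II interference ratio
(STR), the Trail-Making B/A ratio (TMT), and the FrSBe Apathy,
Disinhibition and Executive-Dysfunction subscales (FAP, FID, FEF) — as a
Gaussian graphical model estimated separately within patient groups
(typically: frontal lesions, non-frontal lesions, controls). The scientific
question it serves is not whether group *means* differ (in the motivating
setting they do not), but whether the *pattern of conditional dependence*
among the scores differs by lesion location.

## The model

For a group with score matrix $X \in \mathbb{R}^{n \times p}$ ($p = 9$),
estimation runs on the Pearson correlation matrix $S$. The network is the
partial-correlation matrix implied by a sparse precision matrix
$\Theta$: for nodes $i \neq j$,

$$\rho_{ij \mid \text{rest}} = -\frac{\Theta_{ij}}{\sqrt{\Theta_{ii}\Theta_{jj}}},$$

so an absent edge ($\Theta_{ij} = 0$) means conditional independence given
all other scores. $\Theta$ is estimated by the graphical LASSO,

$$\hat\Theta(\lambda) = \arg\max_{\Theta \succ 0}\;
\log\det\Theta - \operatorname{tr}(S\Theta) - \lambda \sum_{i \neq j} |\Theta_{ij}|,$$

solved by block coordinate descent with exact soft-thresholding (compiled
code in `src/glasso.cpp`); the penalty is applied to off-diagonal entries
only, so the diagonal is never shrunk. Working on $S$ rather than the raw
covariance makes the penalty scale-free and the fitted network invariant to
affine rescaling of any score.

## Penalty selection: BIC, thresholding, refitting

The penalty path is 100 log-spaced values from
$\lambda_{\max} = \max_{i \neq j}|S_{ij}|$ (the smallest penalty that
empties the network) down to $0.01\,\lambda_{\max}$, fitted with warm
starts. Each fit is scored by

$$\mathrm{BIC}(\lambda) = -2\,\ell(\hat\Theta_\lambda) + E_\lambda \log n,
\qquad \ell = \tfrac{n}{2}\left(\log\det\Theta - \operatorname{tr}(S\Theta)\right),$$

where $E_\lambda$ counts the nonzero upper-triangle entries (this is the
extended BIC at $\gamma = 0$; `gamma` raises the penalty by
$4\gamma E\log p$ and is available but not the default). Ties within
$10^{-9}$ resolve toward the larger penalty, i.e. the sparser model, so
selection is deterministic.

Two refinements are applied to the selected model, both on by default and
both exposed as arguments of `estimate_network()`:

* **Thresholding** (`threshold = TRUE`). Selected edges with
  $|\hat\rho_{ij}| < \sqrt{\log(p(p-1)/2)/n}$ are set to zero. Penalized-BIC
  selection alone is not sparsistent here: as $n$ grows, un-shrinking the
  true edges keeps improving the likelihood term, which drags the selected
  $\lambda$ below the noise level and admits spurious small edges. In our
  planted-structure simulations at $n = 5000$ the raw convention admits a
  false-edge rate around 0.16; with the bound it drops below 0.01 while
  sensitivity stays at 1. The bound is the standard
  $\sqrt{\log m / n}$ sparsistency rate ($m$ = number of candidate edges),
  not a tuned constant.
* **Refitting** (`refit = TRUE`). The surviving edge set is refitted by the
  maximum-likelihood estimate constrained to that support (the same solver
  with a $0/\infty$ penalty pattern), and the refitted partial correlations
  are reported. This removes the L1 shrinkage bias from the edge weights;
  without it, bootstrap percentile intervals are centered on biased values
  and their coverage of the data-generating weight degrades noticeably.

Setting both to `FALSE` reproduces the raw penalized convention exactly.

## Bootstrap inference

`bootstrap_pipeline()` draws $B$ (default 1000) $n$-out-of-$n$ resamples and
re-runs the *entire* estimation on each — correlation, penalty path, BIC
re-selection, thresholding, refit, and (optionally) community detection —
so the intervals reflect model-selection variability, not just sampling
noise given a fixed graph. Edge-weight and node-strength intervals are
empirical 2.5/97.5 percentiles with linear interpolation between order
statistics (R quantile type 7); a warning fires below 40 replicates, where
the tails are unresolved. Group differences in centrality are judged by
interval nonoverlap with a closed-interval convention: touching endpoints
count as overlap. Percentile intervals for centrality statistics are known
to be imperfect; no bias correction (BCa or otherwise) is applied, and the
intervals should be read as stability descriptions rather than exact
frequentist statements.

Each replicate derives its RNG seed deterministically from
`(seed, replicate index)` (`derive_seed()`), so ensembles are reproducible
and independent of evaluation order. A resample that leaves any column
constant is redrawn (logged); more than 5% redraws aborts the run.

## Centrality, communities, co-assignment

Node strength is the sum of absolute incident edge weights. Community
structure is found by maximizing the asymmetric signed modularity

$$Q = Q^{+} - \frac{s^{-}}{s^{+} + s^{-}}\,Q^{-},$$

where $Q^{\pm}$ are Newman weighted modularities of the positive and
(absolute) negative subnetworks and $s^{\pm}$ their total weights: positive
within-community weight is rewarded at full rate, negative within-community
weight penalized in proportion to its share. With no negative edges this is
exactly Newman's weighted $Q$. Partial-correlation networks do contain
negative edges, and no convention is universal; `mode = "absolute"` runs
detection on $|W|$ instead. The resolution parameter is fixed at 1.

Maximization uses the two-phase Louvain heuristic with seed-shuffled visit
order. One consequence of the signed objective is that a profitable move
can target a community the node has *no* edges to (through the
negative-part null model), so the local-moving step considers every
community, not just neighboring ones. Because Louvain is greedy,
`best_partition()` restarts it (default 100 times) and keeps the highest-Q
solution, breaking exact ties by the lexicographically smallest canonical
assignment; community ids are always renumbered by first node appearance so
outputs are diff-stable. On graphs of up to 9 nodes the exhaustive oracle
`modularity_optimum()` enumerates all set partitions; in the test suite the
restarted heuristic attains that optimum on essentially every random signed
graph tried.

Community *stability* is summarized by the co-assignment matrix: the
proportion of bootstrap partitions in which two nodes share a community.
The per-node panels color each proportion from red (0) to white (1),
rows = groups, columns = the remaining eight nodes.

## The synthetic generator

Because the motivating clinical data are not public, the package ships a
generator whose defaults emulate the study design: three groups of 67, 66
and 61 subjects, nine variables, equal score means and standard deviations
across groups (so mean tests are null by construction), and group-specific
sparse precision matrices. All groups share a strong memory edge
(15T–15R, partial correlation 0.6) and an executive edge (DSB–FLU, 0.4);
the frontal model merges {15T, 15R, DSB, FLU} into one block — the
coupling of memory with working memory and fluency that distinguishes that
group — while the control and non-frontal models keep memory separate.

Planted blocks are wired as rings (a single edge for two-node blocks) with
every planted edge's partial correlation set exactly. Rings keep each row
of the precision matrix diagonally dominant whenever the strength is below
0.5, guaranteeing positive definiteness without distorting the planted
values; complete blocks cannot carry uniform partial correlations of the
magnitudes used here (a complete 5-node block at 0.3 is already
indefinite), which is why rings were chosen. Infeasible requests fail with
a construction error rather than silently shrinking the target.

Score means/SDs (e.g. 15T: 45 ± 10) are conventional, not calibrated to any
dataset — no per-group score moments are publicly available for the
motivating study — and are
irrelevant to network estimation, which standardizes; they exist so the
preprocessing path (ratio scores, complete-case splitting) is exercised in
realistic units.

What the generator does *not* emulate: non-Gaussian marginals (the real TMT
ratio is skewed; the machinery assumes linear dependence throughout),
item-level questionnaire structure, missingness patterns, and lesion
anatomy. Passing tests therefore demonstrate correctness of the estimation
machinery under the Gaussian model, not robustness to the messiness of
clinical scores.

## Numerical choices and degenerate inputs

* Coordinate-descent tolerance $10^{-6}$ (relative to the mean absolute
  off-diagonal of $S$), maximum 500 sweeps; non-convergence is an error
  carrying $\lambda$, never a silent result.
* At $\lambda = 0$ the solver agrees with the explicit inverse to better
  than $10^{-4}$ (tested), and the reported partials agree with
  regression-residual partial correlations to $10^{-4}$ at $n = 10^4$.
* Missingness is handled by listwise deletion within group: the bootstrap
  needs one fixed $n$ per group, and pairwise deletion can produce
  indefinite correlation matrices. Groups with fewer than $p + 1$ complete
  rows are rejected outright.
* If raw subtest times and precomputed ratio columns are both present, raw
  times win with a warning; nonpositive times are errors naming the
  subject.
* An all-zero network has $Q = 0$ and all-singleton communities; a
  constant variable within a group invalidates the correlation and is
  caught at preprocessing (or triggers bootstrap redraws).
* Kruskal–Wallis on all-identical values (tie correction 0/0) reports
  H = 0 with a warning; Levene on all-constant groups is an error.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` exercise: oracle equivalence at
$n = 10^4$; 100 random signed graphs of up to 6 nodes against the
exhaustive modularity optimum (203 partitions); structure recovery over 50
replicates at $n = 5000$; CI coverage pooled over 25 replicates × 9 planted
edges at $n = 500$, $B = 200$; co-assignment separation at $n = 2000$,
$B = 200$, 10 restarts; null calibration over 100 replicates at $n = 65$;
and type-I calibration of the ANOVA stage over 500 fixture replicates.
These sizes keep a full run within a few minutes on one CPU while leaving
Monte-Carlo error well inside the asserted bands; all of them are plain
function arguments, so larger studies are one edit away.

## Known limitations

* Gaussian, linear dependence only; no nonparanormal or polychoric input.
* Percentile (not bias-corrected) bootstrap intervals.
* The signed-modularity convention is one defensible choice among several;
  results on networks with many negative edges can depend on it.
* Ratio scores (STR, TMT) inherit the reliability problems of test-score
  ratios; the package computes them as defined and takes no position on
  their psychometrics.
* `best_partition()` is a heuristic: global optimality is only verified on
  small graphs, where exhaustive search is feasible.
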