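---
title: "Measuring conversation-induced neural alignment with neuralign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conversation-induced neural alignment with neuralign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the measurement model

When a small group talks its way to a consensus about an ambiguous
experience, do its members' brains subsequently process the world more
similarly? `neuralign` implements the analysis pipeline for studies with the
following design: participants watch movie clips during fMRI, meet in small
groups to reach a consensus interpretation, then watch the same clips (and
novel clips) during a second scan. Controls watch twice without conversing.

The unit of measurement is **inter-subject correlation (ISC)**: for a pair
of participants and a voxel, the Pearson correlation of their BOLD time
series over a clip. For each session this yields a voxel-indexed stack of
N×N symmetric pair matrices (`isc_matrix()`).

### Change in alignment

The central model asks where in the brain conversation increased pairwise
alignment. For each voxel, the *change matrix* (after-conversation ISC minus
before-conversation ISC, `change_stack()`) is unraveled over the strict
lower triangle of subject pairs and regressed on:

* an all-1s **intercept**, absorbing change that occurs with or without
  conversation (e.g. from watching the clip a second time) — control and
  between-group pairs are always included as rows for exactly this reason;
* one **indicator column per conversation group** (1 iff both pair members
  belong to that group), or a single same-group column in the across-groups
  variant.

Matrices from multiple clips are concatenated row-wise and fit in a single
model. A group's β is therefore the conversation-specific change in ISC
over and above the intercept. A *novel-clip* variant uses the
post-conversation ISC matrix of an undiscussed clip as the target with the
same predictors, testing generalization beyond the discussed material.

### Inference: subject-wise permutation

Pair matrices violate the independence assumptions of parametric tests: each
subject participates in N−1 pairs. The null distribution is therefore built
by **subject-wise permutation**: a relabeling of subjects is drawn and
applied *identically to the rows and columns* of every clip's target
matrix; the design is held fixed and the regression refit
(`subjectwise_permutation()`). This preserves the exchangeable unit — the
subject — and hence the dependence structure among pairs. Two design points
the literature leaves open, decided here:

* **One relabeling per draw, reused across concatenated clips.** Permuting
  each clip independently would break subject exchangeability across the
  concatenated model, so the same relabeling is applied to every clip.
* **Add-one smoothing.** Two-tailed p-values are
  `(1 + #{|β_perm| ≥ |β_obs|}) / (1 + n_perm)`, avoiding p = 0 at finite
  n_perm; the raw-proportion rule is available via `smoothing = "raw"`.
  With `exhaustive = TRUE` all N! relabelings are enumerated (identity
  included) and the raw proportion is exact.
* **Ties.** Relabelings that reproduce the observed statistic exactly (e.g.
  group-preserving relabelings) are counted as exceedances, with a 1e-10
  margin against floating-point summation noise; this is the conservative
  convention and makes p-values invariant to subject ordering.

Voxel-wise maps are corrected at the cluster level (`cluster_correct()`):
suprathreshold voxels (default cluster-forming p = 0.01) are grouped into
face-connected components, separately per predictor and sign, and retained
if they meet a 32-voxel minimum extent. These defaults mirror the
group-by-movie analysis convention of the study design this package serves.
Positive and negative clusters are corrected separately; connectivity is
configurable (6/18/26). An optional permutation null
(`null = "max_cluster"`, requires `keep_null = TRUE`) retains clusters
exceeding the 95th percentile of maximum null cluster extents instead of
the fixed minimum; software-specific autocorrelation-function cluster
simulators are deliberately not reproduced.

### Directed neural influence

Change in ISC is symmetric; influence is not. For an ordered pair
(*ego*, *alter*), neural influence is

```
influence(e, a) = ISC(e_pre, a_post) − ISC(e_pre, a_pre)
```

— how much the alter's post-conversation activity moved toward the ego's
*initial* activity (`influence_stack()`). Both triangles of the pair matrix
are used (each subject is tested in both roles); the diagonal is undefined.
Whole-brain influence is the voxel sum of positive influence values.
Influence maps are regressed on social-network centrality with
ego-valued and alter-valued predictor columns (`centrality_design()`),
restricted to ordered same-group pairs, centrality z-scored over the
participants entering the design. An intercept over ordered pairs is
included (the source design is silent on this; a fitted intercept costs one
degree of freedom and protects the centrality βs from absorbing the grand
mean). A constant centrality metric is rejected rather than fitted: after
z-scoring it is 0/0-degenerate, and unscaled it is collinear with the
intercept.

### Network centrality

From directed friendship nominations: eigenvector centrality (how well
connected to well-connected others), Burt constraint
`c_i = Σ_j (p_ij + Σ_q p_iq p_qj)²` over proportional tie strengths, and
brokerage `= constraint^(−0.5)`. Because nomination digraphs make both
metrics unstable (sink nodes; one-sided ties), the default symmetrizes by
union before computing either metric, with directed variants behind flags.
`pca_centrality()` z-scores both metrics and projects onto the first
principal component, sign-oriented so the eigenvector loading is positive;
the PCA is fitted over whatever node set is passed, so the caller chooses
the reference population (full cohort vs participant subsample).

### Behavioral companions

* `survey_distance()`: city-block distance between numeric-coded answers.
* `survey_session_model()`: distance ~ session × within-group with random
  intercepts per pair; the mixed fit is delegated to `lme4`, while the
  bespoke part — permutation p-values for the marginal R² (fixed-effects
  variance fraction) and coefficients, built by refitting on permuted
  distances — is implemented here.
* `survey_influence()`: `d(ego_pre, alter_pre) − d(ego_pre, alter_post)`,
  the city-block analogue of neural influence. The literature gives the
  construct but not a formula; this definition is a documented choice.
* `gini()`: population form `Σ|xᵢ−xⱼ| / (2n²x̄)`, no small-sample
  correction (the estimator variant is not specified at the source; the
  population form keeps `gini(c(0,1)) = 0.5` exact).
* `word_stem_matrix()`: stems used < 5 times corpus-wide fold into a
  `RAREWORD` placeholder, then stems must be used by ≥ 10 speakers and in
  ≥ 3 clips — in that order; the filters are idempotent.
* `word_regression()`: per-stem OLS of a z-scored speaker covariate on stem
  counts, permutation p by shuffling the covariate across *speakers* (it is
  constant within speaker, so turn-level shuffling would be anticonservative).

## The synthetic cohort generator

Every stage is testable without restricted neuroimaging data because the
generator (`sim_config()`, `generate_cohort()`) emulates the data structure
with closed-form ground truth. BOLD series are variance-partitioned white
noise:

```
x_{s,v,t} = √a · g_{v,t} + √b_{grp(s),ses} · h_{grp(s),v,t} + √(1−a−b) · ε_{s,v,t}
```

with `g` a cohort-wide stimulus signal, `h` a group signal carried only by
a contiguous block of "affected" voxels, and all components independent
unit-variance noise redrawn per session and clip. Expected ISC is exactly
`a + b` within groups at affected voxels and `a` otherwise, so the group β
in the change regression has expectation `b_post − b_pre`. Directed
imitation is injected by `inject_influence()`: the alter's post series
becomes `√w · ego_pre + √(1−w) · noise`, giving expected influence `√w` in
the forward direction and 0 in reverse.

Deliberate simplifications, and what they imply: white noise by default
(optional AR(1) with unit marginal variance for autocorrelated-noise
sensitivity checks — real BOLD is autocorrelated, which inflates the
variance of sample correlations; the permutation inference remains valid
because relabeling respects the time-series structure); no hemodynamic
convolution, anatomy, or motion. Passing recovery tests therefore shows the
estimators and their inference are correct under the assumed covariance
structure — not that preprocessing artifacts of real data are handled.
The affected-voxel mask is a near-cubic block at the grid origin so
cluster-extent operations have spatial structure to find; voxels are
flattened in R's native column-major array order. Surveys use a 7-point
scale with 12 items per clip; post-conversation answers move toward the
group mean by a `pull` factor and are re-discretized. Networks come in
`random` (Erdős–Rényi digraph) and `clustered` (cliques joined by
designated brokers, a planted high-brokerage ground truth) flavors. The
generator's effect sizes are calibrated only to make recovery tests
well-powered; source studies do not report generative effect sizes.

## Numerical and degenerate-input conventions

* Zero-variance series yield `NA` (never 0, never an error); such voxels
  are dropped per-voxel in regressions and excluded from summaries.
* No Fisher z-transform anywhere by default: change scores subtract raw r.
  `fisher_z = TRUE` exists for sensitivity analyses only.
* Rolling-window group ISC (`windowed_group_isc()`) uses a 10-TR window,
  step 1, each value mapped to the TR at offset `window %/% 2` from the
  window start; windows shorter than 3 TRs are rejected as degenerate.
  No detrending is applied within windows.
* Rank-deficient designs are rejected naming the collinear columns.
* Ordered-pair vectorization is ego-major, alter-minor, per clip, and
  documented as part of the stable interface.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use cohorts of 6–20
subjects, grids of 24–512 voxels, 150–400 TRs, and 99–2000 permutations
(100 independent seeds for the recovery studies). These sizes were chosen
so each statistical property is measured with comfortable Monte-Carlo
margins while the whole suite stays desk-scale; the same functions run
unchanged at full study scale.

## A minimal end-to-end run

```{r example}
library(neuralign)

cfg <- sim_config(n_subjects = 10, n_groups = 2, n_controls = 2,
                  group_sizes = c(4, 4), grid = c(8, 8, 8),
                  n_timepoints = 400, a_shared = 0.1,
                  b_group_pre = 0.1, b_group_post = 0.4,
                  affected_fraction = 0.125, seed = 1)
cohort <- generate_cohort(cfg, pull = 0.6)
res <- run_full_pipeline(cohort, run_config(n_perm = 999, seed = 1))
res$clusters[, c("predictor", "sign", "n_voxels", "mean_beta")]
```

## Known limitations

* No leave-one-out ISC variant; the pipeline is strictly pairwise.
* No mixed-effects variant of the voxel-wise change model; inference is
  permutation-based at the voxel/cluster level.
* No lagged or Granger-style directionality — influence compares static
  pre/post similarity only.
* The simulator does not emulate preprocessing artifacts; conclusions about
  real data require the standard fMRI preprocessing chain upstream.
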