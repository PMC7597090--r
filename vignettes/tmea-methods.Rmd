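---
title: "Surprisal analysis and weight-sum enrichment: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis and weight-sum enrichment: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `tmea`, the parameters
that matter, the numerical conventions that make runs reproducible, and the
design decisions taken where more than one reasonable choice existed. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The surprisal model

Surprisal analysis assumes the measured system relaxes toward a steady
state of minimal free energy unless constrained. For an entity-by-condition
abundance matrix $X_i(t)$ (strictly positive after pseudocount handling)
the log matrix is decomposed by thin SVD,

$$\ln X_i(t) = \sum_{\alpha=0}^{r} G_{i\alpha}\,\lambda_\alpha(t),
\qquad r + 1 = \min(\#\text{entities}, \#\text{conditions}),$$

with orthonormal weight columns $G_{\cdot\alpha}$ and potentials
$\lambda_\alpha(t) = \sigma_\alpha V_{t\alpha}$. The leading component
($\alpha = 0$) is the baseline state; the surprisal of entity $i$ is the
negative deviation from it, $-\sum_{\alpha\ge 1} G_{i\alpha}
\lambda_\alpha(t)$ (`surprisal_values()`). The free energy invested in
constraint $\alpha$ is

$$F_\alpha(t) = -\lambda_\alpha(t) \sum_i X_i(t)\, G_{i\alpha},$$

additive over constraints; the baseline is excluded from the total by
definition and `free_energy()` rejects $\alpha = 0$. $F$ is reported in the
same arbitrary units as the input abundances; no thermodynamic unit
conversion is attempted.

Assumptions worth keeping in mind: the model is log-linear and low-rank;
replicate and library-size effects are not modeled inside the decomposition
(see below); and the SVD has no notion of time ordering — smoothness of
$\lambda_\alpha(t)$ is an empirical observation, not a constraint.

### Sign convention

SVD component signs are arbitrary, so a fixed convention makes the
decomposition a deterministic function of the input (required for
reproducible enrichment): for $\alpha = 0$ the pair $(G_{\cdot 0},
\lambda_0)$ is flipped so $\sum_i G_{i0} \ge 0$ (ties broken by the first
nonzero weight); for $\alpha \ge 1$ so that $\lambda_\alpha$ is positive at
the first condition where it is nonzero. A consequence the user sees: a
pattern "planted positive" in a simulation may surface with reversed sign —
the positive and negative descriptors of a constraint simply swap. Tests
align directions through the sign of the inner product with the reference
pattern.

### Pseudocount, replicates, normalization

* `log_transform()` defaults the pseudocount to 1 for integer count
  matrices (the conventional offset avoiding $\ln 0$) and 0 otherwise;
  strict positivity is enforced with an error naming the offending entity.
* `aggregate_replicates()` defaults to the mean on the raw abundance scale,
  applied before the log transform, producing one profile per time point.
  The source data format (several replicates per time point) does not
  dictate an aggregation rule; the mean is the least surprising default and
  the median is available. Aggregation is optional — replicate columns can
  also be decomposed directly.
* `normalize_columns()` (off by default everywhere) scales each column to
  the mean column total. It is deliberately not applied silently: the
  decomposition is defined on the data as given, and library-size
  correction is a modeling decision the user should take explicitly.
* `free_energy()` uses the same abundance matrix that produced the log
  matrix — raw, aggregated or normalized as the user chose upstream.

### Choosing the number of constraints

`importance_spectrum()` reports the relative losses
$(\sigma_\alpha - \sigma_{\alpha+1})/\sigma_\alpha$ (0 where
$\sigma_\alpha = 0$); `recovery_fraction()` reports
$\sum_{\alpha\le k}\sigma_\alpha^2 / \sum_\alpha \sigma_\alpha^2$. The
elbow — the last constraint before the relative loss collapses — is a
reporting aid (`suggest_constraints()` returns the $\alpha \ge 1$ with the
largest loss); the retained set stays a user choice, passed explicitly as
`constraint_indices`.

## 2. The directional weight-sum test

For one FAS and constraint, members with strictly positive (negative)
weights form the directional subsets; zero weights belong to neither (the
strict inequalities are part of the statistic's definition, and entities
with exactly zero weight carry no signal for either direction). The test
statistic is the directional sum $\hat w^\pm$. The null resamples $b$
subsets of the observed cardinality $s^\pm$ from the pool of *all*
same-sign weights of the constraint across measured entities — the full
constraint, not the set's complement, because the question is whether this
particular weight mass is exceptional for its size within the constraint.
The empirical p-value is the fraction of resampled sums at least as extreme
(inclusive), so every p is a multiple of $1/b$ and exactly 0 is possible;
the resolution $1/b$ is carried in the result, and an add-one estimator
$(n_{extreme}+1)/(b+1)$ is available for conservative FDR work.

Decisions and their reasons:

* **Without replacement by default.** The null draws subsets of the
  observed pool, i.e. a permutation null; a bootstrap (with-replacement)
  mode exists behind `sampling = "bootstrap"` since for pools much larger
  than $s^\pm$ the two coincide.
* **BH family per (constraint, direction).** Each constraint yields two
  functional descriptors (positively and inversely contributing sets); the
  narrowest defensible family corrects each descriptor separately.
  `per_constraint` and `global` are available.
* **`min_set_size = 5`, inclusive,** applied to the measured-member count;
  catalog members absent from the matrix are dropped with a reported count,
  so tests are conditional on the measured background.
* **Determinism.** One run seed; each (FAS, constraint, direction) test
  derives its own substream seed by a rolling string hash, so results are
  independent of evaluation order and catalog ordering. Identical inputs
  and seed give bitwise-identical records.
* **Tie tolerance.** Resampled sums are accumulated in draw order, so a
  resample of exactly the observed subset can differ from the observed sum
  by floating-point roundoff; inclusive comparison therefore uses a
  tolerance of $10^{-12}\, s\, \max|pool|$ — at the roundoff scale of an
  $s$-term sum, far below any gap between genuinely distinct subset sums.
* **`b = 10000` by default** (configurable, pipeline floor 100): the
  smallest attainable p is $1/b$, so $b$ bounds the resolution after
  correction.

## 3. The hypergeometric baseline

`run_hypgsea()` is the classical one-sided overrepresentation test on
binary labels: $P(X \ge k)$ for $X \sim$ Hypergeom$(N, K, n)$ via
`phyper`, one test per FAS of measured size $\ge 5$, BH across all tested
FASs (a single family, since every annotation yields one test). No mid-p
correction is applied — the discreteness of the test at small set sizes
makes it conservative, and that behavior is part of what the weight-sum
comparison is about; a mid-p variant is deliberately not exposed as a
default. The background $N$ defaults to labeled entities carrying at least
one annotation (common GSEA practice); `background_mode = "all"` uses every
labeled entity. The labels themselves (e.g. DESeq2 DEG calls) are an input,
never computed here.

## 4. WR/CR diagnostics

For a quantile threshold of a constraint's directional pool, a set's weight
ratio (WR) is the fraction of its directional weight mass beyond the
threshold and its count ratio (CR) the corresponding member fraction
("beyond" = above the threshold for positive pools, below for negative;
absolute values keep ratios in $[0,1]$). Regressing WR on CR across sets,
per quantile (1%–99%), measures how much of the weight-sum signal counting
alone explains; the per-direction summary is the 15% trimmed mean of the 99
$R^2$ values. Choices: **within-set denominators** by default (ratios must
be comparable across sets of different sizes to be regressed; a
global-denominator variant is exposed because the definition admits both);
**type-7 quantiles** (R's default interpolation, pinned for
reproducibility); **strict thresholding**, mirroring the strict
inequalities of the directional subsets; quantile thresholds are computed
per constraint, with pairs pooled across the requested constraints.
Undefined $R^2$ (fewer than 3 sets, or zero CR variance) is flagged `NA`
and excluded from the trimmed mean with a reported count.

## 5. The synthetic study generator

The generator is the package's test bed: every statistical property is
validated against data with known ground truth.

* **Structure.** $L^* = G^*\Lambda^*$ with orthonormal $G^*$ from QR of a
  seeded raw matrix; $X = \exp(L^* + \varepsilon)$,
  $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$ on the log scale
  (multiplicative noise on abundances, matching the log-linear model).
* **Defaults as study conditions.** `n_conditions = 11` (a
  high-light-acclimation-style time course), `rank = 3` constraints above
  the baseline, leading singular value $6\sqrt{nm}$ (baseline log abundance
  around 6, i.e. a few hundred counts), `constraint_scale = 0.15`,
  `singular_value_decay = 0.6` (a clear elbow after the designed rank),
  `noise_sd = 0.7`: with these, the baseline plus three constraints recover
  roughly 98–99% of the data — the regime in which an analyst retains three
  constraints. `n_entities = 1000` keeps desk-scale runs fast; planted-power
  simulations use 2000 so that directional subsets are small relative to
  the pools, as they are in transcriptome-scale data.
* **Weights.** The baseline column of $G^*$ is strictly positive
  (lognormal raw column; a steady state has positive composition) with a
  near-constant baseline potential. Constraint weights default to a
  Gaussian bulk plus exactly `outliers_per_direction = 3` isolated outlier
  entities per tail at 8–12 bulk standard deviations. This mirrors measured
  constraint weight distributions — a compact bulk with a handful of genes
  whose weights visibly dominate — and it is what makes the
  single-extreme-driven archetype constructible at all: with a smooth heavy
  tail (e.g. Student t), the largest pool weights are not separated enough
  from the next ones, so no planted set can be dominated by its extremes,
  and conversely a lone pool giant can defeat a genuinely shifted set.
* **Planted archetypes** (`plant_catalog`): `"shift"` samples members with
  probability proportional to $\text{rank}^{strength}$ of the oriented
  weights (the majority-vote case; `strength` is the effect size);
  `"single"` adds `n_extreme` (1–2) entities from the top
  $1-\texttt{tail\_quantile}$ of the directional pool to otherwise random
  members; `"subgroup"` adds a block of tail entities. Null sets are
  uniform draws. All planted memberships are recorded for truth evaluation.
* **What is not emulated:** gene–gene correlation beyond the low-rank
  structure, count discreteness/overdispersion (a pseudocount path is
  exercised with integer matrices in tests, not by a negative-binomial
  mode), batch effects, temporal smoothness of potentials, and annotation
  hierarchy realism. Passing tests therefore demonstrate statistical
  correctness of the machinery under the stated model, not robustness to
  every artifact of real data.

## 6. Problem sizes used by the test suite and acceptance script

Chosen to make the statistical checks informative while keeping a full run
in the minutes range: Monte Carlo oracle comparisons on 200 random pools of
size ≤ 12 at $b = 50{,}000$ against exhaustive enumeration; null
calibration with 2000 random sets at $b = 2000$ (Kolmogorov–Smirnov
distance per direction); planted-archetype power over 20 seeds at
$b = 10{,}000$ with 40 null sets alongside each planted set; SVD oracle on
200 random matrices up to $8 \times 6$ against an independent
eigendecomposition of $L^\top L$.

## 7. Known limitations

* The KS bound used in null-calibration checks (0.02 at $n = 2000$
  p-values) sits near the sampling median of the KS statistic itself, so
  single runs scatter around it; calibration conclusions should rest on the
  distribution across seeds, not one draw.
* Empirical p-values of exactly 0 are reported as computed; users who need
  strictly positive p for downstream tools should switch
  `p_estimator = "add_one"`.
* The per-(constraint, direction) BH family is the narrowest defensible
  choice; with many constraints a global family is more conservative and
  available.
* The decomposition offers no missing-value handling: imputation or
  filtering is the user's responsibility and happens before
  `log_transform()`.
* Multivariate surprisal analysis across omics levels is out of scope;
  each matrix is decomposed on its own.
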