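---
title: "Methods and design notes for stemsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for stemsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how each stage of the package is defined, which knobs
matter, and where a genuinely open design choice was made — in enough detail
that a reader can reproduce or deliberately deviate from any of it.

## Input model

Everything operates on an `ExpressionMatrix`: a genes × samples numeric
matrix of **log-scale** expression with per-sample annotations. Values must
be finite; missing values are rejected by the readers rather than imputed.
Gene identifiers are opaque case-sensitive strings — mapping between symbol
conventions is the caller's job. `quantile_normalize()` (via
`limma::normalizeQuantiles`, ties averaged) forces all samples onto the mean
column-sorted distribution; it is idempotent and rank-preserving per sample.

The log-scale requirement matters for the SNR floor (below): the
`0.2 * |mean|` convention was designed for raw positive intensities, and on
median-centred log data it is nearly inert. The generators emit
median-centred log2-like values for exactly this reason.

## Signal-to-noise signature derivation

For groups $a$ (marker-positive) and $b$ (marker-negative),

$$\mathrm{SNR}(g) = \frac{\bar x_a - \bar x_b}{s_a + s_b},\qquad
s_\cdot \ge \max(0.2\,|\bar x_\cdot|,\ 10^{-8}).$$

Choices, each switchable:

* **sd estimator** — unbiased $n-1$ sample sd by default
  (`unbiased = FALSE` gives the population form). With the tiny group sizes
  of sorted-cell designs (here 6 vs 6) the choice shifts SNR magnitudes by
  ~10% and is the single most consequential convention in the pipeline.
* **sd floor** — on by default for fidelity to the desktop-GSEA metric;
  near-inert on centred data.
* **"commonly regulated" rule** — a gene is called *up* when the pooled SNR
  exceeds `up_threshold` (+1.0) **and** its mean difference is positive in
  every cell line. The pooled conjunct reflects that published tables print
  a single SNR per gene; the per-line sign conjunct is what "commonly
  upregulated across cell lines" has to mean operationally. Either conjunct
  can be disabled (`require_consistency = FALSE`, thresholds at ±Inf).

Output lists are ordered by decreasing |SNR| with lexicographic tie-breaks,
so results are invariant to gene-row permutation.

With 2 replicates per arm and 3 lines, the SNR estimator is noisy: at a true
group difference of 3 noise-sd the estimated pooled SNR has spread ~0.4, so
a threshold of 1.0 leaves a non-negligible miss rate for planted genes even
with no batch structure at all. The acceptance suite measures exactly this
operating characteristic rather than assuming it away; the recovery figures
it reports should be read as properties of a 6-vs-6 design with a hard
threshold, not of the implementation.

## ssGSEA scoring

Within each sample, genes are ranked by expression descending; expression
ties receive average ranks and the walking order breaks residual ties by
gene id for bit-reproducibility. With ascending rank $r_g$ (top gene $=N$)
and in-set weights $r_g^\alpha$ normalized to sum 1, the score is
$\sum_i \left[P_\text{in}(i) - P_\text{out}(i)\right]$ over all list
positions, where $P_\text{out}$ is the unweighted out-of-set step function.

* `alpha = 0.25` is the published ssGSEA default; `alpha = 0` makes the
  score a pure rank-sum statistic (and is what the hand-enumerable unit
  fixtures use).
* Up- and down-signatures are scored separately, never folded into one
  delta score.
* `normalize = "minmax"` divides all scores by the global score range of the
  run — only needed when comparing across cohorts. Correlations and
  median splits within a cohort are invariant to it, which is also why the
  Cox stage standardizes covariates (below): the survival conclusions do
  not depend on the normalization mode.
* The implementation matches gseapy's ssGSEA (`sample_norm_method = "rank"`)
  on random fixtures; one such frozen cross-check ships in the test suite.

## Enrichment map

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ — one-sided, because "enriched" is a directional claim. The
universe must be stated explicitly; the pipeline default is the measured
genes intersected with the collection's union, and the choice is logged in
the output provenance. Raw p-value thresholds (0.01 for nodes, 1e-10 for
edges) follow the enrichment-map convention; a BH-FDR column is emitted for
reference but never used for filtering. Edge tests are pairwise
hypergeometric on set memberships; the network is undirected with no
self-edges.

## Synthetic generators: what they emulate, and what not

`simulate_sorted_experiment()` generates
`baseline + line batch offset + condition shift + noise`:

| parameter | default | rationale |
|---|---|---|
| `effect_size` | 3 | planted genes clear the SNR threshold with margin in expectation (true SNR 1.5 at zero batch) |
| `noise_sd` | 1 | unit scale for all effect sizes |
| `batch_sd` | 0.5 | cell-line heterogeneity at half the replicate noise: strong enough that pooled sds feel it, weak enough that the per-line sign filter stays informative |
| `replicates_per_arm` | 2 | minimal design that still defines within-group sds |

`simulate_tumor_cohort()` mixes two components affinely by purity:
$x_i = p_i(\text{tumor} + a_i\,\mathbb{1}_\text{stem}) + (1-p_i)\,\text{stromal} + \varepsilon$,
with purity ~ Beta(2, 2), latent stemness activity $a_i$ ~ N(0, 1) drawn
**independently** of purity, stemness genes elevated +2 in the tumor
profile, stromal genes +3 in the stromal profile, noise sd 0.3. Survival is
exponential with log-hazard
$\beta_\text{stem}\,z(a) + \beta_\text{strom}\,z(1-p)$, defaults 0.5 and
1.0 per SD — both *harmful*. Censoring is uniform administrative censoring
whose horizon is solved by `uniroot` so the expected censored fraction
equals `censor_rate` (0.3). A two-level subtype label is drawn with
log-odds 1 per SD of activity.

This is the documented generator setting for the confounding demonstration:
because activity and purity are independent, any anticorrelation between
stemness and stromal *scores* — and the univariate-protective /
multivariate-harmful sign flip of the stemness coefficient — can only come
from the purity mixing, which is precisely the mechanism the package is
built to expose. The stromal beta is set above the stemness beta so the
purity channel dominates the univariate fit decisively.

What the generators deliberately do **not** emulate: probe-level microarray
artifacts, heavy-tailed or heteroscedastic noise, a separate immune
component (stromal and immune signatures behave concordantly in bulk
tumors, so one non-tumor component suffices for testability), copy-number
structure, or informative censoring. Passing tests therefore demonstrate
correctness of the statistical machinery under a clean generative model,
not robustness to every failure mode of real cohort data.

## Survival analysis

* Median split (`dichotomize`) with `high = score > cutoff`; the cutoff is
  recorded. A quantile rule is exposed; all-equal scores and empty-side
  splits are errors, not silent degeneracies.
* Log-rank and Kaplan–Meier estimates come from the `survival` package; a
  group with zero events is an error advising a merge.
* Cox fits use Efron tie handling (better than Breslow under heavy ties,
  and equal to it without ties), Newton iterations to a 1e-10 tolerance,
  at most 100 iterations; non-convergence and monotone-likelihood
  (separation) warnings are promoted to errors. Covariates are z-scored by
  default so hazard ratios are per SD and comparable across tumor types;
  a single-covariate binary fixture in the tests pins the estimate against
  a brute-force 1-d partial-likelihood maximization.
* `pan_cohort_cox()` fits each cohort independently; a failing cohort is
  skipped with its reason logged, never silently dropped.

## Other numerical conventions

* Tie-breaks are lexicographic (radix order, locale-independent) wherever an
  ordering must be deterministic: top-variable gene selection, signature
  ordering, ssGSEA walk order, kNN distance ties (smaller sample index).
* kNN vote ties fall back to the single nearest neighbour's class. Under
  label permutation, LOOCV accuracy centres slightly *below* 0.5 for
  balanced labels (excluding the held-out sample leaves its own class
  under-represented among the neighbours); the tests assert chance-level
  behaviour with that bias in mind.
* Duplicate gene rows collapse to the maximum-variance row, with a warning
  (the most informative probe, as in common microarray practice);
  `collapse = "error"` forbids it.
* All generators set the RNG seed from their truth object; identical truth
  gives bit-identical output, and `run_pipeline()` seeds once up front so
  reruns are byte-identical.

## Problem sizes

The simulation-backed checks use 2000 genes × 12 samples for sorted
experiments (50 seeds), a 2000-gene × 400-sample cohort for the confounding
demonstration, 1000 null cohorts of n = 60 for the log-rank type-I rate,
and 200 cohorts of n = 1000 for Cox recovery — sizes at which the
Monte-Carlo error of each reported rate is well below the margin being
asserted, while the full suite stays fast.

## Known limitations

* The SNR derivation offers no moderated-variance or FDR machinery — the
  thresholding convention is the point; use limma if you want shrinkage.
* ssGSEA here has no permutation p-values and no GSVA-style kernel variant.
* The clinical dispatch table (which test for which feature) is
  config-driven rather than inferred; supplements that specify per-feature
  tests can be mirrored exactly by overriding `test =`.
* Purity is consumed as a given covariate; estimating it from expression is
  out of scope.
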