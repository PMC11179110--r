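---
title: "Methods: extracting g and relating it to connectome organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: extracting g and relating it to connectome organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gconnect)
```

## Overview

`gconnect` implements a complete analysis chain for studying a general
cognitive ability factor — Spearman's *g* — in a two-group (patient/control)
design, together with graph-theoretic analysis of resting-state functional
connectomes. The chain has four analytic stages plus a synthetic-data
generator that makes every stage testable without access to any clinical
cohort:

1. **Psychometrics.** *g* is extracted from a multi-test battery by
   exploratory factor analysis and scored per subject.
2. **Group statistics.** Groups are compared on *g* and on individual tests
   with pooled effect sizes and permutation tests; a two-class Fisher
   discriminant provides the "best possible" linear separator against which
   *g* is benchmarked; independent measures are residualized on *g*.
3. **Connectome graph theory.** Subject connectivity matrices are thresholded
   with a spanning-tree backbone and summarized by normalized global metrics
   and the participation coefficient, with corrected group tests and
   per-group PC–*g* correlations.
4. **Pipeline.** A single seeded configuration drives all stages and emits a
   reproducible report bundle.

## The measurement model for g

The battery is modelled as a single-common-factor linear model: for subject
$i$ and test $j$,

$$x_{ij} = \lambda_j f_i + \varepsilon_{ij}, \qquad
f_i \sim N(\mu_{g(i)}, 1), \quad \varepsilon_{ij} \sim N(0, \psi_j),$$

so the population correlation matrix of the tests is
$\Sigma = \Lambda\Lambda' + \Psi$ — the "positive manifold" of uniformly
positive inter-test correlations. The model is estimated by **minimum
residual (ULS)** factoring: uniquenesses are optimized (L-BFGS-B) to minimize
the sum of squared off-diagonal residuals between the observed and implied
correlation matrices, with loadings obtained from the leading eigenvectors of
the reduced correlation matrix. Minres was chosen over maximum likelihood
because it requires no distributional assumption and is the common default in
exploratory practice; on an exactly-one-factor input it reproduces the
planted loadings to numerical precision (tested to 1e-4).

Supporting diagnostics and decisions:

* **Sampling adequacy.** The Kaiser–Meyer–Olkin index compares squared
  correlations with squared anti-image partial correlations (values above
  0.8 are conventionally "meritorious"); Bartlett's sphericity test checks
  that the correlation matrix departs from identity. Both are reported, never
  gated on.
* **Factor count.** Velicer's minimum-average-partial (MAP) test with both
  the squared (1976) and fourth-power (2000) criteria. The count actually
  used downstream is the 1976 answer, overridable via `n_factors` — in a
  general-ability analysis the expected and typical answer is 1.
* **Rotation.** For a single factor rotation is a no-op (sign fixed so the
  loading sum is positive). When more than one factor is retained, an oblique
  quartimin rotation via the gradient-projection algorithm is applied;
  obliqueness is the defensible default for cognitive data where factors
  correlate.
* **Scores.** Thurstone regression scores $W = R^{-1}\Lambda\Phi$, computed
  on the combined sample (patients and controls together) and standardized
  there. The per-factor score validity is
  $\sqrt{\mathrm{diag}(\Phi\Lambda'R^{-1}\Lambda\Phi)}$ and the multiple
  $R^2$ of scores with factors is its square; the package reports both and
  the test suite asserts the identity exactly, since the pair is a useful
  internal consistency check.
* **Fit indices.** RMSR over off-diagonal residuals and a Tucker–Lewis index
  computed from a ULS-proxy chi-square (discrepancy times the Bartlett-style
  multiplier). These are descriptive; the package deliberately does not
  threshold on them.

**Numerical choices.** Uniquenesses are bounded in [0.005, 1]; a solution on
the lower bound is a Heywood case and raises a warning rather than failing.
Pearson correlations on listwise-complete cases are used throughout.
Singular correlation inputs abort with the most collinear pair named.

## Group statistics

Effect sizes are pooled-SD Cohen's *d*, reported as positive magnitudes with
the signed mean difference kept alongside (the convention of printed
effect-size tables). Group inference uses a two-sided permutation test on the
difference in means: exhaustive enumeration when
$\binom{n}{n_1} \le 20{,}000$, otherwise 10,000 sampled permutations with the
+1 correction so p-values are valid and never zero. No family correction is
applied across cognitive measures (star-threshold reporting); corrections are
reserved for the connectome stage where the families are well defined.

The **Fisher discriminant** uses the classical shared-covariance
construction $w \propto S^{-1}(\mu_1 - \mu_0)$ with no prior reweighting
despite unequal group sizes, scaled to unit pooled within-group SD of the
projection (so the projected mean separation equals the Mahalanobis distance,
an invariant the tests check) and sign-fixed so controls score higher. A
ridge of $10^{-8}\,\mathrm{tr}(S)/p$ is added only if $S$ is numerically
singular. The comparison of interest — how strongly the discriminant
correlates with *g* versus with any single test — is exposed by
`lda_vs_g()`.

`adjust_for_g()` residualizes a measure on *g* by OLS over the combined
sample and re-runs the permutation test on residuals, quantifying variance
beyond *g*. Covariate associations use the declared test per covariate
(Pearson, Spearman, two-level *t*, or chi-squared), mirroring how mixed
clinical/sociodemographic tables are analysed.

## Connectome stage

Connectivity matrices are Fisher-*z* transforms of node-by-node temporal
correlations, symmetric with zero diagonal. Graph construction:

* **Negative weights** are set to zero before any construction
  (`negative_policy = "zero"`, with `"abs"` and `"error"` available). At the
  densities analysed, negative associations are not interpreted as edges.
* **Thresholding** is proportional with a **maximum-weight spanning-tree
  backbone**: the backbone (Kruskal on decreasing weight, lexicographic
  tie-break for determinism) is always retained, then the strongest remaining
  edges are added until exactly $\mathrm{round}(d \cdot N(N-1)/2)$ edges are
  present. Every thresholded graph is therefore connected, the stated purpose
  of the backbone; edge-count exactness and backbone containment are tested
  as hard invariants.
* **Metrics.** Transitivity (closed-to-connected triplet ratio), global
  efficiency (mean inverse shortest path), Louvain modularity $Q$, and the
  participation coefficient $PC_i = 1 - \sum_s (k_{is}/k_i)^2$ aggregated to
  unweighted parcel means. Weighted variants (geometric-mean triangle
  intensities; path lengths $1/w$ on weights rescaled to max 1) are the
  default because the thresholded matrices retain weights; binary variants
  are available via `mode = "binary"` since the field uses both and the
  choice is genuinely open.
* **Normalization.** Transitivity and efficiency are divided by their means
  over an ensemble of degree-preserving null graphs (double-edge swaps, 10
  attempted swaps per edge, weights reshuffled onto the rewired edges;
  ensemble size 20 by default). Connectivity of the null is verified after
  rewiring and the swap sequence is redrawn under a derived sub-seed in the
  rare case it was lost; a complete graph, which admits no legal swap,
  is returned unchanged with a saturation warning.
* **Louvain** is run from 100 random vertex orders by default (seeded),
  keeping the best-$Q$ partition; the tests verify it never exceeds the
  exhaustively enumerated maximum modularity on small graphs.
* **Group tests.** Global metrics: permutation tests per density with
  Bonferroni correction across densities within each metric family. Parcel
  PC: permutation tests per module with Benjamini–Hochberg FDR across
  modules. PC–*g* associations: Spearman correlations within each group
  separately, BH-FDR across modules. The default density grid for PC is
  (0.20, 0.30, 0.40); the global-metric grid is configurable.

## What the synthetic generator emulates — and what it does not

`simulate_battery()` plants exactly the measurement model above: its defaults
are an 11-test battery with heterogeneous loadings (0.48–0.70, implying a
single-factor score validity in the low 0.9s, typical of comprehensive
batteries), 79 controls and 110 patients, and a latent shift of −0.85 SD for
the patient group, sized like a moderate-to-large clinical effect on general
ability. The true latent factor is always returned so recovery is directly
testable. `simulate_connectomes()` plants block-modular correlation
matrices (default 90 nodes in 6 modules, within/between correlations
0.5/0.1, subject noise SD 0.06) with the patient group's within-module
correlation reduced by 0.1 — weaker modular segregation, which propagates to
lower normalized transitivity and $Q$ and higher participation coefficients.
Per-subject matrices are PSD-repaired by eigenvalue clipping at 1e-8 followed
by re-normalization to a unit diagonal, the simplest spectral fix.
`simulate_covariates()` draws covariates linear in the true latent factor,
with a neighbourhood-deprivation covariate emitted as a two-level
advantaged/disadvantaged category.

The generator deliberately does **not** emulate: non-Gaussian test score
distributions (the score scale is treated as standardized, and no public
evidence pins the raw distributions), hemodynamics or temporal
autocorrelation of fMRI time series, scanner/site effects, spatially
heterogeneous module sizes of real parcellations, or missing data. Passing
tests therefore certify the statistical machinery — estimation, thresholding,
normalization, calibration, power against planted effects — not the
empirical values any real cohort would produce. Cohort-specific quantities
(a real study's KMO, RMSR, TLI, discriminant–*g* correlation, specific
surviving parcels) require the raw data and are reported by the pipeline,
never asserted.

## Problem sizes and runtime choices

The test-suite and acceptance-script simulations use sizes chosen to make
the planted structure decisively detectable while keeping a full run on one
CPU in the low minutes: 90-node/6-module cohorts with 50 subjects per group
and one density for the planted-difference run (5 null graphs per subject,
10 Louvain restarts), 40 seeds for null calibration of the corrected group
tests, 30 seeds for planted PC–*g* flagging, and 100 seeds for MAP
factor-count recovery at n = 200, p = 11. The demo configuration
(`default_config()`) uses 60 battery subjects and 60 connectomes of 90 nodes
and completes in well under a minute. These are the package's own choices of
demonstration scale; all are configurable upward.

## Known limitations

* Only two-group designs are supported; the discriminant is two-class by
  construction.
* The MAP criterion is the only factor-count selector implemented (parallel
  analysis is not); the count can always be overridden.
* Permutation tests assume exchangeability under the null; no covariate-
  constrained permutation scheme is provided.
* The degree-preserving null preserves the degree sequence and weight
  multiset but not the weight-degree coupling; this is the standard
  rewiring null, and stricter nulls would change normalized values.
* `pc_g_correlation()` expects one matrix per subject; combining multiple
  acquisition runs must happen upstream.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config(seed = 7)
report <- run_pipeline(cfg)
print(report)
write_report(report, "gconnect_report")
```

The report bundle contains the adequacy diagnostics, factor model, subject
*g* scores, effect-size table, discriminant summary, covariate associations,
the density-sweep metric tables with corrected group tests, and a manifest
recording the configuration hash and every derived stage seed, so a re-run
with the same configuration is byte-identical.
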