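# gconnect

Tools for analysing a **general cognitive ability factor (Spearman's g)** in
patient–control designs, and for relating it to the graph-theoretic
organization of resting-state functional connectomes. The package is aimed at
neuropsychology and network-neuroscience researchers who have (a) a
subjects × tests cognitive score table with group labels and covariates and
(b) per-subject node × node connectivity matrices with a parcellation
assigning nodes to modules — or who want to prototype such an analysis on
synthetic cohorts with planted structure.

## What it computes

**Psychometrics.** A single-factor measurement model
`x_ij = λ_j f_i + ε_ij` is fitted to the battery by minimum-residual (ULS)
exploratory factor analysis: Kaiser–Meyer–Olkin sampling adequacy and
Bartlett sphericity diagnostics, Velicer minimum-average-partial (1976 and
2000 criteria) factor-count selection, oblique gradient-projection rotation
when more than one factor is retained, and Thurstone regression factor
scores `W = R⁻¹ΛΦ` standardized on the combined sample — the subject-level
g estimate. Score validity `√(Φ Λ' R⁻¹ Λ Φ)` and its square (multiple R² of
scores with factors) are reported together.

**Group statistics.** Pooled-SD Cohen's d
(`d = |m₁ − m₀| / s_pooled`), exact or sampled two-sided permutation tests,
a two-class Fisher discriminant (`w ∝ S⁻¹(μ₁ − μ₀)`, unit pooled projected
SD) benchmarked against g via `lda_vs_g()`, residualization of independent
measures on g, and typed covariate associations (Pearson / Spearman /
t / χ²).

**Connectome graph theory.** Fisher-z connectivity matrices are thresholded
proportionally with a **maximum-weight spanning-tree backbone** (graphs stay
connected at every density; edge count exactly `round(d·N(N−1)/2)`), then
summarized by transitivity and global efficiency (raw and divided by their
means over degree-preserving double-edge-swap null graphs), Louvain
modularity Q (seeded restarts), and the participation coefficient
`PC_i = 1 − Σ_s (k_is/k_i)²` aggregated to parcel means. Group comparisons
use permutation tests with Bonferroni correction across densities (global
metrics) and Benjamini–Hochberg FDR across parcels (PC); PC–g associations
are Spearman correlations within each group with FDR across parcels.

**Synthetic cohorts.** `simulate_battery()`, `simulate_connectomes()` and
`simulate_covariates()` generate data with planted latent structure (and
return the latent truths), so recovery, calibration and power are all
testable end to end.

## Worked example

```r
library(gconnect)
report <- run_pipeline(default_config(seed = 7))
print(report)
```

```
gconnect pipeline report
  subjects: 60 ; tests: 11
  KMO 0.79 | MAP factors 1 | RMSR 0.075 | score validity 0.94
  g effect size d = 0.857 (perm p = 0.002999); corr(g, LDA) = 0.706
  connectome: 9/9 global metric x density comparisons significant after Bonferroni
```

Reading this: the 11 synthetic tests form an adequate single-factor battery
(KMO 0.79, MAP selects 1 factor, residual correlations RMSR 0.075); the
regression g scores correlate 0.94 with the latent factor they estimate; the
patient group sits 0.857 pooled SDs below controls on g (permutation
p ≈ 0.003); the Fisher discriminant built from all 11 tests correlates 0.706
with g; and at all three densities the planted loss of modular segregation
in patients is detected on every normalized global metric after Bonferroni
correction. `write_report(report, "out_dir")` emits the full CSV/JSON
bundle, byte-identical across runs with the same seed.

A thin command-line wrapper with `simulate` / `gfactor` / `compare` /
`connectome` / `run` / `validate` subcommands is installed at
`inst/cli/gconnect.R` (`system.file("cli", "gconnect.R", package = "gconnect")`).

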