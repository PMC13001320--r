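# circage

Circadian rhythm detection and clock–senescence uncoupling analysis for
aging transcriptomes.

## The problem

Aging disrupts circadian gene expression, but often not by silencing
oscillations outright: individual clock genes can remain rhythmic while the
*relationships* between them degrade — the canonical ~12 h anti-phase
between the positive arm (*Bmal1*) and the negative arm (*Per2*) erodes,
and downstream targets such as the senescence effector *Cdkn1a* (p21)
decouple from their clock regulator. `circage` implements a relational
analysis toolkit for detecting exactly this kind of dysregulation in bulk
time-course RNA-seq (sampled at a few Zeitgeber times, e.g. ZT3/9/15/21),
in single-cell/nucleus two-gene co-expression data, and in per-gene phase
tables from upstream rhythm detectors. It is aimed at researchers studying
circadian biology, cellular senescence and aging who need tested,
reproducible implementations of these analyses.

## What it computes

* **Cosinor rhythm detection** (`fit_cosinor`, `cosinor_by_gene`).
  Per gene, the fixed-effects cosinor model
  `y = M + A·cos(2π(t − φ)/P) + ε` is fit linearly via sine/cosine
  covariates. A gene is classified circadian when the sine or cosine
  coefficient and the joint 2-df amplitude F-test are significant, the
  delta-method acrophase CI is narrower than half the cycle, and a
  simulated quantile-residual uniformity check (Kolmogorov–Smirnov against
  U(0,1)) shows no lack of fit (`quantile_residual_check`,
  `classify_circadian`).
* **Relational coupling metrics** (`above_mean_window`,
  `gene_pair_coupling`, `coupling_contrast`). Above-mean phase windows with
  0–1 normalized profiles; Pearson correlation and y-on-x regression of a
  gene pair on log(TPM+1), pooled across ZTs within age×sex groups; and
  old-minus-young contrasts of R and the intercept.
* **ε-band single-cell stratification** (`stratify_populations`,
  `population_de`, plus `qc_filter_cells`, `lognormalize`). On
  log-normalized (x = *Bmal1*, y = *Cdkn1a*) coordinates, population 2 is
  `y > x + ε`, population 3 is `y < x − ε`, population 1 the coupled band in
  between; populations are compared by Wilcoxon rank-sum tests with BH FDR
  and avg_log2FC thresholds (±0.3).
* **Differential variability** (`differential_variability`, `dv_by_gene`).
  Brown–Forsythe (Levene-type, median-centred) F-statistic for age-related
  variance inflation.
* **Circular phase-set enrichment** (`pathway_phase_enrichment`,
  `compare_age_groups`). ECHO-style phases standardized to the 24 h circle
  (`phase_h = (hours_shifted mod P)·24/P`), per-pathway Rayleigh tests
  (`Z = n·R̄²`, unweighted), amplitude-weighted circular mean phases
  `h̄ = 24·atan2(Σwᵢ sinθᵢ, Σwᵢ cosθᵢ)/(2π)`, BH FDR across pathways with
  ≥10 overlapping genes, and signed circular age shifts
  `Δh = ((h_old − h_young + 12) mod 24) − 12` categorized as Both /
  Young only / Old only.
* **Synthetic study generator** (`simulate_bulk_timecourse`,
  `simulate_cell_pairs`, `simulate_phase_table`). Seeded simulators that
  emulate the study design end-to-end with ground truth, including
  configurable age effects (phase jitter, senescence baseline shift,
  variance inflation, decoupling noise).
* **Pipeline orchestration** (`run_pipeline`, `demo_pipeline`). All stages
  in dependency order, with a JSON manifest of artifacts, parameters, seed
  and md5 checksums; reruns under the same seed are checksum-identical.

## Worked example

```r
library(circage)

sim <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 5, frac_rhythmic = 1,
                                                n_replicates = 8, seed = 42))
young <- sim$dataset$samples$age_group == "young"
fit <- fit_cosinor(sim$dataset$matrix["Bmal1", young],
                   sim$dataset$samples$zt[young], gene = "Bmal1")
fit <- classify_circadian(quantile_residual_check(fit, seed = 1))
fit
#> Cosinor fit (Bmal1) - period 24 h, 32 observations
#>   mesor 7.729, amplitude 2.25, acrophase 10.52 h (SE 0.203 h)
#>   p_sin 8.24e-08, p_cos 6.79e-17, p_amplitude 5.71e-17, resid_p 0.982
#>   classified circadian: TRUE
```

The simulated truth for this gene was acrophase 10.99 h, so the peak time
is recovered to ~0.5 h. Aging contrast of the *Bmal1*–*Cdkn1a* coupling
(correlation drops, intercept — the baseline *Cdkn1a* level — rises):

```r
res <- couple_genes(sim$dataset, "Bmal1", "Cdkn1a", group_by = "age_group")
fits <- attr(res, "fits")
coupling_contrast(fits$young, fits$old)
#> coupling contrast Cdkn1a ~ Bmal1 (old - young):
#>   R: 0.8882 -> 0.5187 (delta -0.3695)
#>   intercept: -0.03083 -> 1.858 (delta +1.888)
```

ε-band stratification of a simulated 5,000-cell mixture recovers the
planted populations almost perfectly (errors sit on the band boundary):

```r
cp <- simulate_cell_pairs(cell_sim_config(n_cells = 5000, seed = 42))
lab <- stratify_populations(cp$cells$x, cp$cells$y, epsilon = 0.5)
table(truth = cp$truth$population, called = lab)
#>      called
#> truth    1    2    3
#>     1 3452    1    0
#>     2   64  692    0
#>     3   77    0  714
```

A full end-to-end run on synthetic data (2,000 genes × 64 bulk samples,
5,000 cells, 60 gene sets, every stage) is one call:

```r
manifest <- demo_pipeline("demo_out", seed = 1)
```

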