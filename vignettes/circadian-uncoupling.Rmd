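---
title: "Methods: cosinor rhythms, clock-senescence uncoupling and circular phase-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosinor rhythms, clock-senescence uncoupling and circular phase-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circage)
```

`circage` analyses circadian dysregulation in aging transcriptomes through
*relational* metrics: instead of asking only whether individual genes
oscillate, it quantifies whether the timing relationships between genes —
the anti-phase of the clock's positive and negative arms, and the coupling
between a clock activator and a senescence effector — remain intact. This
vignette documents the statistical models, the tunable parameters, the
synthetic-data generator used to validate everything, and the numerical
and design choices that were genuinely open.

## The cosinor model

For one gene sampled at hours $t$ (Zeitgeber time, ZT), expression is
modelled as

$$y = M + A\cos\!\big(2\pi (t-\varphi)/P\big) + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),$$

with mesor $M$ (rhythm-adjusted mean), amplitude $A \ge 0$ (half
peak-to-trough) and acrophase $\varphi$ (peak time, hours). The model is
linearised as $y = M + \beta_s \sin(2\pi t/P) + \beta_c \cos(2\pi t/P)$ and
fit by least squares; then $A = \sqrt{\beta_s^2+\beta_c^2}$ and
$\varphi = \tfrac{P}{2\pi}\,\mathrm{atan2}(\beta_s,\beta_c) \bmod P$.

Assumptions and consequences:

* **Fixed effects, replicates exchangeable.** With only four timepoints per
  cycle a mixed-effects cosinor with per-animal random effects is barely
  identifiable and prone to overfitting; we deliberately use the
  fixed-effects fit treating replicates as independent. Replicate labels
  are stored by the readers but no pairing structure is exploited.
* **Period fixed at 24 h** for bulk ZT designs. Four timepoints over one
  cycle cannot identify the period; free-period fitting is out of scope.
  The period is still a parameter so simulated sensitivity checks and
  non-24 h inputs are possible.
* **Significance of the amplitude** is the joint 2-df F-test of
  $(\beta_s,\beta_c)$; individual coefficient t-tests give `p_sin` and
  `p_cos`. A "significant phase estimate" is operationalised as a
  delta-method CI narrower than half the cycle
  ($1.96\,\mathrm{SE}(\hat\varphi) < 12$ h): an acrophase whose CI covers
  the whole circle carries no timing information.
* **Zero-variance genes** get the degenerate convention $A = 0$,
  `p_amplitude = 1`, acrophase undefined — a flat gene is never circadian.

Across-gene multiple testing is available in two modes: raw $\alpha$ per
gene (default) or BH adjustment of `p_amplitude` within each group
(`adjust = TRUE` in `cosinor_by_gene()`); both are provided because
rhythm-detection practice varies and neither choice is forced by the
classification rule itself.

### Simulated quantile residuals

Model adequacy is checked with a parametric analogue of simulated quantile
residuals for the Gaussian model: `n_sim` (default 250) response sets are
drawn from the fitted model, each observation's quantile among its
simulations is computed, and the quantiles are tested against U(0,1) with
a one-sample Kolmogorov–Smirnov test. A gene whose `resid_p` falls at or
below the threshold (default 0.05) is not classified circadian, however
strong its harmonic terms.

Because the simulation uses parameters estimated from the same data, the
check is conservative (observed rejection under a well-specified model is
below nominal — the suite verifies $\le 7\%$ at $\alpha=0.05$). Its power
against timepoint-dependent variance is correspondingly modest at small
$n$: with 10-fold noise inflation at two of four timepoints, detection
reaches ~80% only around two dozen replicates per timepoint. That size is
what the power test uses; users of 3-replicate designs should read
`resid_p` as a guard against gross misfit, not a sensitive diagnostic.

## Relational metrics on bulk data

**Above-mean phase windows.** Per gene, per-ZT means across replicates are
min-max normalised to [0, 1]; the window is the set of ZTs whose mean
strictly exceeds the cycle mean. Strict inequality makes the constant-gene
case well defined (empty window, all-zero profile) and the window invariant
to positive rescaling of expression.

**Pairwise coupling.** For a gene pair $(x, y)$ the package reports
Pearson's $R$ with its two-sided t-test p-value and the OLS slope and
intercept of $y$ on $x$, after an optional $\log(v+1)$ transform (the
default, since these analyses are conventionally run on log(TPM+1)).
Orientation matters and is fixed: $y$ is the downstream/senescence gene,
$x$ the clock gene, so the intercept is interpretable as the baseline level
of the senescence gene when clock expression is at its (log) origin.
Samples are pooled across ZTs within an age×sex group — the coupling is a
property of the whole cycle, not of one timepoint. A per-ZT-means mode
(`per_zt_means = TRUE`) is available because published scatter plots can be
drawn either way; per-sample points are the default since they retain the
full $n$. The age contrast is simply old-minus-young differences of $R$ and
the intercept. Published correlation values from any particular animal
cohort are cohort-specific; the package asserts (and its tests verify) the
*directions* — $|R|$ decreasing and intercept increasing with age under
decoupling — not magnitudes.

## Single-cell stratification

Cells pass QC if none of the rules fire: `detected_genes < 200`,
`> 6000`, `umi < 500`, `> 25000`, `mito_frac > 0.10`,
`ribo_frac > 0.25` (strict inequalities; a cell exactly at a limit is
kept). Counts are log-normalised as
$\ln(1 + c \cdot s / \text{total})$ with scale $s = 10^4$.

On log-normalised coordinates the three populations are

* population 2: $y > x + \varepsilon$ (high senescence gene relative to
  clock gene),
* population 3: $y < x - \varepsilon$ (the mirror),
* population 1: the band $|y - x| \le \varepsilon$ around the diagonal.

The inequalities are strict, so boundary cells fall in population 1, the
partition is exhaustive and exclusive, and labels are invariant to adding
a common constant to both coordinates. The band half-width
$\varepsilon$ has no canonical published value; the default 0.5 log-units
was chosen once so that the three-population geometry is cleanly
reproducible on the package's synthetic mixtures, and it is a top-level
argument everywhere it appears. The diagonal is literally $y = x$; an
analysis preferring a data-driven axis can pre-rotate coordinates, but no
such estimation is built in, keeping the rule transparent.

Population DE uses two-sided Wilcoxon rank-sum tests (normal approximation
with average ranks and continuity correction), BH FDR, and
`avg_log2FC` = difference of group means of log2-scale values; direction
calls require both FDR < 0.05 and $|\text{avg\_log2FC}| \ge 0.3$. The two
anchor genes are retained in DE output (the senescence gene appearing "up"
in population 2 is expected by construction).

## Differential variability

Age-related variance inflation is tested per gene with the Brown–Forsythe
statistic: absolute deviations from each group's median, then a one-way F
with df $(1, n_a+n_b-2)$. This is a plain, unmoderated test — no
empirical-Bayes shrinkage or precision weighting — chosen for transparency
and because its null behaviour is easy to verify (the suite checks null
p-value uniformity and that planted 3× noise-SD inflation is detected well
above the type-I rate). If both groups' deviations are constant the
statistic is 0 and $p = 1$.

## Circular phase-set enrichment

Upstream rhythm detectors report a per-gene peak offset ("hours shifted")
and period. Phases are standardised to the 24 h circle as
$h = (\text{hours shifted} \bmod P)\cdot 24/P$. If a particular upstream
build emits the negated sign convention, `negate_phase = TRUE` flips it;
the convention is not otherwise guessed. A row filter
(`filter_circadian_calls()`) implements the stringent call thresholds used
for fibroblast-style tables: period 20–28 h, $|AC| > 0.15$, $p < 0.05$,
BH- and BY-adjusted $p < 0.01$.

Per pathway (gene sets intersected with the phase table, retaining sets
with $\ge 10$ overlapping genes):

* **Rayleigh test**, unweighted: $\bar R = |\sum e^{i\theta_j}|/n$,
  $Z = n\bar R^2$, with the classical series approximation for $p$. The
  amplitude weights deliberately do **not** enter the test — they would
  change its null distribution — only the mean phase.
* **Weighted circular mean**:
  $\bar\theta = \mathrm{atan2}(\sum w_j \sin\theta_j, \sum w_j\cos\theta_j)
  \bmod 2\pi$, $\bar h = 24\bar\theta/2\pi$, with the initial amplitude as
  a nonnegative weight. A numerically zero resultant (perfect antipodal
  cancellation) returns an explicit undefined-mean status instead of an
  arbitrary angle.
* **BH FDR** across retained sets; FDR < 0.05 flags significant phase
  clustering.

Age contrast: pathways present in both groups get the shortest signed
circular difference $\Delta h = ((h_{old} - h_{young} + 12) \bmod 24) - 12
\in [-12, 12)$; pathways significant in at least one group are retained and
categorized Both / Young only / Old only. An exact half-cycle shift maps to
$-12$ — a consequence of the half-open range of the formula, documented
rather than symmetrised so that the reported value is always exactly the
formula's.

The series approximation for the Rayleigh p-value is accurate for the
$n \ge 10$ sets the overlap filter admits; the suite verifies calibration
(empirical type-I within [0.035, 0.065] at $\alpha = 0.05$, $n = 50$).

## The synthetic-data generator

The generator exists so every stage can be validated against known truth;
its defaults are the emulated study conditions, chosen once:

* **Bulk**: 4 timepoints (ZT3/9/15/21) over 24 h, 8 replicates per
  timepoint per age group (64 samples), 30% rhythmic genes, mesor
  U(4, 8), amplitude U(1, 3), Gaussian noise SD 0.5 on the expression
  scale, truncated at zero. Role genes default to *Bmal1* (positive arm),
  *Per2* (negative arm, +12 h), *Cdkn1a* (senescence, sharing the
  positive-arm acrophase) but are configuration, not hard-coded symbols.
* **Age effects** (old samples only): phase jitter SD 2 h on the negative
  arm (eroding anti-phase), senescence baseline shift of 1 log-unit
  (multiplying the deterministic signal by $e^1$ — additive on the log
  scale the coupling analysis uses), noise-SD inflation ×3 on a 10% gene
  subset, and independent decoupling noise (SD 1.5) on the clock-senescence
  pair. No published effect sizes exist for these; values were chosen for
  testability — large enough that 100-seed directional checks are stable,
  small enough that rhythms remain detectable.
* **Cells**: 5,000 cells, weights (0.7, 0.15, 0.15), planted band 0.5
  log-units, per-coordinate noise SD 0.1. Populations 2/3 are offset beyond
  the band by a strictly positive exponential margin, so the noise-free
  mixture is exactly recoverable and, with noise, misclassification is
  confined to within $3\sqrt{2}\sigma$ of a band boundary ($\sqrt{2}\sigma$
  being the SD of the noise on $y - x$).
* **Phase tables**: 60 disjoint sets of 30 genes; half clustered
  (wrapped-normal SD 1 h around a set-specific centre), half uniform;
  a `center_shift` argument produces paired young/old tables with a known
  circular shift.

What the generator does **not** emulate: count noise and TPM
normalisation artefacts, batch effects, animal-level correlation,
cell-type structure, doublets, ambient RNA, or realistic gene-gene
correlation beyond the configured pairs. Passing tests therefore
demonstrate correctness of the statistics under their stated models and
the qualitative aging directions, not performance on any real cohort.

## Numerical choices and degenerate inputs

* Identical seeds give bit-identical generator output; all randomness
  flows through one seeded generator per call and the caller's RNG state
  is restored.
* `fit_cosinor` is exact (to ~1e-12; tests assert 1e-8) on noise-free
  cosinor data for any $(M, A, \varphi, P)$ with $\ge 3$ distinct
  timepoints; rank-deficient designs (< 3 distinct times) are errors.
* The vectorised per-group fitter shares one design-matrix factorisation
  across genes and is verified against per-gene `lm()` fits to 1e-10.
* ZT is half-open in [0, 24); values in [24, 48) wrap with a warning,
  beyond that is an error. Boundary conventions elsewhere (QC, ε-band,
  above-mean windows, $\Delta h$) are strict and documented at each
  function.
* BH adjustment wraps the standard step-up implementation and is checked
  against a brute-force oracle to 1e-12.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
these sizes, chosen to make the statistical assertions stable: 2,000 genes
for type-I calibration; 500 genes for parameter recovery; 2,000 replicates
for Rayleigh calibration; 200 uniform sets for enrichment family
calibration; 100 seeds for directional aging checks; 3,000-cell mixtures;
and a full demo pipeline at 2,000 genes × 64 samples, 5,000 cells and 60
gene sets that completes in a few seconds and is checksum-identical across
reruns under a fixed seed.

## Limitations

* No count-likelihood (negative binomial) cosinor; inputs are assumed
  roughly variance-stabilised (TPM or log-normalised).
* No mixed-effects rhythm modelling or batch correction; those belong
  upstream.
* The upstream oscillator fit that produces phase tables is consumed, not
  reimplemented; its sign convention must be supplied by the user.
* The ε-band rule is intentionally simple; it does not model
  expression-magnitude-dependent dispersion around the diagonal.
* Directional aging properties are validated on the generator's model of
  aging, which is a caricature of real transcriptomes.
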