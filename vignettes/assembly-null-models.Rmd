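---
title: "Methods: dispersion, null models and the synthetic immigration gradient"
author: "betadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dispersion, null models and the synthetic immigration gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind `betadev`,
in the spirit of the methods sections of the ordination and
community-ecology packages it builds on.

## 1. The scientific question

An experiment that feeds replicate hosts a defined bacterial mix across a
wide dilution series manipulates **immigration** — the number of individuals
arriving from a fixed species pool — while holding pool composition
constant.  Two assembly forces then shape among-host variation:

* **Drift**: with few founders, which taxa establish and how they fluctuate
  is dominated by demographic chance; hosts diverge unpredictably.
* **Selection**: with many founders, all taxa establish and within-host
  fitness differences deterministically drive the same winner everywhere;
  hosts converge.

Observed beta-diversity confounds these forces with sampling: groups whose
hosts contain fewer individuals or fewer taxa show more among-host variation
for purely combinatorial reasons.  The package therefore pairs a dispersion
estimate of beta-diversity with an abundance-constrained null model, and
reports the standardized deviation between them.

## 2. Beta-diversity as multivariate dispersion

For a group of $n$ samples with relative-abundance profiles $p_i$:

1. **Dissimilarity.** Bray–Curtis,
   $d(x,y) = 1 - 2\sum_k \min(x_k,y_k) / (\sum_k x_k + \sum_k y_k)$,
   computed with `vegan::vegdist()`.  On profiles that sum to one this
   equals half the $L_1$ distance — the identity is asserted in the tests.
2. **Square-root transform** (default on).  Bray–Curtis is semimetric; its
   principal-coordinate decomposition can have negative eigenvalues, and
   large imaginary parts clamp dispersion estimates to zero (step 5).  The
   element-wise square root is monotone (group ranks are unchanged) and
   empirically reduces the negative spectrum; the tests check the count of
   negative eigenvalues never increases on random tables.
3. **Principal coordinates.** Gower double-centering of $-D^2/2$ and a
   symmetric eigendecomposition.  Axes with $\lambda > 0$ are real
   coordinates scaled by $\sqrt{\lambda}$; axes with $\lambda < 0$ are kept
   as an *imaginary block* scaled by $\sqrt{|\lambda|}$, so that for every
   pair the squared input dissimilarity equals squared real distance minus
   squared imaginary distance.  This reconstruction identity is the
   correctness oracle for the decomposition (tolerance $10^{-6}$).
   Eigenvalues with $|\lambda| \le 10^{-8}\max|\lambda|$ are treated as
   numerical zeros and dropped.
4. **Spatial median.** The group center is the geometric median — the point
   minimizing summed distances to the group's points — computed *per block*:
   once on the real axes, once on the imaginary axes.  A joint objective
   under the subtractive metric would be unbounded below (moving the center
   to infinity along an imaginary axis clamps every distance to zero), so
   the per-block formulation is the only well-posed reading, and it is also
   what `vegan::betadisper(type = "median")` computes.  The solver is a
   damped Weiszfeld iteration started at the coordinate-wise median,
   stopping when the center moves less than $10^{-10}$ (at most 1000
   iterations); iterates that land on a data point are nudged by flooring
   distances at $10^{-12}$.  Degenerate cases are resolved
   deterministically: $n=1$ returns the point, $n=2$ the midpoint (the
   symmetric representative of the minimizer, which is non-unique on a
   segment).
5. **Distances and adjustments.** Each sample's distance to the center is
   $z_i = \sqrt{\max(0,\, d_{real}^2 - d_{imag}^2)}$ — negative squared
   distances are clamped at evaluation time, never inside the
   eigendecomposition.  With the (default) bias adjustment each $z_i$ is
   multiplied by $\sqrt{n/(n-1)}$, offsetting the downward bias of
   dispersion in small groups.  The group's beta is the mean $z_i$.

`beta_dispersion()` runs one ordination of *all* samples and computes group
centers within it (the `betadisper` convention, convenient for plotting and
per-sample tables).  The tests verify it against two independent oracles:
direct geometric computation in original coordinates for Euclidean point
clouds, and `vegan::betadisper(type = "median", bias.adjust = TRUE,
sqrt.dist = TRUE)` for Bray–Curtis tables.

A `center = "centroid"` option exists because the field's terminology mixes
"centroid" and "spatial median"; the spatial median is the default as it is
the robust estimator normally intended.

## 3. The abundance-constrained null model

`beta_deviation()` asks, per group: *is the observed dispersion different
from what stochastic sampling of the pool would produce, given what each
host demonstrably contains?*  Each null replicate rebuilds every host
community under two exact constraints — observed richness $S$ and observed
community size $N$ (total 16S copy number) — by:

1. drawing $S$ taxa without replacement, probability proportional to the
   pool's relative proportions (equal, for the motivating design);
2. giving each selected taxon one founding individual;
3. distributing the remaining $N-S$ individuals multinomially over the
   selected taxa (renormalized pool proportions).

This founding-individual scheme satisfies both constraints exactly in a
single pass, with no rejection sampling (a richness-conditioned rejection
scheme would stall whenever $N$ is large and $S$ small).  Every null
replicate is re-analysed by the *identical* dispersion pipeline as the
observed data (same transform, center and adjustment flags), and

$$\mathrm{SES} = \frac{\beta_{obs} - \overline{\beta}_{null}}
{\mathrm{sd}(\beta_{null})},$$

with the standard deviation of the null *distribution* (denominator
$R - 1$), not the standard error of its mean — the conventional SES scale on
which $|\mathrm{SES}| > 2$ marks a large departure.  A null SD of zero
(e.g. $S = k$ and $N = S$ for every host, forcing a single possible
community) is flagged `degenerate` and SES is reported as `NA`, never
$\pm\infty$.

Two design choices worth making explicit:

* **Per-group ordinations.** Observed and null betas inside
  `beta_deviation()` are computed from each group's own samples (the
  group-subset dissimilarity matrix and its own embedding).  This makes the
  observed value and its null distribution strictly exchangeable — the null
  replicates cannot be influenced by unrandomized samples from other
  groups — at the cost that the observed beta can differ in the last
  decimals from the shared-ordination value reported by
  `beta_dispersion()` when the input is strongly non-Euclidean.
* **Constraint integerization.** Copy-number-scaled abundances are real
  valued; the null model needs whole individuals.  `integerize()` rounds to
  the nearest integer but keeps at least one individual for any taxon with
  positive abundance, so observed richness survives rounding and the
  richness constraint is well defined.  Rounding happens only here, at the
  null-model boundary; all other stages stay real-valued.
* **Reproducible substreams.** The master seed is hashed with each group
  label into an independent substream, so adding or removing a group never
  changes another group's null draws; results are bit-reproducible given
  `(seed, n_reps, tables)`.

Under data generated by the null process itself, SES is calibrated:
distributionally close to standard normal, so its mean across groups is
near zero and roughly 5% of groups exceed $|SES| > 1.96$.  Note the
precision of any such check scales as $1/\sqrt{\#groups}$ — with 20 groups
the Monte-Carlo standard error of the mean SES is about 0.22, so small
nonzero means are expected in any single calibration run.

## 4. The synthetic experiment generator

`simulate_study()` emulates the statistical structure of the motivating
design, with defaults chosen once to match its stated conditions:

| parameter | default | rationale |
|---|---|---|
| `n_taxa` | 5 | five focal families at equal pool proportions |
| `base_density` | 1.69e5 CFU/uL | top-treatment inoculum density |
| `dilution_exponents` | 0 … −5 | six treatments spanning five orders of dilution |
| `replicates_per_cell` | 7 | the experimental cells held 5–9 hosts |
| `colonization_scale` | 2 uL | the inoculum dose volume; expected propagules = dose × density × proportion |
| `establishment_prob` | 0.3 | survival of ingestion/gut passage; chosen so the lowest treatment colonizes only sporadically while mid treatments colonize reliably |
| `growth_rate` | 2 per generation | generic doubling for gut bacteria |
| `selection` | 0 | drift is the neutral reference; selection regimes set it explicitly |
| `drift_size` | 2000 | ceiling of the per-generation resample; communities below it are resampled at their own size |
| `carrying_capacity` | 1e5 | cap on deterministic growth before resampling |
| `n_generations_between_stages` | 12 | ~10 days of development at roughly a generation per day, plus initial establishment growth |
| `measurement_noise` | 0.1 (sdlog) | qPCR-like multiplicative noise; no error model was stated, this is a typical assay CV |

**Colonization** draws per-taxon propagules as Poisson with the mean above,
thinned binomially by establishment — so, conditional on its total, a
founding community is a multinomial sample of the pool, which is exactly
the process the null model assumes.  **Ontogeny** then iterates
growth-then-resample (a Wright–Fisher-with-selection scheme): counts are
multiplied by per-taxon fitness factors, proportionally rescaled if the
total would exceed the carrying capacity, and the next generation is drawn
multinomially with $\min(\texttt{drift\_size}, \text{total})$ individuals.
The $\min$ makes the *effective community size* emerge from immigration:
small founding populations are resampled at their own size and drift hard,
large ones are buffered — the central mechanism the design manipulates.
With equal fitness the expected composition is invariant under both steps
(a martingale), so composition changes only by drift; extinct taxa stay
extinct.  **Destructive sampling** is modeled explicitly: 3rd-instar and
5th-instar samples come from different hosts of the same treatment, as in
the experiment, so stages are linked by treatment, not by individual.

What the generator deliberately does **not** capture: naturally acquired
non-focal taxa are off by default (turning `background_taxa` on generates a
log-normal background community that exercises the focal-subsetting and
exclusion paths); there is no host immune feedback, no strain-level
evolution, and no quantified molt bottleneck; and — like the experiment
itself — the instar axis is confounded with elapsed time, so "stage
effects" and "time effects" are inseparable by construction.  Consequently,
passing tests demonstrate the *analysis machinery* (calibration under
drift, detection of imposed selection, exact constraint preservation), not
the realism of any particular biological parameter value.

In the drift regime at strong dilution, many hosts are never colonized;
they carry no focal reads and are excluded (and logged) by
`subset_focal()`, exactly as empty sequencing libraries would be.  Groups
reduced below $n = 2$ are skipped with a warning.  One consequence worth
noting: *raw* dispersion can decline with immigration even without
selection, because low-immigration groups have lower richness and smaller
communities — this is precisely the sampling artefact the null model
controls for, and why the drift-vs-selection contrast is made on SES, not
on raw beta.

## 5. Problem sizes used by the test suite

The suite favors many small, seeded configurations: random tables of 4–12
samples and 4–10 taxa for the metric and ordination oracles; 1000-draw
constraint and moment checks for the null sampler; a 20-group × 8-host ×
500-replicate calibration of SES under the null; paired selection/drift
studies of 6 treatments × 2 stages × 8 hosts analysed with 200 null
replicates; and 2000-run martingale checks for the within-host dynamics.
These sizes give stable Monte-Carlo margins (3 standard errors for moment
checks) while keeping a full run in the low minutes on one core.

## 6. Known limitations

* The GLMM stage of a full analysis (immigration × instar effects with
  plant/lineage random effects) is intentionally out of scope;
  `model_input.csv` is formatted for `lme4`/`glmmTMB`-class software.
* No PERMDISP permutation test or PERMANOVA is provided; dispersion is
  exported for regression-style modeling, not tested for homogeneity.
* The null model is abundance-based; no incidence-only (Raup–Crick style)
  variant is implemented.
* Whether richness should be preserved per host or resampled per group is
  ambiguous in the field's descriptions of this null; the package preserves
  each host's observed richness, the literal and stricter reading.
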