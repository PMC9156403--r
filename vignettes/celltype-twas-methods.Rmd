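---
title: "Cell-type-specific TWAS by deconvolution: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific TWAS by deconvolution: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decontwas)
```

# The analysis problem

Bulk blood transcriptomes are mixtures. A case-control difference confined
to one cell type is diluted by the other cell types, can cancel against an
opposite-signed difference elsewhere, and is invisible when the affected
population is rare. `decontwas` implements the statistical-deconvolution
route around this: estimate cell-type proportions per sample from bulk DNA
methylation against a reference panel, then test case-control differences
*per cell type* through an interaction regression on the bulk signal — no
cell sorting or single-cell assay required. Downstream stages interpret the
per-transcript results: pathway enrichment that respects the correlation of
neighbouring markers, a causal-mediation scan for genetic regulators of the
case-associated transcripts (deQTLs), and concordance statistics against
external result sets.

# Models

## Proportion estimation

For each sample the bulk methylation profile over the CpGs shared with the
reference panel is modelled as a convex combination of the per-cell-type
mean profiles: minimise $\lVert m - Rw\rVert^2$ subject to $w \ge 0,\ \sum_c
w_c = 1$. The default estimator is non-negative least squares followed by
renormalisation onto the simplex. Enforcing the sum-to-one constraint inside
the solve (a weighted augmented-row formulation, `method = "sum1"`) is
available; on well-conditioned references the two agree to numerical
precision, which the test suite checks on exact mixtures.

## The cell-type interaction model

With proportions $P_c$ and case status coded 0/1, every transcript's bulk
abundance is regressed, without an intercept, on

$$Y^{bulk} = \sum_{c=1}^{n_c} m_c P_c \;+\; \sum_{c=1}^{n_c}
  m_c^{case}\,(\mathrm{case} \times P_c) \;+\; \text{covariates} + E .$$

Because the proportions sum to one, the model needs no constant (dropping
one proportion and adding an intercept is the same model; the package keeps
the symmetric no-intercept form). The interaction coefficient $m_c^{case}$
estimates the case-control difference of the cell-type-$c$ mean, tested with
a two-sided $t$ statistic on residual degrees of freedom. All transcripts
share one design matrix, so the whole transcriptome is fitted from a single
QR decomposition. Covariates enter as plain additive columns, not interacted
with proportions. With a single cell type and $P \equiv 1$ the model
collapses *exactly* to the ordinary two-group comparison; the suite asserts
numerical equality with the classical $t$-test.

Multiple testing uses Benjamini-Hochberg q-values, computed separately per
cell type and for the bulk analysis, with significance at $q < 0.1$. A
Storey-type $\pi_0$-rescaled variant is available behind a flag; BH is the
default because it is deterministic and assumption-light. Calibration is
monitored with the genomic-inflation factor
$\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$ and with full TWAS reruns
under case-label permutation (`permutation_calibration()`), whose average
$\lambda$ should sit near 1.

## Pathway enrichment by circular permutation

Markers (transcripts) are mapped to genes whose intervals are extended by a
10 kb strand-aware upstream flank (promoters); a marker may map to several
overlapping genes, and a gene is a "top gene" when at least one of its
markers passes the $q < 0.1$ rule, counted once. Per pathway with at least
three genes in the universe, Cramér's V of the 2×2 table (top gene ×
pathway membership) is the enrichment statistic. The null rotates the
ordered top-marker indicator around a genome-wide circle (chromosomes
concatenated in sorted order; per-chromosome rotation behind a flag) —
rotation preserves the number of top markers and the local correlation of
neighbouring markers, and automatically accounts for gene size. The p-value
is the fraction of rotations with V at least the observed value, ties
included, floored at $1/n_{perm}$ because a permutation p of exactly zero is
unreportable. Family-wise error control at $\alpha = 0.05$ uses the
Westfall-Young single-step max-V distribution from the same rotations
(Bonferroni behind a flag — the lighter choice when pathways are few).
Significant pathways are clustered by Louvain community detection on the
Jaccard-similarity graph (edge threshold 0.25, fixed seed); none of the
clustering constants are sharp, they only organise the report.

Two numerical properties worth knowing: with small gene universes V takes
few distinct values, and because ties count toward the upper tail the null
p-values are *conservative*, not uniform — valid ($P(p \le \alpha) \le
\alpha$) but discrete. And when markers are exchangeable (no spatial
structure), the rotation null converges to the gene-label permutation null
as the circle grows; the suite verifies both properties.

## Regulation scan (mediation)

The scan asks whether a marker (SNP, CpG or hormone) acts on case status
*through* a differentially expressed transcript. Candidates need a nominal
case-status association ($p < 0.05$, OLS of the marker on status) and — for
positional markers — a location within the gene body ± 10 kb
(strand-agnostic). For every candidate gene, all annotated transcripts with
expression data are tested. Covariates are regressed out of markers and
mediators beforehand; case status is never residualised, and markers are
never regressed on the mediator or the outcome, preserving the
instrumental-variable asymmetry that gives SNP findings their causal
reading.

Per pair, the mediator model is linear (mediator ~ marker) and the outcome
model logistic (status ~ mediator + marker); the logit link is the standard
choice for a binary outcome in this quasi-Bayesian framework. Inference
draws parameter vectors from each model's asymptotic normal distribution
and recomputes the average causal mediation effect (ACME) per draw by
averaging potential-outcome probabilities at marker values 1 vs 0 (the
default dosage contrast), over both treatment arms. Because covariates are
residualised out first, the average over the observed sample reduces to a
one-dimensional Gaussian integral over the mediator prediction error, which
the package evaluates by deterministic quantile quadrature (101 equal-mass
normal nodes) — the same quantity the usual per-sample error simulation
approximates, with less Monte Carlo noise per draw. The p-value is
$2\min(\Pr(\text{draw} \le 0), \Pr(\text{draw} \ge 0))$; when a tail count
is exactly zero the draw count escalates tenfold through
1,000 → 10,000 → 100,000 → 1,000,000 until the p-value resolves or the
schedule ends. BH q-values over all tested pairs define the significant set
at $q < 0.1$.

One modelling caveat is prominent: per-sample *cell-type* expression is not
observable from deconvolution, so the mediator for a transcript flagged in a
cell-type context is its covariate-residualised **bulk** abundance.

## Overlap statistics

Cross-study concordance takes the best (minimum-p) transcript per gene,
ranks genes, intersects the top 5% of two result sets and applies the exact
one-sided upper-tail binomial sign test against the 50% null for shared
effect directions. The one-sided upper tail is the variant that reproduces
both published worked values this package checks (0.17 for 7 of 10, 0.92 for
7 of 19). Gene-set 2×2 enrichment cross-classifies a gene universe by query
and target membership; the odds ratio is $ad/bc$ (flagged infinite when
$bc = 0$) with a two-sided Fisher exact test.

# The synthetic cohort generator

Real cohorts of this design are access-controlled, so the package ships a
generator whose ground truth exercises every stage: Dirichlet proportions
for six blood cell types (CD8T, CD4T, B, Mono, Gran, NK), Gaussian
per-cell-type expression on a log2(TPM+1)-like scale, bulk expression as the
proportion-weighted mixture plus measurement noise, a Beta-distributed
methylation reference panel mixed by the same proportions, cis-SNPs with
per-cell-type eQTL slopes, mediation paths from SNP through transcript to
case status, and hormone levels with optional case shifts. Identical
configurations (including the seed) reproduce the dataset exactly.

Key generator decisions, made once:

* **Independent per-cell-type variation.** Per-sample expression deviations
  are independent across cell types (SD `within_sd`, default 1) — this is
  what "cell-type-specific signal" means, and a shared deviation would make
  interaction effects undetectable at any noise scale. The price is that
  the bulk residual variance, $\sigma_w^2 \sum_c P_c^2 + \sigma_b^2$, varies
  with the proportions.
* **Measurement noise dominates** (`bulk_noise_sd` default 1, on the same
  scale as `within_sd`). This is the regime in which classical homoscedastic
  OLS inference is calibrated; permuted-label average lambdas measure
  1.02-1.05 at the default settings. Shrinking `bulk_noise_sd` strengthens
  the mixture heteroscedasticity and inflates lambda (about 1.12 at
  `bulk_noise_sd = 0.25`) — a real phenomenon of mixture regressions, worth
  remembering when interpreting slightly elevated lambdas on real data.
* **Symmetric Dirichlet(1) proportions.** Every cell type is identifiable
  and statistically reachable. Real blood is far more skewed (granulocytes
  near 60%, B-cells near 6%); effects in rare cell types are accordingly
  harder in practice than in these simulations, and effect sizes here are
  chosen for test power, not biological realism — power tests plant 3-SD
  case effects, the size needed for reliable q < 0.1 detection at n = 600
  under the calibrated-noise defaults.
* **Mediation labels come from the observed mediator.** When mediation
  paths are configured, proportions and bulk expression are generated
  first and case labels are drawn from the logistic model on the *observed*
  bulk abundance of the mediator transcript (plus the direct dosage term).
  Drawing labels from a latent pre-mixture signal instead would attenuate
  the planted path roughly tenfold against the mediator the scan actually
  uses. Consequently `prop_case_shift` cannot be combined with mediation
  (labels cannot both follow the proportions and cause them); case
  proportion shifts are modelled by redrawing case rows from an
  alpha-renormalised Dirichlet, which keeps the simplex constraint.
* **Coordinates** live on two synthetic chromosomes, 0-based half-open in
  memory and 1-based inclusive on disk; SNPs and CpGs are placed inside
  transcript bodies (cycled) so cis relationships exist by construction.

What the generator does **not** emulate: count-level noise and
library-size effects, linkage disequilibrium and population structure,
correlated transcripts/co-expression modules, array probe artefacts, and
realistic blood proportion skew. Passing tests therefore demonstrate the
statistical machinery on data meeting its assumptions, not performance on
real cohorts.

# Numerical choices and degenerate inputs

* Transcript QC applies its rules sequentially in the documented order
  (depletion targets, unannotated, presence < 1% of samples with strict
  inequality, mean TPM < 1, mean TPM > 20,000); a transcript counts toward
  the first rule that removes it, so the report columns sum to the number
  removed.
* A cell type absent from all cases makes its interaction column constant;
  the transcript × cell-type result is flagged untestable (`p = NA`) rather
  than fitted, and NA p-values propagate NA q-values without shrinking the
  number of tests for the other contexts.
* Rank-deficient designs abort with the offending column names rather than
  silently dropping columns.
* Logistic outcome fits that fail to converge (separation) flag the pair
  non-converged with NA results.
* Proportion estimates that collapse to the zero vector (all-zero NNLS
  solution) fall back to the uniform simplex point.
* The permutation p floor $1/n_{perm}$ and the tie rule (ties count as
  extreme) follow the definitions above; both are asserted in tests.

# Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use cohorts of 200-600
samples, 50-2,000 transcripts, 40-60 SNPs, 120-150 CpGs, 10 label
permutations, 1,000-4,000 circular rotations, and mediation schedules
capped at 10,000 draws (the full default schedule still ends at 1,000,000);
these sizes make every property measurable with Monte Carlo error well
inside the asserted tolerances while the full suite completes in a few
minutes.

# Known limitations

* Estimated proportions enter the TWAS as fixed covariates; their
  estimation error is ignored (the deconvolution recovers truth to
  r > 0.99 under the shipped noise levels, so this is second-order here,
  but it is not nothing on real arrays).
* The interaction model's classical SEs are mildly anti-conservative when
  per-cell-type biological variance rivals measurement noise (see above).
* The mediation scan's mediator is bulk abundance even for cell-type
  findings.
* Circular permutation assumes a meaningful genomic order; it is not
  applicable to unordered marker sets (the gene-label permutation is, and
  coincides under exchangeability).
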