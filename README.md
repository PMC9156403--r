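# decontwas

Cell-type-specific transcriptome-wide association analysis (TWAS) by
statistical deconvolution, for case-control studies measured in bulk blood.

Bulk tissue mixes cell types, so a transcriptional case-control difference
confined to one cell type is diluted, cancelled, or hidden entirely in a
whole-tissue analysis. `decontwas` implements the deconvolution route
around this and the downstream analyses that interpret its results:

* **Cell deconvolution** — per-sample cell-type proportions estimated from
  bulk DNA methylation against a reference panel by constrained least
  squares (w ≥ 0, Σw = 1), plus case-control comparison and validation of
  the estimates.
* **Cell-type TWAS** — the no-intercept interaction regression

  ```
  Y_bulk = Σ_c m_c P_c + Σ_c m_c^case (case × P_c) + covariates + E
  ```

  whose interaction coefficient `m_c^case` is the case-control difference
  of the cell-type-c mean, tested per transcript × cell type with t
  statistics; Benjamini–Hochberg q-values per context (significance at
  q < 0.1); genomic-inflation lambdas and full label-permutation reruns for
  calibration. A bulk TWAS adjusted for proportions is included.
* **Pathway enrichment** — marker-level circular permutations (rotations of
  the genomically ordered top-marker vector) with Cramér's V on the
  gene-level 2×2 table as the statistic, Westfall–Young FWER control at
  α = 0.05, 10 kb strand-aware promoter flanks for marker→gene mapping, and
  Louvain clustering of significant pathways.
* **Regulation (deQTL) scan** — quasi-Bayesian causal mediation per
  (marker, transcript) pair: linear mediator model, logistic outcome model,
  ACME with Monte Carlo p-values under H0: a×b = 0, draw counts escalating
  1,000 → 1,000,000 tenfold while the p-value is unresolvable, q < 0.1
  significance; cis pre-selection (nominal case association p < 0.05 within
  gene body ± 10 kb).
* **Overlap statistics** — top-5% cross-study gene overlap, exact one-sided
  binomial sign tests on shared effect directions, and 2×2 Fisher
  enrichment of gene sets over a universe.
* **Synthetic multi-omics generator** — Dirichlet proportions for six blood
  cell types, per-cell-type case effects, eQTL and mediation paths,
  reference-panel methylation mixtures and hormone levels, all with known
  ground truth, so the entire pipeline is testable end to end.

## Worked example

Simulate a 600-sample cohort with one planted B-cell effect (3 within-cell
SD), deconvolve the methylation, and run the cell-type TWAS:

```r
library(decontwas)

cfg <- simulation_config(
  n_samples = 600, n_cases = 300, n_transcripts = 100, n_snps = 40,
  effect_map = data.frame(transcript = 1, celltype = 3, effect = 3),
  seed = 42)
ds <- simulate_cohort(cfg)

P <- estimate_proportions(ds$methylation, ds$reference_panel)
round(validate_proportions(P, ds$proportions_true)$pearson, 4)
#> [1] 0.9990 0.9992 0.9991 0.9989 0.9990 0.9989

res <- fit_celltype_twas(ds$expression, ds$phenotypes, P)
res[!is.na(res$q) & res$q < 0.1, ]
#>     transcript_id gene_id context effect    se     t        p        q
#> 114       TX00014  G00014    CD4T  -2.08 0.589 -3.54 4.37e-04 4.37e-02
#> 192       TX00092  G00092    CD4T   1.78 0.558  3.20 1.47e-03 7.35e-02
#> 201       TX00001  G00001       B   3.14 0.542  5.80 1.09e-08 1.09e-06
```

The deconvolution recovers the true proportions at r > 0.998 per cell type,
and the planted transcript surfaces in the right cell type with an effect
estimate (3.14 ± 0.54) covering the simulated value of 3. The two CD4⁺
hits are false discoveries, which a q < 0.1 threshold tolerates by design.
The B-cell context's inflation factor here is
`compute_lambda(res$p[res$context == "B"])` → 0.886 (noisy around 1 at 100
transcripts; calibration checks use 2,000).

The full pipeline (QC → deconvolution → TWAS → pathways → regulation →
overlap) runs from one configuration:

```r
run_pipeline(list(
  simulate = list(n_samples = 300, n_cases = 150, n_transcripts = 80),
  out_dir = "out", covariates = "age", seed = 1))
```

Every output file carries the package version, config hash and seed in its
header; `manifest.tsv` lists MD5 checksums, identical across reruns with
the same seed.

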