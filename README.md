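# mmpkit

Quantifying an individual's **Microbial Metabolic Phenotype (MMP)** — the
capacity of their gut microbiota to ferment specific dietary fibers into
specific short-chain fatty acids (SCFAs) — and modelling what happens to
those SCFAs in vivo.

The package is aimed at microbiome researchers working with ex vivo fecal
fermentation assays: stool slurry is spiked with a fiber (inulin, pectin,
cellulose, or nothing as control), sampled in duplicate wells at 0, 2 and
4 h, and SCFA concentrations (acetate, propionate, butyrate, in mM) are
quantified by GC-FID. `mmpkit` covers everything downstream of the
chromatograph:

- **Rate estimation** — the production rate of SCFA *s* from fiber *f* in
  donor *d* is the two-point slope of the replicate-averaged concentration
  over the linear window, control-subtracted:
  `rate(d, f, s) = [C(4h) − C(2h)]/2h − [C_ctrl(4h) − C_ctrl(2h)]/2h`,
  with replicate-agreement QC (coefficient of variation per well pair).
- **MMP construction** — the donors × (fiber:SCFA) rate matrix, z-scored
  per column across the cohort; phenotype *types* by UPGMA
  (average-linkage) clustering of donor profiles; high/low producer
  classes by the boundary-inclusive rule `high ⇔ z ≥ 0`; temporal
  stability between two visits as a 2×2 contingency of classes with an
  exact two-tailed Fisher test (point-probability rule).
- **Community analysis** — OTU-table processing in the fixed order
  *filter (< 5,000 reads) → rarefy (to lowest depth) → total-count
  normalize → optional taxonomic collapse*, Shannon diversity,
  Jensen–Shannon distance, and cross-validated random-forest prediction
  of high/low producers from relative abundances (5-fold stratified CV,
  vertically averaged ROC, impurity importances).
- **Absorption model** — a phenomenological model of in vivo SCFA fate:
  constant microbial production φ (mM/h) into the colonic lumen with
  first-order epithelial absorption at effective rate k (1/h),
  `d[B]/dt = φ − k[B]`, integrated over one colonic transit τ (default
  12 h). Closed forms give the produced/absorbed/excreted mass balance,
  the absorbed fraction `1 − (1 − e^{−kτ})/(kτ)`, (k, τ) phase diagrams,
  a two-phase variant with substrate depletion at time t₁, and per-donor
  predictions from an MMP rate matrix. Reference absorption constants:
  0.091 (CaCo monolayer) and 0.0019 (dialysis bag).
- **Synthetic cohorts** — a seeded generator producing complete study
  inputs (two visits of SCFA tables, OTU tables with planted producer
  taxa, ground truth) so that every pipeline stage has a
  parameter-recovery test.
- **Pipeline runner** — `run_pipeline()` orchestrates
  simulate → rates → mmp → stability → predict → absorb with plain-file
  handoff and an md5 manifest; `inst/cli/mmpkit.R` is a thin command-line
  wrapper.

## Worked example

```r
library(mmpkit)

coh <- generate_cohort(cohort_config(seed = 42, n_donors = 8, otu_spec = NULL))
net <- net_production_rates(production_rates(coh$scfa_visit1))
head(net[net$fiber == "inulin", ], 3)
#>   donor  fiber       scfa rate_mM_per_h
#> 4   D01 inulin    acetate          5.83
#> 5   D01 inulin   butyrate          5.72
#> 6   D01 inulin propionate          2.80

z <- zscore_columns(mmp_matrix(net))
upgma_cluster(z, k = 2)$labels
#> D01 D02 D03 D04 D05 D06 D07 D08
#>   1   2   1   2   1   2   1   2

replicate_cv(coh$scfa_visit1)
#> Replicate QC: 288 groups; overall CV 23.2%; overall %diff 32.8%; 0 zero-mean flagged

absorption_outcome(phi = 1.2, k = effective_rate(0.091), tau = 12)
#> Absorption outcome: produced 28.800 mmol, absorbed 11.276 (39.2%), excreted 17.524; C(tau) = 8.762 mM
```

Reading the output: donor D01 is an inulin specialist (rates well above
the cohort), and the k = 2 UPGMA cut splits the cohort into the two
planted fiber-specialist types. The replicate CV of the simulated wells
matches the assay's measured reproducibility (~23.5%). At the
CaCo-derived absorption constant, roughly 39% of the butyrate produced
over a 12 h transit is absorbed by the epithelium and the rest is
excreted — at the dialysis-bag constant the absorbed share drops to ~1%,
which is why stool SCFA content alone can say little about in vivo
production.

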