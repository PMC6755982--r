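# ctpls

Imaging transcriptomics of case–control cortical-thickness differences via
partial least squares regression.

## What it is for

Case–control MRI studies produce per-region cortical-thickness difference
maps (ΔCT = case mean − control mean, scanner-site adjusted).  Given a
reference region × gene expression matrix on the same parcellation, `ctpls`
asks which genes' regional expression profiles co-vary with ΔCT, where those
genes are expressed across the cortex, and what they are enriched for.  It
is aimed at researchers running imaging-transcriptomics analyses who want
the whole inferential chain — not just the PLS fit — as tested, reusable,
deterministic code.

The statistical core:

- **PLSR** of ΔCT on expression (NIPALS, sequential deflation): component-1
  gene weights ∝ X′y, earlier components invariant to the requested model
  size.
- **Inference**: repeated-CV component selection (one-SE rule), permutation
  test of per-component response variance explained (add-one p), bootstrap
  z-scoring of gene weights over region resamples with sign alignment.
- **Winner's-curse correction**: FDR inverse quantile transformation,
  z<sub>fiqt</sub> = sign(z)·Φ⁻¹(1 − p<sub>BH</sub>/2); genes selected by
  |z<sub>fiqt</sub>| > 1.96.
- **Spatial profile**: mean standardized expression of the significant set
  per Von Economo class, against a random-gene-set permutation null,
  two-tailed FDR q < 0.025.
- **Enrichment**: logistic regression of candidate-set membership on
  significant-set membership + log gene length (OR, Wald CI), BH within set
  families (Bonferroni for cell-type markers), hypergeometric
  over-representation, top-N cell-type marker construction.
- **Synthetic data**: a generator with planted ground truth (latent spatial
  factor shared by expression and ΔCT, planted gene set, planted spatial
  class, site offsets) so everything above is testable with no external
  data.

## Worked example

```r
library(ctpls)

b   <- simulate_bundle(simulation_params(spatial_boost = 1, seed = 1))
dct <- compute_delta_ct(regress_out_site(b$cohort))
al  <- align_regions(b$expression, dct, b$annotation)

fit <- fit_plsr(al$expression, al$delta_ct, ncomp = 2)
fit
#> PLSR fit: 60 region(s) x 2000 gene(s), 2 component(s)
#>   response variance explained per component:
#>     0.918 0.078

score_delta_correlation(fit, al$delta_ct)   # component-1 scores vs deltaCT
#> r = 0.958, p = 2.89e-33

wt  <- adjust_weight_table(
  bootstrap_weights(al$expression, al$delta_ct, n_boot = 200, seed = 1))
sig <- select_significant(wt)               # |z_fiqt| > 1.96
length(sig)
#> [1] 153
evaluate_recovery(sig, b$truth, colnames(al$expression))
#> $sensitivity 1        # all 100 planted signal genes recovered
#> $fpr         0.028    # false positives among the 1,900 non-signal genes

ve <- ve_enrichment(al$expression, al$annotation, sig, B = 1000, seed = 1)
ve[c("ve_class", "z", "q", "direction")]
#>   ve_class      z      q direction
#> 2        2 13.752 0.0035      over   <- the planted class
#> 4        4 -5.050 0.0035     under
#> ...

enr <- enrich_families(sig, b$gene_sets, colnames(al$expression),
                       covariates = b$gene_meta)
enrichment_table(enr)[1, ]
#>       Category      Dataset     OR Upper CI (95%) Lower CI (95%)        P P_corrected
#> 1 dysregulated planted_down 18.446          28.66         11.873 1.88e-38    3.76e-38
```

The numbers mean: one latent component explains ~92% of ΔCT variance and its
regional scores track ΔCT (r = 0.96); the bootstrap-z/FIQT selection
recovers every planted signal gene at a 2.8% false-positive rate; the
significant set is over-expressed exactly in the boosted Von Economo class;
and the planted gene set is the top enrichment (OR ≈ 18) while decoys stay
flat.

`run_pipeline(run_config(simulate = list(...), seed = 1, out_dir = "run"))`
executes the same chain end to end from one config (YAML supported), writing
stage TSVs, a markdown report, and a manifest with per-stage seeds and
output checksums.  A thin CLI with `simulate` / `run` / `report` subcommands
lives at `inst/cli/ctpls.R`.

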