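---
title: "Linking regional cortical-thickness differences to gene expression with PLSR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking regional cortical-thickness differences to gene expression with PLSR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpls)
```

# The problem

Case–control neuroimaging studies routinely find distributed differences in
cortical thickness, but a thickness map alone says nothing about molecular
mechanism.  Imaging transcriptomics bridges the two scales: if a reference
atlas provides gene expression for the same cortical parcellation, one can ask
which genes' regional expression profiles co-vary with the regional
case–control difference map, and whether those genes are enriched for
biologically meaningful sets (e.g. genes dysregulated in post-mortem cortex,
rare-variant hits, cell-type markers).

`ctpls` implements that analysis as a reusable, fully testable pipeline:

1. a site-adjusted per-region case-minus-control thickness difference, ΔCT;
2. partial least squares regression (PLSR) of ΔCT on a region × gene
   expression matrix;
3. inference on the fit — cross-validated component selection, a permutation
   test of explained variance, bootstrap z-scoring of gene weights, and a
   winner's-curse correction (FIQT) before selecting significant genes;
4. spatial characterization of the selected genes across the seven Von
   Economo cytoarchitectonic classes against a permutation null;
5. gene-set enrichment by gene-length-adjusted logistic regression, plus
   hypergeometric over-representation and cell-type marker sets.

Because the real inputs (restricted MRI cohorts, donor brain expression,
third-party gene lists) cannot be shipped, the package includes a synthetic
data generator with planted ground truth.  Every statistical claim the test
suite makes is made against that known truth or against an independent
closed-form oracle.

# The model

## ΔCT with scanner-site adjustment

Thickness is modelled per region as

$$CT_{s,r} = \mu_r + \beta_r\,\text{group}_s + \gamma_{r,\text{site}(s)} + \varepsilon_{s,r},$$

with cases coded 1 and controls 0.  `regress_out_site()` fits the site and
group indicators per region by OLS and removes the centered fitted site
contribution from each subject's thickness.  Two choices here were genuinely
open and are worth stating:

* **Group stays in the design.**  Sites differ in case/control composition;
  with group omitted, part of the group contrast would be absorbed into the
  site means and then subtracted.  A site whose subjects all belong to one
  group is flagged — there the two terms are confounded and the adjustment
  cannot separate them.
* **Only the site component is removed.**  Re-centering raw residuals on the
  observed group means looks equivalent but is not: residuals of a model that
  contains group sum to zero within each group, so group means — and hence
  ΔCT — would be returned unchanged and the adjustment would be a no-op at
  the contrast level.  Removing the centered site term adjusts the contrast
  while keeping values in millimetres and leaving the regional grand mean
  untouched.

`compute_delta_ct()` is then simply the case-minus-control mean per region.

## PLSR and why NIPALS

With expression matrix $X$ (regions × genes, columns z-scored by default) and
response $y = \Delta CT$, single-response PLSR extracts components
$t_k = X_k w_k$ maximizing covariance with the deflated response.  The
package implements NIPALS with sequential deflation, which has two properties
the downstream inference relies on:

* component-1 weights are exactly proportional to the cross-covariance
  $X^\top y$ — this is the closed-form oracle the test suite checks on random
  instances;
* earlier components are unaffected by how many components are requested, so
  the component-1 gene ranking does not depend on the model-size choice.

Expression columns are standardized before fitting because expression scales
are heterogeneous across genes; a raw mode (`scale. = FALSE`) exists for
matrices that are already normalised.

## Component count and the permutation test

`select_n_components()` runs repeated k-fold cross-validation over regions
(default 10-fold × 5 repeats; the search ceiling for a full-scale analysis in
this literature is 35 components).  PLS CV error curves drop steeply and then
plateau; a strict minimizer habitually drifts several components into the
plateau for sub-percent RMSEP gains.  The default selection rule is therefore
the standard one-standard-error rule — the smallest model within one SE of
the minimum — with the strict minimizer available via `rule = "min"`.  The
mean-only baseline (0 components) is part of the curve, so on association-free
data the selector can and does return 0; `run_pipeline()` floors the fitted
model at one component and reports the curve.

`permutation_test_components()` permutes $y$ across regions, refits, and
records per-component response variance explained; p-values use the add-one
estimator $(1 + \#\{null \ge obs\})/(B+1)$ (default $B = 10{,}000$, scaled
down in tests).  One behaviour deserves a note: with many more genes than
regions, a single PLS component can explain most of even a permuted
response in sample, so the null distribution of explained variance sits high
and the test has limited power at desk scale (tens of regions, thousands of
genes).  It remains exactly calibrated under the null — which is what the
test suite verifies — and its power grows with the number of regions.

## Bootstrap z-scores and the winner's curse

`bootstrap_weights()` resamples regions with replacement (default 1,000
replicates; replicates with fewer than three distinct regions are redrawn),
refits, sign-aligns each replicate's component to the reference weights (a
PLS component is defined up to a global sign), and forms $z = w/\widehat{se}$.

Selecting genes by top |z| overestimates the selected effects — the winner's
curse.  `fiqt_adjust()` applies the FDR inverse quantile transformation:
two-sided p-values from the z-scores are Benjamini–Hochberg adjusted and
mapped back to same-signed normal quantiles,
$z_{fiqt} = \mathrm{sign}(z)\,\Phi^{-1}(1 - p_{adj}/2)$ (computed in the
upper-tail form to keep precision for extreme z).  Magnitudes never increase
and the |z| ordering is preserved.  Significance uses $|z_{fiqt}| > 1.96$
(two-sided q < 0.05); the selection is unsigned because with a signed
response the weight sign carries no directional meaning.  Reporting
conventions follow the field: top genes are ranked by $|z_{fiqt}|$ with ties
broken by |weight| then gene id, and the default report depth is 200 genes
(about 1% of a whole-genome matrix).

## Spatial characterization

`regional_set_score()` z-scores each gene across regions and averages over
the selected set; `ve_enrichment()` compares each Von Economo class's mean
score against a null built from random same-size gene sets drawn from the
measured-gene universe.  The null randomizes *genes*, not regions: that
preserves the cortical spatial covariance structure, which region shuffling
would destroy.  (A spatial-autocorrelation-preserving "spin" null over
regions is a known alternative and is out of scope.)  Two-tailed add-one
p-values are BH-adjusted across the seven classes and called significant at
q < 0.025 per tail, i.e. a two-tailed 0.05.  Genes with zero variance across
regions carry no spatial information and are dropped with a warning; a fully
constant matrix returns an all-zero profile rather than an error.

## Gene-set enrichment

`logistic_enrichment()` regresses candidate-set membership on
significant-set membership plus log gene length over the measured-gene
universe; the enrichment OR is the exponentiated membership coefficient with
Wald 95% CI.  Orientation matters only once covariates enter: this
orientation asks whether candidate lists are explained by length rather than
by PLSR selection, which is exactly the confounder the covariate exists to
remove.  Gene length enters as log(length) because plausible length effects
are multiplicative.  With a constant covariate the model reduces to the
marginal 2×2 odds ratio — the closed-form oracle in the tests.  An empty 2×2
cell triggers the Haldane–Anscombe correction (0.5 per cell) with an explicit
`corrected` flag, never silently.

`enrich_families()` adjusts p-values within set families: BH everywhere,
Bonferroni for cell-type marker sets (they are nearly disjoint by
construction).  A set is *enriched* when q < 0.05 **and** OR > 1.
`build_celltype_sets()` ranks genes per cell class by
$\log((x_c + 1)/(\bar{x}_{others} + 1))$ — the "+1" pseudocount guards zero
expression, and "others" means the mean of the remaining classes (the
source literature's phrasing is ambiguous on this point; this is the
documented reading).  `over_representation()` is a local hypergeometric
stand-in for web-based pathway tools.  Gene-level association z-scores
(SNP-to-gene collapsed statistics are consumed as input, never computed)
are thresholded at z ≥ 1.96 by default into a candidate set tested in the
same logistic framework.

The gene universe for every enrichment test is the set of genes present in
the aligned expression matrix — all tests are conditional on what was
measured.

# The synthetic data generator

`simulate_bundle()` draws, per region $r$, a latent spatial factor
$t_r \sim N(0,1)$ that drives both sides of the analysis:

* expression: $X_{r,g} = \text{loading} \cdot t_r \cdot 1\{g \in
  \text{signal}\} + N(0, \sigma_x^2)$;
* truth: $\Delta CT_r = a\,t_r$; per-subject thickness adds a regional
  baseline (2.5 mm ± 0.1 mm), the group effect, a per-site offset, and
  subject noise.

Defaults are the study conditions the pipeline is tested under: 60 regions,
2,000 genes, 100 signal genes with loading 1, latent effect 1 mm/SD, noise
SD 0.5 for both expression and thickness, 62 cases / 87 controls over 4
sites with 0.1 mm site offsets.  Cohort sizes mirror a typical multi-site
paediatric case–control sample; the noise levels put per-gene signal
correlations around 0.9 and per-region ΔCT standard errors around 0.08 mm,
i.e. clearly detectable but far from noiseless.  A planted "downregulated"
gene set of 100 genes draws half its members from the signal genes; decoy
sets of realistic sizes (65–150) populate the other families.  Gene lengths
are log-normal (meanlog 9, sdlog 1) and independent of membership unless the
length-confounded mode is on; Von Economo classes 1–7 tile the regions in
contiguous blocks; the planted-spatial mode adds a fixed boost to signal-gene
expression in one class — the tested condition sets the boost equal to the
signal loading, so the spatial contrast has the same magnitude as the latent
coupling.  `null_bundle()` zeroes both couplings and reports an empty truth
set, giving exact null data for calibration.

What the generator does **not** emulate: spatial autocorrelation within
classes, donor/probe/batch structure of real expression atlases, non-linear
or multi-factor coupling (a multi-factor option exists but defaults to one),
and realistic effect sizes of psychiatric imaging (planted effects are large
so that recovery tests are sharp).  Passing tests therefore demonstrate that
the machinery is correct and calibrated — not that any particular real
dataset would yield a particular finding.

# Numerical and design choices

* Master seed → per-stage derived seeds (fixed documented offsets), recorded
  in the run manifest; two runs of one config are byte-identical, which the
  manifest's md5 checksums make checkable.
* Zero-variance genes are dropped before fitting (logged); bootstrap
  resamples that lose a gene's variance set its column to zero instead of
  propagating NaN.
* Permutation and bootstrap p-values / SEs use add-one and SD estimators so
  nothing is ever exactly zero; FIQT caps adjusted p at 1, mapping to
  $z_{fiqt} = 0$.
* Tie-breaks (top-gene ranking, cell-type sets) are deterministic:
  magnitude, then gene id.
* Test problem sizes: oracle checks run on ≤20×50 instances; calibration
  suites use 200 replicates at B = 199 on 40-region bundles; end-to-end
  recovery uses 10 seeds at the default 60×2,000 conditions with 200
  bootstrap replicates and B = 1,000 spatial nulls.  These are the package's
  chosen desk-scale conditions; full-scale defaults remain 10,000
  permutations and 1,000 bootstrap replicates.

# Known limitations

* The permutation test's power at desk scale is limited (see above); with a
  few hundred regions it behaves as in the full-scale literature.
* The spatial null does not preserve spatial autocorrelation of the gene
  sets' scores (no spin test).
* The logistic enrichment assumes one covariate (length); other gene-level
  covariates would need the same treatment.
* `aggregate_to_regions()` pools samples across donors (the most direct
  reading of a median across cortical samples); a donor-wise median is not
  currently implemented.
* ΔCT is a group-mean contrast; subject-level covariates other than site and
  group (age, IQ, sex) are assumed handled by cohort matching upstream.
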