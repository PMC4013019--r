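---
title: "Genetic risk scores as ecological predictors: models and methods"
author: "ecogrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic risk scores as ecological predictors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogrs)
```

## The two-level analysis

`ecogrs` implements a two-level analysis of candidate-gene variation in
coronary disease, the design used in eco-epidemiologic studies of
nitric-oxide-synthase (NOS) gene variants and myocardial infarction (MI).

**Individual level.** Case-control studies are scanned by multivariate
logistic regression of MI status on SNP allele dosages, adjusted for age,
sex and the remaining scanned SNPs (one joint model). Per-study log odds
ratios are pooled by inverse-variance fixed-effect meta-analysis:
$\hat\beta = \sum_i w_i b_i / \sum_i w_i$, $w_i = 1/\mathrm{SE}_i^2$,
$\mathrm{SE} = (\sum_i w_i)^{-1/2}$. A genetic risk score (GRS) is then
built from SNPs that reach $p < 0.1$ in *every* replicate meta-analysis
with a concordant risk allele (the allele with pooled $\beta > 0$),
pruned greedily by linkage disequilibrium ($r^2 < 0.2$, lowest $p$
first). The GRS is the unweighted risk-allele dosage sum: homozygotes
for the non-risk allele contribute 0, heterozygotes 1, risk-allele
homozygotes 2, so a 4-SNP score is bounded by $[0, 8]$. Its
interindividual predictive value is summarized by Nagelkerke's $R^2$ and
the ROC AUC with a Hanley–McNeil confidence interval.

**Population level.** Mean GRS per population is treated as an
ecological exposure. Its spatial structure is tested with Moran's $I$
and Geary's $C$ randomization tests and distance-class correlograms,
interpolated over geographic space by ordinary kriging with a spherical
semivariogram, and regressed (Spearman + OLS) against population
coronary event rates, with Bonferroni outlier detection and
exclusion-and-refit.

All genotype data live in a `GenotypeExperiment`, a
`SummarizedExperiment` with a `dosage` assay (alternate-allele count,
`NA` = missing, fractional after imputation) and an `imputed` mask.

## The synthetic-data generator

The paper-scale data behind such analyses (consortium case-control
genotypes, reference population panels, surveillance event rates)
cannot ship with a package, so `ecogrs` generates data with the
statistical structure the analysis assumes:

* **Geographic clines.** Alternate-allele frequencies follow a
  logit-linear cline, $p_s(\phi, \lambda) = \mathrm{logit}^{-1}(a_s +
  b_s \phi + c_s \lambda)$ in decimal degrees. By default only the
  causal SNPs carry a latitude slope (0.03 logit/degree), producing the
  northward mean-GRS gradient the population level is designed to
  detect.
* **LD blocks.** Haplotypes are drawn through a latent Gaussian copula:
  within each contiguous block the latent vector is AR(1) with
  parameter $\rho$ ($0.6$ by default), and allele $s$ is the alternate
  iff the latent value falls below $\Phi^{-1}(p_s)$. Marginal
  frequencies are exact; blocks and individuals are independent. This
  gives tunable block-wise $r^2$ so the pruning steps are genuinely
  exercised.
* **Disease model.** Case status is Bernoulli with
  $\mathrm{logit}^{-1}(\beta_0 + \sum_s \beta_s g_s + \beta_{age}
  \cdot age + \beta_{sex} \cdot sex)$; by default 4 of 60 SNPs are
  causal with log odds ratios spaced in $[0.2, 0.5]$, matching the
  effect-size scale reported for candidate-gene MI variants. Sampling
  is outcome-conditional (drawn until the case and control quotas are
  filled) with an attempt cap of $100 (n_{cases} + n_{controls})$ so a
  degenerate model fails loudly instead of looping. Age is
  Normal(60, 10) years and sex Bernoulli(0.5); cohort studies report
  only that adjustments used age and gender, so these are placeholders,
  not inferred values.
* **Event rates.** Population coronary event rates (events per 100,000
  per year) are linear in mean GRS with Gaussian noise: default
  intercept 20, slope 30 per score unit, noise SD 5; negative draws are
  truncated at zero (rates are physical quantities) with a warning.

What the generator does *not* emulate: coalescent-realistic haplotype
structure, demographic history, genotyping batch effects, reference-
panel imputation error, or confounding of the GRS-event-rate coupling.
Passing tests therefore demonstrate that the estimators recover the
structure they assume, not that real data satisfy those assumptions.

## Default study conditions

The generator defaults are fixed study conditions, not tuning knobs:
three case-control studies of 2000 cases / 2000 controls, two replicate
dosage sets per study (the analysis of imputed data is conventionally
run in duplicate with two imputation algorithms; here replicates are
independent missingness + expected-dosage-imputation draws of the same
study), 60 SNPs in 5-SNP LD blocks on three contigs mirroring the three
NOS gene regions (chromosomes 7, 12, 17; 5 kb spacing), a panel of 30
populations of 40 individuals on a European window (latitude 35–65,
longitude −10–30), and an 11-population event-rate table (the size of
the surveillance set such studies pair with their genotyped
populations).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `qc.min_call_rate` | 0.75 | SNPs/samples with call rate strictly below are removed |
| `qc.min_imputation_quality` | 0.6 | keep SNPs with quality strictly above, in all studies |
| `qc.ld_prefilter_r2` | 0.8 | greedy genomic-order prefilter before association |
| `selection.p_max` | 0.1 | strict `<` in every replicate meta-analysis |
| `selection.prune_r2` | 0.2 | score SNPs pairwise strictly below |
| `spatial.n_perm` | 999 | randomization-test permutations |
| `spatial.n_classes` | 6 | equal-count correlogram distance classes |
| `kriging.n_grid` | 100 | nodes along the longer bounding-box side |

Threshold semantics are deliberately asymmetric: call-rate and pruning
thresholds remove *strictly below* / keep *strictly below* the stated
$r^2$, while the imputation-quality filter keeps *strictly above* 0.6 —
these match the conventional phrasing of the QC protocol they encode.

## Numerical and design choices

* **Logistic fits** use Newton/IRLS with step-halving, so the
  log-likelihood never decreases; convergence is max |score| < 1e-8
  (cap 100 iterations). |beta| > 15 during iteration raises a
  separation error; a singular information matrix raises a collinearity
  error, and the joint association scan then falls back (with a
  warning) to per-SNP models adjusted for age and sex. Wald p-values
  are reported, matching standard meta-analysis inputs.
* **HWE exact test**: the standard two-sided exact definition (sum of
  configurations no more probable than the observed one, enumerated
  over heterozygote counts given the allele counts), no mid-p.
* **LD $r^2$** is the squared Pearson correlation of unphased dosages
  (composite LD) over pairwise-complete samples: no phase is available,
  and it agrees closely with haplotype $r^2$ under HWE while being
  deterministic. Greedy prefilter ties are broken by genomic order
  (first kept wins); score pruning orders by the minimum p-value across
  replicates, which is deterministic.
* **Missing dosages** are imputed to their conditional expectation
  $2\hat p$ within the sample's population (a stand-in for
  haplotype-based imputation, which is out of scope); imputed entries
  are fractional and flow into association and scoring unchanged, with
  no per-individual completeness rescaling.
* **Spatial weights** default to row-standardized inverse great-circle
  distance (haversine on a 6371.0088 km sphere); binary-threshold and
  distance-class schemes are available. The randomization tests are
  one-sided for positive autocorrelation by default ("greater" for
  $I$, "less" for $C$) with the +1 permutation p-value convention, so
  p is never zero and never below $1/(n_{perm}+1)$. Correlogram
  classes are equal-count quantile bins (ties broken by stable pair
  order) and their per-class p-values are two-sided, since class-level
  coefficients can be of either sign.
* **Kriging** feeds great-circle distances directly into the
  semivariogram and kriging system — at regional scales the spherical
  model remains valid on sphere distances, and no map projection is
  introduced. The spherical fit minimizes $N(h)$-weighted least squares
  from a coarse multi-start grid ($c_0 \in \{0, .25, .5\}$,
  $c_1 \in \{.5, 1\}$ of the empirical maximum; $a \in \{.25, .5, 1\}$
  of the maximum lag), which is deterministic and avoids local minima.
  $\gamma(0) = 0$ exactly (the nugget acts for $h > 0$), which makes
  the zero-nugget predictor an exact interpolator; kriging variances in
  $(-10^{-9}, 0)$ are clipped to 0. All sites are used at every node
  (no search neighborhood; $n \le 40$).
* **Ecological regression**: the multivariate model admits predictors
  with univariate OLS slope $p < 0.05$; outlier exclusion uses the
  Bonferroni criterion adjusted $p < 0.01$ on externally studentized
  residuals of the GRS univariate model, the criterion conventionally
  reported for excluding an aberrant island population. Sex strata are
  analyzed fully independently.
* **Determinism**: one master seed; per-stage sub-seeds by fixed
  offsets. Two runs with the same configuration and seed produce
  byte-identical outputs (hashes recorded in the run manifest).

## Problem sizes in the test suite

The unit and property tests run at reduced sizes chosen to make the
checked contrasts detectable with comfortable margins: oracle
comparisons at $n = 6$–200, calibration loops at 200–1000 replicates,
and the selection-recovery check at its full study conditions (three
studies of 2000/2000, 60 SNPs, 20 seeds). The end-to-end determinism
check runs the pipeline at 300/300 cases/controls and 12 populations,
since byte-identity is size-independent.

## Known limitations

* Expected-dosage imputation ignores LD; it is unbiased under MCAR but
  less accurate than haplotype-based imputation, and a SNP unobserved
  in an entire population cannot be imputed there.
* The GRS is unweighted (a beta-weighted variant exists via the model
  table's `weight` column but is not the default); no external-GWAS
  reweighting, standardization or reclassification metrics.
* Relatedness and ancestry-outlier QC are out of scope (they require
  genome-wide context).
* Kriging is isotropic ordinary kriging only; no universal or
  anisotropic variants, no cartographic clipping of the exported grid.
* Ecological regressions are plain OLS/Spearman on population units;
  they carry the usual ecological-inference caveats and no
  spatially-correlated-error model.
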