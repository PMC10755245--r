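---
title: "Methods: polygenic smoking risk and the brain-age gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic smoking risk and the brain-age gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bagprs` packages an imaging-genetics workflow whose scientific question is
whether the genetic liability to smoking, summarized as a polygenic risk
score (PRS), is associated with accelerated apparent brain ageing (the
brain-age gap, BAG), and whether that association is mediated by smoking
exposure and gray-matter volume. This vignette documents the models, their
assumptions, the tunable parameters, and the design decisions taken where
the methodology admits more than one defensible choice.

## Genotype quality control

SNP-level filters are the standard array-QC trio, applied with strict
inequalities: minor-allele frequency (MAF) < 0.01, call rate < 0.95, and
Hardy–Weinberg equilibrium (HWE) p < 1e-5. Samples with more than 5% missing
calls are removed *before* any SNP statistic is computed, because sample
exclusions are study-level decisions that precede marker QC. MAF is computed
on non-missing calls only.

The HWE test is the Pearson chi-square goodness-of-fit with 1 df against
the proportions implied by the sample allele frequency, without continuity
correction — the test used in mainstream array pipelines. An exact or mid-p
test would behave differently in tiny samples; we deliberately match the
conventional choice, and the test suite pins the implementation to an
independent enumeration oracle on every genotype-count triple with total
≤ 30. Monomorphic SNPs return p = 1 by convention (they carry no HWE
information, and the MAF filter removes them anyway). A SNP failing several
filters is attributed to its first failure in the order MAF, call rate,
HWE; an any-failure count is reported alongside so the attribution rule
cannot hide overlap.

## P+T polygenic scores

**Clumping.** Index SNPs are selected greedily by ascending discovery
p-value; each index removes remaining SNPs on the same chromosome within
±250 kb whose dosage r² with it exceeds 0.1 (pairwise-complete observations
in the LD panel, which is the target sample itself). Ties on p are broken
by chromosome, position, then SNP id, so the output is deterministic. The
greedy algorithm is checked against an independently written set-based
reference on random panels.

**Scoring.** At threshold P_T, the score is the per-SNP average
`score_i = (Σ_{p_j < P_T} β_j G_ij) / m_i`, with `G_ij` the effect-allele
dosage. The average (rather than the raw sum) is the PLINK `--score`
default; it keeps scores comparable across thresholds that admit different
SNP counts. The unnormalized sum is available via `average = FALSE`.
Missing dosages are imputed with twice the target-sample effect-allele
frequency, the standard mean-imputation rule, so scores are defined for all
subjects. Alleles are matched exactly: a summary-stats SNP whose effect
allele equals the panel's other allele is flipped (`2 − G`); anything else
is skipped with a warning. No strand-flip heuristics are attempted.

**Threshold scan.** Scores are computed at 100 thresholds, 0.005 to 0.5 in
steps of 0.005. Each score's association with the smoking phenotype is a
partial correlation after residualizing both variables on the covariate set
(age, sex, handedness, BMI, alcohol, TIV and five ancestry components in
the default pipeline); p-values use `df = n − 2 − k`. Thresholds are ranked
by |r|: "strongest association" is read as magnitude, since a strongly
negative score would be as informative; signed ranking is available via
`rank_by = "signed"`. The binary ever-smoker indicator is the default
selection phenotype (the continuous liability is not observable in real
data); the scan accepts any numeric phenotype. The optimal score is
z-scored (mean 0, SD 1) before all downstream analyses.

## Brain age and bias correction

Regional gray-matter volumes (166 regions by default) are first replaced by
their least-squares residuals on sex, ethnicity, handedness, BMI, alcohol,
TIV, scanning site and education. Residualization is exact: the test suite
requires |cor(residual, covariate)| < 1e-10, and rank-deficient covariate
sets fail with the collinear columns named rather than being silently
dropped.

The age model is a gradient-boosted tree regressor (xgboost) under nested
five-fold cross-validation: the outer loop partitions subjects once (seeded
shuffle stratified by age decile, which stabilizes fold age distributions);
the inner loop selects hyperparameters by minimum mean MAE on training
subjects only; the refit model predicts its held-out fold. Every subject
gets exactly one out-of-fold prediction, and the five per-fold models are
kept as an ensemble whose mean prediction scores new cohorts. The default
search grid is tree depth {2, 4, 6} × learning rate {0.05, 0.1} × rounds
{100, 300} — deliberately small, since regional-volume feature sets are
low-dimensional and heavily regularized models dominate; the grid is fully
configurable, and a single-row grid skips the inner loop. All fits run
single-threaded with seeded RNG, so identical seeds give byte-identical
predictions.

**Bias correction.** Regression to the mean makes raw BAG negatively
correlated with age (young subjects over-predicted, old under-predicted).
Among the published correction schemes we use the "regress training-set BAG
on age, subtract the fitted trend" form: corrected BAG
`= BAG − (slope·age + intercept)`, with slope and intercept estimated on
the never-smoker training out-of-fold predictions only and then applied
unchanged to every cohort. This variant was chosen because it transfers
cleanly from the training population to new groups, which is exactly how
the non-smoker model is applied to smokers; by least-squares algebra the
corrected BAG is orthogonal to age on the fitting cohort (the tests require
|r| < 1e-6) and near-orthogonal on held-out cohorts from the same
population. A constant age vector leaves the slope undefined and errors.
Fit quality is summarized by Pearson r with a Fisher-z 95% CI
(SE = 1/√(n−3); the CI method is a convention choice), RMSE and MAE.

## Association and comparison statistics

Associations of the z-scored PRS with continuous outcomes (corrected BAG,
total gray-matter volume, pack-years, quit duration) are ordinary
least-squares fits with an intercept — the Gaussian case of the generalized
linear model; logistic regression is provided for binary smoking status.
Two covariate models are carried through the pipeline: model 1 (sex, age)
and model 2 (sex, age, TIV, handedness, BMI, alcohol, site, education).
Group comparisons use the Welch t-test (no equal-variance assumption) with
classical Cohen's d on the pooled SD (n−1 denominators); the method
combination is a documented choice, as neither variant is dictated by the
workflow. FDR control is Benjamini–Hochberg step-up, delegated to
`stats::p.adjust` and pinned in tests to a brute-force step-up oracle. The
region-wise scan reports one covariate-adjusted partial correlation per
region with BH-adjusted q-values; constant regions are returned as NA and
excluded from the adjustment rather than poisoning it. The per-SNP scan
uses the Frisch–Waugh identity (residualize phenotype and mean-imputed
dosages on the covariates once) for speed, which reproduces per-SNP OLS
with `df = n − k − 2`; significance lines are Bonferroni `0.05/m` and
suggestive `1/m` with `m` the number of testable (non-monomorphic) SNPs.

## Mediation

Mediation is the linear product-of-coefficients decomposition. For one
mediator: `m ~ x + C` gives the a-path, `y ~ x + m + C` gives the b-path
and the direct effect τ′, `y ~ x + C` gives the total effect τ, and the
indirect effect is a·b, so τ = τ′ + a·b holds exactly (the tests demand
1e-8). Two mediators enter in parallel — no path between them — because the
reported decomposition (per-mediator effects plus a combined effect) is the
parallel one; a sequential variant is out of scope. Covariates are
regressed out of every sub-model.

Inference is a nonparametric case-resampling bootstrap (rows resampled
jointly, 1000 resamples by default) with bias-corrected percentile
intervals: `z0 = Φ⁻¹(P(θ* < θ̂))`, bounds at `Φ(2 z0 ± z_{α/2})`. We use BC
rather than BCa because the acceleration constant is not part of the
reference procedure. The proportion mediated PM = 100·(τ − τ′)/τ is
computed from point estimates, not bootstrap averages, matching its printed
definition; it is flagged unstable when |τ| is below tolerance (1e-8 by
default) or when τ and τ′ disagree in sign (suppression), where a
percentage loses meaning.

## Enrichment

SNPs entering the optimal score are mapped to genes by interval
containment: BED intervals are 0-based half-open, SNP positions 1-based, so
a SNP maps when `start < pos ≤ end` after adding the optional flank. The
conversion lives in one function because mixing the two conventions is the
classic off-by-one in this step. A SNP overlapping several genes maps to
all of them. Over-representation is the upper-tail hypergeometric test
`P(X ≥ k)` per gene set, BH-adjusted across sets; the universe defaults to
all genes in the interval file, since no background is canonical. Only the
count-based test is implemented — rank-based GSEA answers a different
question. Live GO/KEGG retrieval is out of scope; collections are supplied
as GMT files.

## The synthetic cohort generator

The generator exists so the pipeline can be exercised end to end without
restricted data. It emulates the causal structure the analysis assumes:

- **Genotypes.** Two latent Gaussian allele draws per subject share a
  block-constant correlation (`within_block_corr`, default 0.6) and are
  thresholded at the allele-frequency quantile, so each SNP is in HWE
  marginally while blocks of `ld_block_size` SNPs (default 10) carry
  controllable dosage LD — a Gaussian-copula construction needing no
  haplotype panel. Blocks span < 250 kb with 1 Mb between blocks, so the
  clumping window never crosses blocks. Missingness is injected completely
  at random (default 1%) to exercise call-rate QC and mean imputation.
- **Discovery GWAS.** True effects (default: 50 causal SNPs of 1000,
  effects ~ N(0, 0.05)) plus sampling noise at
  `se_j = 1/√(2·MAF_j(1−MAF_j)·N)` for a discovery sample of `discovery_n`
  (default 50,000), with Wald p-values.
- **Smoking.** A liability in which the standardized true score explains
  `h2_liability` (default 0.3) of the variance, plus small sex/BMI terms
  and Gaussian noise filling the remainder; ever-smokers are the top
  `smoking_prevalence` quantile (default 0.56, the study-scale smoker
  fraction). Pack-years for smokers are `max(0, 20 + 8·liability_z + ε)`,
  exactly 0 for never-smokers; 55% of smokers are former, with a uniform
  1–30-year quit duration.
- **Atrophy.** Regional volumes are a fixed baseline (~3600 mm³ per
  region) plus a linear age slope per region (default −3 mm³/year), the
  whole-brain pack-year slope spread over regions (default −40
  mm³/pack-year — about 0.08 apparent years per pack-year against the age
  slope), small sex/TIV effects, and region noise (SD 50 mm³). Total
  gray-matter volume is the exact regional sum. Ages are uniform on 44–81.
- **Covariates.** Sex, ethnicity, handedness, BMI, alcohol, site and
  education come from simple parametric families; ancestry PCs are standard
  normals independent of genotype, treated purely as nuisance terms.

Where the study conditions fix a value (age range, 166 regions, smoker
fraction, QC cuts, clump and grid parameters, 1000 bootstraps) the defaults
are those values; where they do not (effect-size scales, atrophy slopes,
noise SDs), defaults were chosen once for a realistic-looking, testable
signal and are documented here rather than revisited.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: realistic human LD maps and allele-frequency
spectra, population stratification correlated with genotype, relatedness,
sex chromosomes, imputation uncertainty, scanner/site effects beyond an
independent site label, non-linear age trajectories, and measurement error
in smoking self-report. Tests on this cohort validate the *machinery*
(estimators, orderings, invariants, calibration), not effect sizes in any
real population.

## Numerical choices and degenerate inputs

- Rank checks use QR; collinear design columns are named in the error.
- Zero-variance inputs error early (`bagprs_degenerate`) rather than
  returning NaN: constant age in bias fitting, zero pooled SD in
  comparisons, constant x/m/y in mediation.
- Thresholds admitting zero SNPs are recorded with `n_snps_used = 0` and
  excluded from ranking; an all-empty scan errors.
- Clumping ties on p are broken lexicographically; bootstrap resamples that
  fail to fit are dropped from the interval computation.
- Seeds: every stochastic function takes an explicit seed; the pipeline
  derives per-stage seeds from its master seed and records them in the run
  manifest.

The test suite runs the heavier properties at deliberately modest sizes —
cohorts of 400–1000 subjects, 150–300 SNPs, 20–40 regions, nested CV with a
single-row hyperparameter grid, 100–300 bootstrap resamples — chosen as the
smallest problems at which the properties under test are comfortably
resolved; the acceptance script uses n = 3000 for the bias-transfer check,
n = 2000 with 1000 resamples for mediation recovery, and n = 900 cohorts
across three atrophy-slope levels for the end-to-end monotonicity check.

## Known limitations

- The P+T score is the classical construction; LD-aware Bayesian shrinkage
  methods (lassosum, PRS-CS) are out of scope.
- The GWAS scan has no genomic-control or mixed-model correction for
  stratification; ancestry PCs enter only as covariates.
- Mediation assumes linear models and no exposure–mediator interaction;
  sensitivity analysis for unmeasured confounding is not implemented.
- Sample-level sex-mismatch QC is not implemented (it requires
  X-chromosome intensity data outside the package's inputs).
- The interfaces are R functions rather than shell commands; `run_pipeline()`
  plus the per-stage functions are the orchestration surface.
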