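# bagprs

Imaging-genetics analysis linking polygenic risk for smoking to the
brain-age gap, as a tested, reusable R package.

Tobacco smoking is heritable, and smoking accelerates gray-matter loss.
`bagprs` implements the full analysis chain used to connect the two at the
level of apparent brain ageing:

1. **Genotype QC** — SNPs are excluded at minor-allele frequency < 1%, call
   rate < 95% or Hardy–Weinberg equilibrium p < 1e-5 (Pearson chi-square,
   1 df); samples with > 5% missing calls are dropped first.
2. **Polygenic risk score (P+T)** — discovery-GWAS summary statistics are
   LD-clumped (greedy by ascending p, r² > 0.1 within ±250 kb removed), and
   scores are computed at 100 p-value thresholds P_T ∈ [0.005, 0.5] in steps
   of 0.005: score_i = (Σ_{p_j < P_T} β_j G_ij) / m_i with effect-allele
   dosages and mean-imputed missing calls. The threshold whose score has the
   strongest covariate-adjusted partial correlation with smoking is selected
   (top 10 recorded) and the optimal score is z-scored.
3. **Brain age** — 166 regional gray-matter volumes are residualized for
   nuisance covariates and fed to a gradient-boosted tree regressor
   (xgboost) under nested five-fold cross-validation, trained on
   never-smokers only. The brain-age gap BAG = predicted − chronological age
   is corrected for regression-to-the-mean by subtracting the training-set
   trend of BAG on age, leaving the corrected BAG orthogonal to age.
4. **Statistics** — covariate-adjusted associations of the score with BAG,
   total gray-matter volume and smoking parameters (two covariate models);
   Welch t comparisons with Cohen's d; Benjamini–Hochberg FDR; a region-wise
   partial-correlation scan; a per-SNP GWAS scan with Bonferroni (0.05/m)
   and suggestive (1/m) thresholds.
5. **Mediation** — product-of-coefficients mediation (single or two parallel
   mediators) with bias-corrected case-resampling bootstrap intervals and
   the proportion mediated PM = 100·(τ − τ′)/τ.
6. **Enrichment** — SNP-to-gene mapping by interval containment (BED,
   0-based half-open, against 1-based SNP positions) and hypergeometric
   over-representation of the mapped genes against GMT gene sets.

Because the original cohort data are access-restricted, the package ships a
first-class synthetic cohort generator that emulates the assumed causal
chain — genotypes in LD blocks → polygenic smoking liability → pack-years →
regional atrophy — so every stage, and the pipeline end to end, is testable
offline.

## Worked example

```r
library(bagprs)

res <- run_pipeline(pipeline_config(
  sim = sim_config(n_subjects = 800, n_snps = 300, n_causal = 40, seed = 7),
  param_grid = data.frame(max_depth = 3, eta = 0.1, nrounds = 80),
  n_boot = 200, seed = 7))

res
#> <bagprs_pipeline> n = 800 (448 smokers), 300 SNPs post-QC, 62 index SNPs, optimal P_T = 0.015

glance(res$prs$scan)
#> # A tibble: 1 × 5
#>   optimal_threshold     r        p n_snps_used n_thresholds
#>               <dbl> <dbl>    <dbl>       <int>        <int>
#> 1             0.015 0.427 2.54e-36          25          100

glance(res$brainage$fit)
#> # A tibble: 1 × 6
#>       r  r_lo  r_hi  rmse   mae     n
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <int>
#> 1 0.955 0.945 0.964  3.58  2.91   352

res$comparisons
#> # A tibble: 2 × 6
#>   measure       cohens_d     t        p    n1    n2
#>   <chr>            <dbl> <dbl>    <dbl> <int> <int>
#> 1 corrected_bag    0.631  8.68 2.92e-17   448   352
#> 2 prs_z            0.951 13.4  4.24e-37   448   352

tidy(res$mediation$bag_tgmv)
#> # A tibble: 5 × 4
#>   term       estimate   ci_lo ci_hi
#>   <chr>         <dbl>   <dbl> <dbl>
#> 1 acme1        0.0282 -0.0960 0.209
#> 2 acme2        0.766   0.0962 1.35
#> 3 acme_total   0.794   0.102  1.33
#> 4 tau          2.10    0.892  3.07
#> 5 tau_prime    1.30    0.386  2.08
```

Reading the output: the threshold scan picked P_T = 0.015 (25 SNPs), whose
z-scored score correlates r = 0.43 with smoking liability after covariate
adjustment. The never-smoker brain-age model reaches out-of-fold r = 0.955
(MAE 2.91 years) on this synthetic cohort, smokers carry a corrected-BAG
excess of d = 0.63, and in the two-mediator model most of the score's
effect on pack-years flows through total gray-matter volume (acme2) rather
than BAG (acme1), with PM ≈ 38%. Every result object has `tidy()`,
`glance()` and `autoplot()` methods.

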