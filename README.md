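# sgllmm

Multi-locus genome-wide association mapping for quantitative traits under
population structure, combining a **linear mixed model** (LMM) with a
**sparse group lasso** (SGL) over gene-grouped SNPs, plus stability
selection, mixed-model phenotype prediction, a structured synthetic-data
generator, and precision-recall evaluation of causal-SNP recovery.

## Who this is for

Statistical geneticists analysing a quantitative trait on a genotyped panel
(plant accessions, inbred lines, human cohorts) where relatedness and
population stratification confound single-SNP scans, and where SNPs have a
natural gene grouping that should inform selection.

## The model

The phenotype of *m* samples is

    y = X b + y_pop + phi,    y_pop ~ N(0, sg2 * K),    phi ~ N(0, se2 * I)

with `X` the (standardized) dosage matrix, `K = Z Z' / p` the realized
relationship matrix, and `delta = se2/sg2` the variance ratio. Fitting is
two-stage:

1. **Null model** (`estimate_delta`): with `b = 0`, profile out `sg2`
   through the eigendecomposition `K = U S U'` and minimize the
   one-dimensional profile likelihood in `delta` (grid on `ln delta` in
   [-10, 10], then bounded refinement).
2. **Rotation + sparse fit**: multiply `y` and `X` by
   `diag(1/sqrt(S + delta)) U'` so GLS becomes OLS, then solve

        min_b  ||y~ - X~ b||^2 / (2n)
               + lambda (1-alpha) sum_G sqrt(p_G) ||b_G||_2
               + lambda alpha ||b||_1

   along a 100-point geometric lambda path (`fit_path`), with `lambda`
   chosen by 5-fold cross-validation on held-out explained variance
   (`cv_select_lambda`) and SNPs ranked by **stability selection**
   (`stability_select`): 100 half-sample refits at the CV winner plus 9
   larger path penalties; a SNP's score is the fraction of resamples in
   which it ever enters the model; frequency >= 50% defines the selected
   set. New samples are predicted by `predict_phenotype` as
   `X'b + K_{X'X}(K_{XX} + delta I)^{-1}(y - Xb)`.

Four method variants share one code path: `lasso` / `sgl` (no mixed-model
rotation) and `lasso-lmm` / `sgl-lmm` (`alpha = 1` forces the lasso), which
is how the benchmark (`run_benchmark`) compares them.

## Worked example

Simulate a structured panel (300 samples, 400 SNPs in 40 gene groups, 15
causal SNPs in 3 groups, signal weight 0.4, confounder weight 0.7) and run
the full pipeline:

```r
library(sgllmm)
library(dplyr)

cfg <- sim_config(n_samples = 300, n_groups = 40, snps_per_group = 10,
                  sigma_sig = 0.4, sigma_pop = 0.7, seed = 11)
sim <- simulate_dataset(cfg)
run <- run_pipeline(sim$genotypes, sim$phenotype, sim$groups,
                    alpha = 0.95, n_resamples = 50, seed = 11)
run
#> <sgl_lmm_run> method sgl-lmm, alpha = 0.95
#> <null_model> delta = 0.07178, sigma_g2 = 0.3658
#> <cv_result> best lambda = 0.04729 (index 28 of 100), mean EV = 0.241
#> <stability_result> 13 of 400 SNPs selected (freq >= 0.50) over 50 resamples
```

`delta = 0.072` says the kinship random effect dominates the iid noise
(strong confounding, as simulated); cross-validation keeps about a quarter
of held-out variance explained by the sparse fixed effects. The ranked
stability table is the main result — `frequency` is the fraction of 50
half-sample refits in which the SNP entered the model:

```r
tidy(run) |> filter(frequency >= 0.5) |> head(8)
#> # A tibble: 8 × 6
#>   snp_id  group_id frequency selected beta_at_best_lambda  rank
#>   <chr>   <chr>        <dbl> <lgl>                  <dbl> <int>
#> 1 snp0050 gene005       1    TRUE                 -0.148      1
#> 2 snp0155 gene016       1    TRUE                 -0.138      2
#> 3 snp0182 gene019       1    TRUE                  0.0995     3
#> 4 snp0186 gene019       0.92 TRUE                 -0.0558     4
#> 5 snp0190 gene019       0.9  TRUE                  0.0527     5
#> 6 snp0331 gene034       0.82 TRUE                 -0.0380     6
#> 7 snp0157 gene016       0.72 TRUE                 -0.0394     7
#> 8 snp0258 gene026       0.7  TRUE                 -0.0232     8
```

Selected SNPs concentrate in a handful of genes, as the group penalty
encourages. Scoring the ranking against the simulated truth:

```r
ev <- pr_curve(run$stability$table$frequency,
               sim$causal_mask[match(run$stability$table$snp_id,
                                     sim$genotypes$snp_ids)])
ev
#> <ranking_eval> 15+/385- , PR-AUC = 0.6028, ROC-AUC = 0.8734
```

At this moderate signal level the ranking is good but imperfect — causal
SNPs with near-zero simulated effects are undetectable in principle (see
the methods vignette). `autoplot()` works on paths, CV curves, stability
results and PR curves; `tidy()`/`glance()` on every fitted object.

A thin command-line front end wrapping these functions ships at
`inst/cli/sgl-lmm.R` (subcommands `simulate`, `kinship`, `fit-null`, `run`,
`predict`, `evaluate`, `benchmark`).

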