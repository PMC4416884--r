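# pathrisk

Predicting censored survival (or recovery) risk from gene expression by
letting **gene sets and single genes compete as one feature pool**.

Single-gene survival signatures are notoriously unstable: with thousands of
genes, ~10² patients and heavy censoring, the genes that screen as
prognostic in one cohort rarely screen in the next. A gene-set expression
index averages noise over many member genes and is far more reproducible —
but curated collections are incomplete, and a set-only predictor is blind to
prognostic genes outside every set. `pathrisk` implements the hybrid
approach: every gene set becomes a per-sample expression index, every single
gene rides along as a pseudo gene set with one member, and one supervised
principal-components pipeline screens, selects and combines them.

## The method in brief

1. **Summarize.** Standardize each gene on training samples
   (`e' = (e − μ)/σ`). For each set `g` with `N_g` present members, take the
   per-sample **maxmean** statistic
   `u_gj = absmax[mean((e')₊), mean((e')₋)]`, then rescale `u_g` so the
   feature has the average mean and average variance of its member genes —
   putting set indices and raw genes on one scale. A one-member set
   reproduces its gene exactly.
2. **Score.** Every feature gets the Cox partial-likelihood score statistic
   at β = 0, `s = U(0)/√I(0)` (Breslow ties) — asymptotically N(0,1) under
   the null, so `|s|` is comparable across features.
3. **Select.** The `|s|` threshold is tuned by 100 repeats of 3-fold
   event-stratified cross-validation; every fold refits the whole pipeline
   and scores the held-out third by the Cox likelihood ratio of its
   predicted risk.
4. **Combine.** Selected features are centered, weighted by their member
   counts `diag(N₁…Nₙ)`, and reduced to the first principal component; with
   all `Nᵢ = 1` this is conventional PCA. Risk scores are projections onto
   the stored loading, oriented so higher risk means shorter survival.
5. **Evaluate.** Cox likelihood ratio, Harrell's C, Cox–Snell R², and the
   median-split log-rank test.

Everything — standardization, summary rescaling, centering, the loading —
is estimated on training samples only and replayed on test samples.

## Worked example

No external cohort is needed: the packaged generator builds a
benchmark-scale cohort (3 000 genes, 150 + 150 samples, 200 candidate sets
of which 5 carry planted pathway-level hazard signal, 30 % of signal genes
missing from the annotation):

```r
library(pathrisk)

sim <- simulate_cohort(sim_config(orphan_fraction = 0.3, seed = 2))
fit <- train_risk_model(sim$expr_train, sim$surv_train, sim$collection,
                        mode = "hybrid", n_repeats = 10, grid_size = 8,
                        seed = 2)
fit
#> <risk_model> mode = hybrid
#>   3200 candidate features, |score| threshold 2.933 -> 32 selected (5 gene sets, 27 single genes)

glance(fit)
#> # A tibble: 1 x 8
#>   mode   n_features n_selected n_gene_sets n_single_genes threshold cv_performance train_cox_coef
#>   <chr>       <int>      <int>       <int>          <int>     <dbl>          <dbl>          <dbl>
#> 1 hybrid       3200         32           5             27      2.93           5.32         0.0112

risk <- predict(fit, sim$expr_test)
evaluate_risk(risk$risk, sim$surv_test)
#> # A tibble: 1 x 9
#>   likelihood_ratio c_index r_squared logrank_p logrank_chisq split n_low n_high     n
#>              <dbl>   <dbl>     <dbl>     <dbl>         <dbl> <dbl> <int>  <int> <int>
#> 1             63.3   0.738     0.344  7.40e-11          42.4  16.2    75     75   150

sum(paste0("GS:", sim$truth$informative_sets) %in% fit$selected$feature_id)
#> [1] 5
```

Read: the cross-validated threshold keeps 32 of 3 200 candidate features —
all 5 planted informative sets plus 27 single genes, many from the hidden
(unannotated) signal blocks. On the held-out cohort the predictor reaches
Harrell's C = 0.74 (0.5 is chance), a Cox likelihood ratio of 63
(χ²₁ ≈ 3.8 at p = 0.05), and splitting test samples at the median risk
separates the two Kaplan–Meier curves at log-rank p ≈ 10⁻¹⁰. Performance
varies seed to seed (C roughly 0.6–0.78 under these conditions); `tidy(fit)`
lists the selected features with scores and loadings, and `autoplot(fit)`,
`autoplot(fit$search)` and `plot_km_split(risk$risk, sim$surv_test)` draw
the selection, the CV threshold curve and the KM curves.

The same pipeline runs from the shell on TSV/GMT files:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "pathrisk.R", package = "pathrisk"))')
Rscript $cli simulate --out_dir data --seed 1
Rscript $cli train    --expression data/expr_train.tsv --survival data/surv_train.tsv \
                      --gmt data/sets.gmt --mode hybrid --out_dir fit --seed 1
Rscript $cli predict  --predictor fit/predictor.json --expression data/expr_test.tsv \
                      --out risk.tsv
Rscript $cli evaluate --risk risk.tsv --survival data/surv_test.tsv --out report.json
```

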