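# mrstrat

Cell-type-stratified two-sample Mendelian randomization from summary
statistics.

## What problem this solves, and for whom

Two-sample Mendelian randomization (MR) estimates the causal effect of
an exposure on an outcome using genetic variants as instrumental
variables, from GWAS summary statistics alone. Standard practice pools
every genome-wide-significant variant into one instrument set — but
risk variants typically act by regulating particular genes in
particular cell types, and pooling averages that biology away.

`mrstrat` is for statistical geneticists and epidemiologists who have,
besides their exposure and outcome GWAS, *per-cell-type* (e.g.
single-cell-derived) cis-eQTL summary statistics. It assigns each GWAS
locus to the cell type(s) where its signal colocalizes with an eQTL
signal, builds a separate quality-controlled instrument set per cell
type, and reports a causal-effect estimate per cell type — so the
result reads "higher BMI raises disease risk through variants acting in
excitatory neurons", not just "higher BMI raises disease risk".

## The method in brief

1. **Colocalization with fine-mapping.** Per gene region (variant span
   ± 100 kb, MHC excluded), both the GWAS and the eQTL z-scores are
   fine-mapped with a sum-of-single-effects model,
   `z ~ N(R mu, R)`, giving 0.9-coverage credible sets. Every
   credible-set pair is tested for a shared causal variant by Bayes
   factor enumeration of the five colocalization hypotheses
   (`PPH0..PPH4`, per-variant log ABF = `log(1-r)/2 + r z^2/2` with
   `r = W/(V+W)`; priors p1 = p2 = 1e-4, p12 = 1e-5). `PPH4 > 0.8`
   declares colocalization and the top per-SNP H4 variant becomes a
   candidate instrument for that cell type.
2. **Instrument selection and QC.** Exposure relevance at
   `p < 5e-8`; removal of variants (or proxies at r² > 0.8) associated
   with confounders; greedy LD clumping (r² 0.001, 10,000 kb window);
   proxy substitution for variants missing from the outcome
   (r² > 0.8); allele harmonization with removal of palindromic
   variants at intermediate frequency (MAF > 0.42); radial IVW/Egger
   outlier removal at alpha 0.05; F-statistic
   `F = R^2 (N - k - 1) / (k (1 - R^2))` with
   `R^2_i = beta_i^2 / (beta_i^2 + SE_i^2 N)`, flagging `F < 10`.
3. **MR estimation.** Wald ratio, IVW (multiplicative random effects),
   MR-Egger, weighted median, weighted mode, and a robust adjusted
   profile score estimator; Cochran's Q, Rucker's Q′, the Egger
   intercept test, a simulation-based global pleiotropy test and
   leave-one-out sensitivity; a decision tree picks the main method
   (1 IV → Wald; all diagnostics clean → IVW; pleiotropy but Q′ clean →
   Egger; otherwise → weighted median). Significance is Bonferroni
   over outcomes × contexts (18 × 10 gives `p < 2.78e-4`).

Everything is driven either from R (`run_pipeline()`, `mr_fit()`, the
`simulate_*()` generators) or from the thin CLI in
`inst/cli/mrstrat.R` (subcommands `full`, `coloc`, `mr`, `simulate`).

## A worked example

Simulate a complete two-cell-type study with a causal effect
(beta = 0.5 per SD of exposure) routed through the variants that
colocalize in cell type A only, then run the full pipeline:

```r
library(mrstrat)
st  <- simulate_study(n_genes = 8, seed = 101)
res <- run_pipeline(st$exposure, st$eqtl, list(disease = st$outcome),
                    st$ld, seed = 101)
res
#> Cell-stratified MR results (Bonferroni threshold 0.025):
#>  outcome context         status n_iv chosen_method   beta      se         p
#>  disease   cellA             ok    8           ivw 0.4945 0.05547 4.894e-19
#>  disease   cellB no-instruments    0            NA     NA      NA        NA
#>  significant
#>         TRUE
#>        FALSE
```

Eight gene regions colocalize in cell type A (the planted context), the
harmonized instruments pass QC, and the IVW estimate 0.49 ± 0.06
recovers the planted 0.5 well inside its interval; cell type B's eQTL
signals sit on different causal variants, nothing colocalizes, and the
row is reported as `no-instruments` rather than a spurious estimate.
The per-fit detail shows the whole estimator suite and why IVW was
chosen as the main method:

```r
summary(res$fits[["cellA.disease"]])
#> Two-sample MR fit, 8 instruments
#>   method   beta      se   ci_low ci_high    pvalue n_iv main
#>      ivw 0.4945 0.05547  0.38578  0.6032 4.894e-19    8    *
#>    egger 0.5534 0.31073 -0.05564  1.1624 7.493e-02    8
#>  wmedian 0.5396 0.07546  0.34721  0.6384 8.624e-13    8
#>    wmode 0.5668 0.10213  0.29418  0.6809 2.867e-08    8
#>     raps 0.5032 0.04442  0.41616  0.5903 9.474e-30    8
#> Main MR method: ivw (branch 2) - no directional pleiotropy detected (all p > 0.05)
#>   triggering p-values: cochran_q_p=0.604, egger_intercept_p=0.854, presso_p=0.665
#> Cochran Q = 5.464 (df 7, p = 0.604); Rucker Q' = 5.427 (df 6, p = 0.49)
#> Egger intercept = -0.002643 (SE 0.01372), p = 0.854
#> Global pleiotropy test: RSS = 7.372, p = 0.6653 (1000 simulations)
```

## Layout

- `R/` — summary-statistics I/O and LD (`read_sumstats`, `load_ld`,
  `ld_from_genotypes`), fine-mapping (`susie_rss`, `credible_sets`),
  colocalization (`coloc_abf`, `coloc_susie`, `colocalize_region`),
  instrument pipeline (`select_candidates` … `instrument_strength`),
  estimators and diagnostics (`mr_fit` and friends), orchestration
  (`run_pipeline`, `bonferroni_adjust`, `write_report`), generators
  (`simulate_*`).
- `vignettes/cell-stratified-mr.Rmd` — the models, assumptions,
  defaults and design decisions in full.
- `tests/testthat/` — unit, property and calibration tests; all
  fixtures are generated in code.
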