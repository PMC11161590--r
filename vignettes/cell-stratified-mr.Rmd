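---
title: "Cell-type-stratified Mendelian randomization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-stratified Mendelian randomization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrstrat)
```

## The problem

Two-sample Mendelian randomization (MR) uses genetic variants as
instrumental variables to estimate the causal effect of an exposure
(say, BMI) on an outcome (say, a disease), from summary statistics of
two non-overlapping GWAS. Conventionally every genome-wide-significant
variant is an eligible instrument, which averages over the biology: a
risk variant typically acts by regulating a gene in a *particular* cell
type. `mrstrat` stratifies the instrument set by cell type before
estimation: a variant only instruments the exposure *in context c* if
the GWAS signal at its locus colocalizes with an eQTL signal for some
gene in cell type *c*. Each cell type then gets its own instrument set
and its own causal-effect estimate, so the analysis can say not just
"BMI causes X" but "BMI causes X through expression changes in
excitatory neurons".

The pipeline has three stages: (1) fine-mapping + colocalization of the
exposure GWAS against per-cell-type cis-eQTLs; (2) instrument selection
and quality control per cell type; (3) a suite of two-sample MR
estimators with pleiotropy diagnostics and a decision tree that picks
the main estimate.

## Stage 1: fine-mapping and colocalization

### Sum-of-single-effects fine-mapping

For a region of $p$ variants with marginal z-scores $z$ and an LD
(genotype correlation) matrix $R$, the standard regional model is

$$ z \sim N(R\,\mu,\; R), \qquad \mu = \textstyle\sum_{l=1}^{L} \mu_l, $$

where each single effect $\mu_l = \gamma_l \beta_l$ has one non-zero
coordinate ($\gamma_l$ multinomial over variants, $\beta_l \sim
N(0,\sigma_{0l}^2)$). `susie_rss()` fits this by coordinate ascent:
each effect in turn is re-fit as an exact Bayesian single-effect
regression on the residualized z-scores, with per-variant log Bayes
factor $-\tfrac12\log(1+\sigma_0^2) + \tfrac{z_r^2}{2}
\frac{\sigma_0^2}{1+\sigma_0^2}$. The variational objective (ELBO) is
tracked and is non-decreasing; convergence is declared when it changes
by less than `tol`.

Numerical choices:

* `L = 10`, `max_iter = 100`, `tol = 1e-3`, mirroring the published
  defaults of the sum-of-single-effects literature.
* $\sigma_{0l}^2$ is estimated per effect by one-dimensional
  maximization of the single-effect marginal likelihood and floored at
  0. An effect whose prior variance hits 0 collapses to its uniform
  prior, contributes nothing to the fit, and can never produce a
  credible set — this is what prevents phantom sets in null regions.
* LD matrices that fail positive semi-definiteness within $10^{-8}$ get
  a small ridge on the diagonal; matrices that are grossly indefinite
  (minimum eigenvalue below $-0.1$, usually a z/LD mismatch) are an
  error rather than silently "fixed".

A 0.9-coverage credible set per effect is the smallest
descending-probability prefix with cumulative inclusion mass $\ge 0.9$;
sets with purity (minimum absolute pairwise LD) below 0.5 are
discarded.

### Colocalization

For one gene in one cell type, the GWAS (trait 1) and the eQTL
(trait 2) are compared over the gene's cis region. Per variant and
trait, the asymptotic log Bayes factor for association is

$$ \log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac{r z^2}{2},
   \qquad r = \frac{W}{V+W}, $$

with $V$ the squared standard error and $W$ the squared prior effect
SD (0.15 for quantitative traits, 0.2 on the log-odds scale for binary
traits). Five hypotheses are enumerated — H0 no association, H1/H2 one
trait only, H3 both traits with distinct causal variants, H4 both with
a shared causal variant — with per-variant priors $p_1 = p_2 =
10^{-4}$, $p_{12} = 10^{-5}$ (the cited framework's documented
defaults, the only defensible reading of "default parameters"). All
Bayes-factor accumulation is in log space with log-sum-exp reductions,
so $|z| = 40$ is unremarkable.

When both traits yield credible sets, every pair of sets is tested
separately using the per-effect single-effect Bayes factors from the
fine-mapping fits (`coloc_susie()`), which is what makes multiple
causal variants per region tractable; when either side has no credible
set the single-causal-variant enumeration (`coloc_abf()`) is the
recorded fallback. A result with PPH4 strictly greater than 0.8 is
declared colocalized, and the variant maximizing the per-SNP H4
posterior is taken as the shared causal variant (ties break by smaller
GWAS p-value, then lexicographic id). When several credible-set pairs
colocalize for one gene, all pairs are reported and each contributes
its top variant; the multiplicity is flagged in the run log.

Regions are the span of a gene's tested cis-variants plus a 100 kb
flank on each side. The input schema deliberately carries no gene
coordinates (eQTL summary files rarely agree on them), so the tested
span is the natural anchor. The extended MHC
(chr6:28,477,797–33,448,354, GRCh37, closed interval) is excluded
before analysis because its LD structure defeats fine-mapping.

## Stage 2: instrument selection and quality control

Colocalized causal variants are pooled per cell type (union across
genes) and pass through a fixed stage order, each stage logging what it
dropped and why:

1. **Relevance**: exposure $p < 5\times10^{-8}$.
2. **Independence from confounders**: a candidate is removed when it or
   a proxy in LD at $r^2 > 0.8$ appears in a user-supplied
   confounder-association table at $p < 5\times10^{-8}$. The table is a
   local file, not a web query; any (snp, trait, p) export works. The
   paper trail behind such tables names education, drinking and smoking
   as the confounders of record for adiposity exposures. The
   confounder p-value threshold is configurable because no consensus
   value exists.
3. **LD clumping**: greedy by ascending p (ties: position, then id),
   keeping a variant only if no kept variant within 10,000 kb has
   $r^2 > 0.001$ with it. Sorting makes the result independent of input
   order.
4. **Proxy substitution**: an index variant absent from the outcome
   GWAS is replaced by its highest-$r^2$ proxy ($r^2 > 0.8$) present in
   both datasets and itself exposure-significant; provenance is kept.
5. **Harmonization**: outcome effects are aligned to the exposure's
   effect allele, handling allele swaps (negate, flip frequency) and
   strand flips (only attempted when the allele pair is
   non-palindromic). Palindromic variants (A/T, C/G) with minor-allele
   frequency above 0.42 — i.e. EAF inside (0.42, 0.58) — in either
   dataset are removed as strand-ambiguous, as are palindromes with a
   missing frequency; the remainder are resolved by frequency matching.
   Harmonization is involutive.
6. **Radial outlier removal**: per-variant ratio estimates with
   first-order radial weights $w_j = \hat\gamma_j^2/\mathrm{se}(\hat\Gamma_j)^2$
   are fit by origin-constrained (IVW) and intercept (Egger) radial
   regressions; each variant's Q contribution is referred to
   $\chi^2_1$ and the union of variants significant at $\alpha = 0.05$
   under either fit is removed in a single pass (an `iterate` option
   repeats to exhaustion; the single pass is the default because the
   source procedure discards outliers once). Below 3 instruments the
   filter passes through unchanged.
7. **Instrument strength**: per-variant
   $R^2_i = \beta_i^2/(\beta_i^2 + \mathrm{SE}_i^2 N)$, summed, and
   $F = R^2 (N-k-1) / (k (1-R^2))$; $F < 10$ flags the set as weak (the
   flag is reported, not silently acted on).

## Stage 3: the estimator suite and the decision tree

`mr_fit()` is the central fitting function; it returns a classed object
with `print`, `summary`, `coef`, `confint`, `plot` and `residuals`
methods. With instrument-exposure effects $\hat\gamma_j$ and
instrument-outcome effects $\hat\Gamma_j$:

* **Wald ratio** (k = 1): $\hat\Gamma/\hat\gamma$, SE by the
  first-order delta method.
* **IVW** (k ≥ 2): origin-constrained WLS of $\hat\Gamma$ on
  $\hat\gamma$ with weights $1/\mathrm{se}(\hat\Gamma)^2$, multiplicative
  random-effects SE scaled by $\max(1, \sqrt{Q/(k-1)})$.
* **MR-Egger** (k ≥ 3): the same regression with an intercept after
  orienting all $\hat\gamma_j > 0$; the slope is the causal estimate
  under InSIDE, the intercept the average directional pleiotropy. The
  intercept test uses a t reference with $k-2$ df.
* **Weighted median** (k ≥ 3): weighted 50th percentile of the ratio
  estimates (midpoint convention, linear interpolation), weights
  $\hat\gamma^2/\mathrm{se}(\hat\Gamma)^2$; SE by seeded parametric
  bootstrap (default 1000 draws), percentile CI.
* **Weighted mode** (k ≥ 3): argmax of the weighted kernel density of
  the ratios; bandwidth is a weighted-MAD scale times a modified
  Silverman factor (`bandwidth_factor` default 1, with a weighted-SD
  fallback when more than half the weight ties at one ratio); exact
  density ties break toward the smaller ratio; bootstrap SE/CI as for
  the median.
* **Robust adjusted profile score** (k ≥ 3): solves
  $\sum_j \psi(t_j)\,\hat\gamma_j/\sigma_j +
  (\psi(t_j)t_j - \delta)\,\beta\,\mathrm{se}(\hat\gamma_j)^2/\sigma_j^2 = 0$
  with $t_j = (\hat\Gamma_j - \beta\hat\gamma_j)/\sigma_j$,
  $\sigma_j^2 = \mathrm{se}(\hat\Gamma_j)^2 + \beta^2\,\mathrm{se}(\hat\gamma_j)^2 + \tau^2$,
  $\psi$ the Huber score (c = 1.345, $\delta = 2\Phi(c)-1$), and the
  overdispersion $\tau^2 \ge 0$ from the companion moment equation;
  SE from the sandwich variance of the score.

Diagnostics: Cochran's Q ($\chi^2_{k-1}$) for the IVW fit, Rucker's Q′
($\chi^2_{k-2}$) for the Egger fit (Q ≥ Q′ by nesting), the Egger
intercept test, a simulation-based global pleiotropy test (observed
leave-one-out weighted RSS against a parametric null, p reported with
the +1 correction so it is never exactly 0; default 1000 draws, k ≥ 4),
and a leave-one-out table flagging any variant whose exclusion flips
the sign or the significance of the IVW estimate.

The main method is chosen by the decision tree: (1) one instrument →
Wald ratio; (2) Cochran Q, Egger intercept and the global test all
clean at $\alpha = 0.05$ → IVW; (3) pleiotropy detected but Q′ clean →
MR-Egger; (4) pleiotropy detected and Q′ significant → weighted median,
preferred over the weighted mode for power (both are always reported).
A diagnostic that cannot be computed (e.g. the global test below 4
instruments) is treated as non-significant but the choice is marked
*diagnostic-incomplete* rather than silently trusted; a diagnostic
required by the branch actually reached is an error if missing.

Finally, significance is declared at the Bonferroni threshold
$\alpha/(\text{outcomes}\times\text{contexts})$ per exposure — e.g. 18
outcomes over 8 cell types + 2 tissues give $0.05/180 =
2.78\times10^{-4}$.

## The synthetic-data generators

The generators are first-class, tested code; every fixture in the test
suite comes from them, seeded.

* `simulate_ld()` builds block-autoregressive LD ($r = \rho^d$ within a
  block, blocks unlinked), and `simulate_genotypes()` realizes it with
  a Markov-chain haplotype sampler whose transition kernel reproduces
  the adjacent correlation exactly (optionally written as VCF).
* `simulate_region_sumstats()` draws marginal z-scores directly from
  $N(R z_{\text{true}}, R)$ — exactly the model the fine-mapping and
  colocalization machinery assumes — and back-computes betas and SEs
  from allele frequency and sample size. This is deliberate: no
  individual-level phenotypes, desk-scale fast, and z/LD consistency by
  construction. Default effective sample sizes ($n_{\text{GWAS}} =
  10^5$, $n_{\text{eQTL}} = 200$) echo the scale disparity between
  biobank GWAS and single-cell eQTL studies; planted causal z-scores
  default to 8, a clearly genome-wide-significant but not degenerate
  signal.
* `simulate_mr_dataset()` plants a causal effect with configurable
  pleiotropy (none, balanced, directional with InSIDE holding by
  construction, or outliers). Default exposure effects 0.03–0.1 per SD
  with SE 0.004 and outcome SE 0.05 give instruments of realistic
  strength (F well above 10) and ratio noise.
* `simulate_study()` wires whole studies: multiple gene regions on
  separate chromosomes (so clumping windows never collide), a shared
  cell-type context whose eQTL causal variants coincide with the GWAS
  ones, a distinct context whose causal variants sit in unlinked
  blocks, and an outcome affected only through the exposure.

What the generators do **not** emulate: real human LD maps and
allele-frequency spectra, sample overlap between the two GWAS, winner's
curse in instrument discovery, non-normal effect distributions, and
assay-specific eQTL noise. Passing calibration on these simulations
shows the machinery is implemented correctly and calibrated under its
own assumptions; it does not certify performance on any particular real
dataset.

## Problem sizes used in the checks

The shipped calibration checks use 200 seeded regions for the
colocalization and fine-mapping rates, 500 replicates for IVW CI
coverage (2000 in the acceptance script), 200 for the Egger-intercept
sign rate and the global-test size, 500 for the Q-test size, and 100
end-to-end pipeline runs on a 15-gene, 2-context study. These sizes put
Monte-Carlo error comfortably below the margins being tested while
keeping a full run in the minutes range on one core.

## A worked example

```{r example, eval = FALSE}
st <- simulate_study(n_genes = 8, seed = 101)
res <- run_pipeline(st$exposure, st$eqtl, list(disease = st$outcome),
                    st$ld, seed = 101)
res
fit <- res$fits[["cellA.disease"]]
summary(fit)
plot(fit)
```

## Known limitations

* No multivariable MR, no Steiger directionality filtering, no
  outlier-*correction* (outliers are removed by the radial filter, not
  re-estimated), no CAUSE/contamination-mixture estimators.
* Single-causal-variant colocalization is the fallback, not a
  user-visible mode switch per gene.
* No genome-build liftover; all coordinates are assumed GRCh37.
* The confounder filter searches proxies only within the loaded LD
  matrix.
* Trans-eQTL tables pass through unchanged (nothing in the machinery is
  cis-specific), but regions are still formed from the variant span, so
  extremely dispersed trans signals would form oversized regions.
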