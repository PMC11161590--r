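# Seedable synthetic-data generators with known ground truth for every
# pipeline stage. Regional summary statistics are simulated directly at
# the z-score level under the standard model z ~ N(R z_true, R) — exactly
# the model the fine-mapping and colocalization machinery assumes — with
# betas/SEs back-computed from z, allele frequency and sample size.
# Default effective sample sizes (n_gwas 1e5, n_eqtl 200) echo the scale
# disparity between biobank GWAS and single-cell eQTL studies.

#' Block-autoregressive LD matrix
#'
#' Within each block the correlation decays as `rho^distance`; blocks are
#' mutually unlinked. `rho = 0` gives the identity.
#'
#' @param n_snps Number of variants.
#' @param rho Within-block adjacent correlation, in `[0, 1)`.
#' @param block_size Variants per block (last block may be shorter).
#' @param snp_ids Optional ids (default `snp1..snpP`).
#' @return LD matrix.
#' @export
simulate_ld <- function(n_snps, rho = 0.9, block_size = n_snps,
                        snp_ids = paste0("snp", seq_len(n_snps))) {
  stopifnot(rho >= 0, rho < 1, block_size >= 1)
  block <- rep(seq_len(ceiling(n_snps / block_size)), each = block_size)[seq_len(n_snps)]
  idx <- seq_len(n_snps)
  d <- abs(outer(idx, idx, "-"))
  r <- rho^d * outer(block, block, "==")
  diag(r) <- 1
  as_ld_matrix(r, snp_ids)
}

#' Simulate a genotype reference panel realizing an AR LD structure
#'
#' Haplotypes are drawn from a Markov chain whose transition kernel
#' reproduces the target adjacent correlation exactly (so LD at distance d
#' is `rho^d` in expectation); genotypes are sums of two haplotypes.
#' Optionally written as an uncompressed VCF v4.2.
#'
#' @param n_snps,rho,block_size As [simulate_ld()].
#' @param n_samples Diploid sample count.
#' @param maf Allele frequency used for every site.
#' @param vcf_path Optional path to write a VCF.
#' @param seed Optional RNG seed.
#' @return Integer dosage matrix (SNPs x samples) with ids as rownames;
#'   attribute `"vcf_path"` when written.
#' @export
simulate_genotypes <- function(n_snps, n_samples, rho = 0.9,
                               block_size = n_snps, maf = 0.3,
                               vcf_path = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  block <- rep(seq_len(ceiling(n_snps / block_size)), each = block_size)[seq_len(n_snps)]
  draw_hap <- function() {
    h <- integer(n_snps)
    h[1] <- stats::rbinom(1, 1, maf)
    for (j in 2:n_snps) {
      if (block[j] != block[j - 1]) {
        h[j] <- stats::rbinom(1, 1, maf)
      } else {
        pr <- if (h[j - 1] == 1) maf + rho * (1 - maf) else maf * (1 - rho)
        h[j] <- stats::rbinom(1, 1, pr)
      }
    }
    h
  }
  dos <- matrix(0L, n_snps, n_samples)
  for (s in seq_len(n_samples)) dos[, s] <- draw_hap() + draw_hap()
  rownames(dos) <- paste0("snp", seq_len(n_snps))
  if (!is.null(vcf_path)) {
    write_vcf(dos, vcf_path)
    attr(dos, "vcf_path") <- vcf_path
  }
  dos
}

# Minimal uncompressed VCF v4.2 writer for a dosage matrix (REF=A, ALT=G).
write_vcf <- function(dos, path, chrom = "1", pos = NULL) {
  if (is.null(pos)) pos <- seq_len(nrow(dos)) * 1000L
  gt_of <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT",
                     paste0("sample", seq_len(ncol(dos)))), collapse = "\t"))
  body <- vapply(seq_len(nrow(dos)), function(i) {
    paste(c(chrom, pos[i], rownames(dos)[i], "A", "G", ".", "PASS", ".",
            "GT", gt_of[dos[i, ] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

# Draw alleles for p SNPs; a configurable fraction are palindromic so the
# harmonization paths get exercised.
draw_alleles <- function(p, palindrome_frac = 0.2) {
  pal <- stats::runif(p) < palindrome_frac
  ea <- sample(c("A", "C", "G", "T"), p, replace = TRUE)
  oa <- character(p)
  oa[pal] <- flip_strand(ea[pal])
  for (i in which(!pal)) {
    oa[i] <- sample(setdiff(c("A", "C", "G", "T"),
                            c(ea[i], flip_strand(ea[i]))), 1)
  }
  list(ea = ea, oa = oa)
}

# Marginal z-scores for one region: z ~ N(R z_true, R).
draw_region_z <- function(R, z_true, chol_R = NULL) {
  if (is.null(chol_R)) chol_R <- chol(R + diag(1e-8, nrow(R)))
  drop(R %*% z_true) + drop(crossprod(chol_R, stats::rnorm(nrow(R))))
}

# Back out beta/se from z, maf and n for a standardized trait.
z_to_beta <- function(z, maf, n) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n)
  list(beta = z * se, se = se)
}

sumstats_skeleton <- function(snp, chr, pos, alle, eaf, z, n) {
  bs <- z_to_beta(z, eaf, n)
  data.frame(snp = snp, chr = as.character(chr), pos = as.integer(pos),
             ea = alle$ea, oa = alle$oa, eaf = eaf,
             beta = bs$beta, se = bs$se,
             p = 2 * stats::pnorm(-abs(z)), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate one region's GWAS and per-context eQTL summary statistics
#'
#' Plants a causal variant for the GWAS trait and, per context, either the
#' same (shared) or a distinct (or no) causal variant for the eQTL trait,
#' then draws marginal z-scores from `N(R z_true, R)` and back-computes
#' betas and SEs.
#'
#' @param n_snps Region size (default 50).
#' @param rho,block_size LD structure (see [simulate_ld()]).
#' @param causal Index of the GWAS causal SNP (default centre of block 1).
#' @param z_gwas Target causal z-score for the GWAS trait (default 8).
#' @param contexts Named list: each element a list with `shared` (logical),
#'   optional `causal` (index; required when not shared and not null) and
#'   `z` (target z, default 8). A context with `causal = NA` is a null
#'   context.
#' @param n_gwas,n_eqtl Effective sample sizes (defaults 1e5 and 200).
#' @param maf_range Allele-frequency range (default 0.05-0.5).
#' @param palindrome_frac Fraction of palindromic variants.
#' @param chrom,pos_start,pos_step Coordinates assigned to the variants.
#' @param gene Gene id label for the eQTL records.
#' @param seed Optional RNG seed.
#' @return List: `gwas` (canonical data frame), `eqtl` (one data frame,
#'   all contexts stacked), `ld`, `truth` (planted indices/ids and
#'   config).
#' @export
simulate_region_sumstats <- function(n_snps = 50, rho = 0.9,
                                     block_size = n_snps,
                                     causal = NULL, z_gwas = 8,
                                     contexts = list(cellA = list(shared = TRUE, z = 8)),
                                     n_gwas = 1e5, n_eqtl = 200,
                                     maf_range = c(0.05, 0.5),
                                     palindrome_frac = 0.2,
                                     chrom = "1", pos_start = 1e6,
                                     pos_step = 2000, gene = "gene1",
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- simulate_ld(n_snps, rho = rho, block_size = block_size)
  chol_R <- chol(unclass(R) + diag(1e-8, n_snps))
  if (is.null(causal)) causal <- max(1L, min(n_snps, block_size) %/% 2L)
  snp <- paste0(chrom, "_", gene, "_snp", seq_len(n_snps))
  rownames(R) <- colnames(R) <- snp
  pos <- pos_start + (seq_len(n_snps) - 1L) * pos_step
  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  alle <- draw_alleles(n_snps, palindrome_frac)

  z_true <- numeric(n_snps)
  z_true[causal] <- z_gwas
  gwas <- sumstats_skeleton(snp, chrom, pos, alle, maf,
                            draw_region_z(R, z_true, chol_R), n_gwas)

  eqtl <- list()
  truth_ctx <- list()
  for (cx in names(contexts)) {
    cfg <- contexts[[cx]]
    zc <- if (is.null(cfg$z)) 8 else cfg$z
    ci <- if (isTRUE(cfg$shared)) causal else cfg$causal
    zt <- numeric(n_snps)
    if (!is.null(ci) && !is.na(ci)) zt[ci] <- zc
    e <- sumstats_skeleton(snp, chrom, pos, alle, maf,
                           draw_region_z(R, zt, chol_R), n_eqtl)
    e$gene <- gene
    e$context <- cx
    eqtl[[cx]] <- e
    truth_ctx[[cx]] <- list(causal = if (is.null(ci)) NA_integer_ else ci,
                            shared = isTRUE(cfg$shared))
  }
  list(gwas = gwas, eqtl = do.call(rbind, eqtl), ld = R,
       truth = list(causal_gwas = causal, causal_snp = snp[causal],
                    contexts = truth_ctx, seed = seed))
}

#' Simulate a two-sample MR instrument dataset with known truth
#'
#' Per-SNP exposure effects are drawn uniformly from `gamma_range`
#' (positive); outcome effects are `true_beta * gamma + pleiotropy +
#' noise` with the configured SEs. Pleiotropy models: `"none"`,
#' `"balanced"` (N(0, tau)), `"directional"` (N(delta, tau), independent
#' of instrument strength so InSIDE holds), `"outlier"` (`n_outlier` SNPs
#' receive a direct effect of `outlier_size` outcome-SE units).
#'
#' @param k Number of instruments (default 20).
#' @param true_beta Causal effect (default 0.3).
#' @param gamma_range Exposure effect range (default 0.03-0.1 per SD).
#' @param se_exp,se_out Summary-statistic standard errors.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"outlier"`.
#' @param tau Pleiotropy SD for balanced/directional models.
#' @param delta Mean directional pleiotropy.
#' @param n_outlier,outlier_size Outlier model parameters.
#' @param palindrome_frac Fraction of palindromic variants.
#' @param seed Optional RNG seed.
#' @return List: `exposure`/`outcome` canonical tables, `instruments`
#'   (pre-harmonized table ready for [mr_fit()]), `truth`.
#' @export
simulate_mr_dataset <- function(k = 20, true_beta = 0.3,
                                gamma_range = c(0.03, 0.1),
                                se_exp = 0.004, se_out = 0.05,
                                pleiotropy = c("none", "balanced",
                                               "directional", "outlier"),
                                tau = 0.05, delta = 0.1, n_outlier = 1,
                                outlier_size = 10, palindrome_frac = 0.2,
                                seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k >= 1, se_exp > 0, se_out > 0)
  gamma <- stats::runif(k, gamma_range[1], gamma_range[2])
  direct <- switch(pleiotropy,
                   none = rep(0, k),
                   balanced = stats::rnorm(k, 0, tau),
                   directional = stats::rnorm(k, delta, tau),
                   outlier = {
                     d <- rep(0, k)
                     d[sample.int(k, n_outlier)] <- outlier_size * se_out
                     d
                   })
  se_exp <- rep(se_exp, length.out = k)
  se_out <- rep(se_out, length.out = k)
  bx <- stats::rnorm(k, gamma, se_exp)
  by <- stats::rnorm(k, true_beta * gamma + direct, se_out)
  snp <- paste0("iv", seq_len(k))
  alle <- draw_alleles(k, palindrome_frac)
  eaf <- stats::runif(k, 0.05, 0.95)
  chr <- as.character(rep_len(1:22, k))
  pos <- (seq_len(k)) * 25000000L
  exposure <- data.frame(snp = snp, chr = chr, pos = pos, ea = alle$ea,
                         oa = alle$oa, eaf = eaf, beta = bx, se = se_exp,
                         p = 2 * stats::pnorm(-abs(bx / se_exp)), n = 1e5,
                         stringsAsFactors = FALSE)
  outcome <- exposure
  outcome$beta <- by
  outcome$se <- se_out
  outcome$p <- 2 * stats::pnorm(-abs(by / se_out))
  outcome$n <- 5e4
  instruments <- data.frame(snp = snp, ea = alle$ea, oa = alle$oa,
                            beta_exp = bx, se_exp = se_exp,
                            p_exp = exposure$p, eaf_exp = eaf,
                            beta_out = by, se_out = se_out, eaf_out = eaf,
                            context = "sim", provenance = "original",
                            stringsAsFactors = FALSE)
  class(instruments) <- c("instruments", "data.frame")
  list(exposure = exposure, outcome = outcome, instruments = instruments,
       truth = list(beta = true_beta, gamma = gamma, direct = direct,
                    pleiotropy = pleiotropy,
                    outliers = snp[direct != 0 & pleiotropy == "outlier"],
                    seed = seed))
}

#' Simulate a complete multi-gene, multi-context study
#'
#' Builds everything [run_pipeline()] needs, with a causal effect of the
#' exposure on the outcome routed through every gene region's causal
#' variant. In the `shared` context the eQTL causal variant coincides
#' with the GWAS causal variant in every gene region (so those regions
#' colocalize and feed instruments); in the `distinct` context the eQTL
#' causal variant sits in an unlinked LD block (so colocalization fails
#' and the context yields no instruments).
#'
#' @param n_genes Gene regions (default 15; one instrument each).
#' @param n_snps_per_gene Variants per region (two unlinked AR blocks).
#' @param rho LD decay within blocks.
#' @param true_beta Causal effect of exposure on outcome (default 0.5).
#' @param z_gwas,z_eqtl Planted causal z-scores.
#' @param contexts Labels for the shared-causal and distinct-causal
#'   contexts.
#' @param n_gwas,n_eqtl,n_outcome Effective sample sizes.
#' @param seed Optional RNG seed.
#' @return List: `exposure`, `eqtl`, `outcome`, `ld` (block-diagonal over
#'   all regions), `truth`.
#' @export
simulate_study <- function(n_genes = 15, n_snps_per_gene = 40, rho = 0.9,
                           true_beta = 0.5, z_gwas = 9, z_eqtl = 8,
                           contexts = c(shared = "cellA", distinct = "cellB"),
                           n_gwas = 1e5, n_eqtl = 200, n_outcome = 5e4,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  block <- n_snps_per_gene %/% 2L
  gwas <- eqtl <- outc <- list()
  lds <- list()
  truth <- list(causal_snps = character(n_genes), beta = true_beta)
  for (g in seq_len(n_genes)) {
    chrom <- as.character(((g - 1L) %% 22L) + 1L)
    pos0 <- 1e6 + ((g - 1L) %/% 22L) * 5e7
    ctx <- list()
    ctx[[contexts[["shared"]]]] <- list(shared = TRUE, z = z_eqtl)
    ctx[[contexts[["distinct"]]]] <- list(shared = FALSE,
                                          causal = block + block %/% 2L,
                                          z = z_eqtl)
    reg <- simulate_region_sumstats(
      n_snps = n_snps_per_gene, rho = rho, block_size = block,
      causal = block %/% 2L, z_gwas = z_gwas, contexts = ctx,
      n_gwas = n_gwas, n_eqtl = n_eqtl, chrom = chrom, pos_start = pos0,
      gene = paste0("gene", g), palindrome_frac = 0.1)
    # outcome trait: affected through the exposure at the causal variant
    gamma <- reg$gwas$beta[reg$truth$causal_gwas]
    se_out_c <- 1 / sqrt(2 * reg$gwas$eaf * (1 - reg$gwas$eaf) * n_outcome)
    zt_out <- numeric(n_snps_per_gene)
    zt_out[reg$truth$causal_gwas] <- true_beta * gamma / se_out_c[reg$truth$causal_gwas]
    R <- unclass(reg$ld)
    z_out <- draw_region_z(R, zt_out)
    out <- reg$gwas
    out$beta <- z_out * se_out_c
    out$se <- se_out_c
    out$p <- 2 * stats::pnorm(-abs(z_out))
    out$n <- n_outcome
    gwas[[g]] <- reg$gwas
    eqtl[[g]] <- reg$eqtl
    outc[[g]] <- out
    lds[[g]] <- reg$ld
    truth$causal_snps[g] <- reg$truth$causal_snp
  }
  p_tot <- n_genes * n_snps_per_gene
  ld <- matrix(0, p_tot, p_tot)
  ids <- unlist(lapply(lds, rownames))
  dimnames(ld) <- list(ids, ids)
  off <- 0L
  for (g in seq_len(n_genes)) {
    idx <- off + seq_len(n_snps_per_gene)
    ld[idx, idx] <- lds[[g]]
    off <- off + n_snps_per_gene
  }
  list(exposure = do.call(rbind, gwas), eqtl = do.call(rbind, eqtl),
       outcome = do.call(rbind, outc), ld = as_ld_matrix(ld, ids),
       truth = truth, contexts = unname(contexts))
}
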