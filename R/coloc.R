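# Bayesian colocalization of two association signals (GWAS trait 1, eQTL
# trait 2) in one region: per-SNP asymptotic Bayes factors under a normal
# effect prior, enumeration of the five hypotheses H0-H4, and a
# credible-set-pairwise mode that reuses per-effect Bayes factors from the
# fine-mapping fit when multiple causal variants are present. All Bayes
# factor accumulation is in log space.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`), or both (`p12`), and the prior effect-size standard
#' deviations for quantitative (`prior_sd_quant`) and binary
#' (`prior_sd_cc`, log-odds scale) traits. Defaults are the field-standard
#' values.
#'
#' @param p1,p2,p12 Per-SNP prior association probabilities.
#' @param prior_sd_quant,prior_sd_cc Prior effect SDs.
#' @return List of class `"abf_params"`.
#' @export
abf_params <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd_quant = 0.15, prior_sd_cc = 0.2) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p1 + p2 + p12 <= 1,
            prior_sd_quant >= 0, prior_sd_cc >= 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant, prior_sd_cc = prior_sd_cc),
            class = "abf_params")
}

#' Log approximate Bayes factor for one association
#'
#' With sampling variance `V = se^2`, prior variance `W = prior_sd^2`,
#' `z = beta/se` and shrinkage `r = W/(V+W)`, the natural log of the
#' asymptotic Bayes factor is `log(1-r)/2 + r z^2/2`.
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @param prior_sd Prior effect SD (`>= 0`); 0 gives log BF = 0.
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd < 0)) stop("prior_sd must be non-negative")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log1p(-r) + r * (beta / se)^2 / 2
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Hypothesis enumeration from two vectors of per-SNP log Bayes factors.
# Unnormalized masses: H0 = 1; H1 = p1*S1; H2 = p2*S2;
# H3 = p1*p2*(S1*S2 - S12); H4 = p12*S12, with S12 = sum_i BF1_i*BF2_i.
coloc_enumerate <- function(labf1, labf2, params) {
  l1 <- logsumexp(labf1)
  l2 <- logsumexp(labf2)
  l12 <- logsumexp(labf1 + labf2)
  # log(S1*S2 - S12), guarded for the single-SNP region where S1*S2 = S12
  d <- l12 - (l1 + l2)
  lh3_body <- if (d >= 0) -Inf else l1 + l2 + log1p(-exp(d))
  lh <- c(H0 = 0,
          H1 = log(params$p1) + l1,
          H2 = log(params$p2) + l2,
          H3 = log(params$p1) + log(params$p2) + lh3_body,
          H4 = log(params$p12) + l12)
  pph <- exp(lh - logsumexp(lh))
  names(pph) <- paste0("PP", names(lh))
  snp_l <- labf1 + labf2
  list(pph = pph, per_snp_h4 = exp(snp_l - logsumexp(snp_l)))
}

new_coloc_result <- function(enum, snps, mode, signal_pair = NULL, trait1_p = NULL) {
  names(enum$per_snp_h4) <- snps
  structure(list(pph = enum$pph, per_snp_h4 = enum$per_snp_h4, snps = snps,
                 n_snps = length(snps), mode = mode, signal_pair = signal_pair,
                 trait1_p = trait1_p),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization (", x$mode, " mode, ", x$n_snps, " SNPs",
      if (!is.null(x$signal_pair))
        paste0(", signal pair ", x$signal_pair[1], "/", x$signal_pair[2]),
      ")\n", sep = "")
  print(round(x$pph, 4))
  top <- which.max(x$per_snp_h4)
  cat("Top shared-variant candidate:", names(x$per_snp_h4)[top],
      "(h4 share", signif(x$per_snp_h4[top], 3), ")\n")
  invisible(x)
}

# Align trait 2 records to trait 1's allele orientation on the shared SNPs.
# Returns merged data frame with beta2 sign-corrected; allele-incompatible
# SNPs are dropped.
align_traits <- function(trait1, trait2) {
  shared <- intersect(trait1$snp, trait2$snp)
  if (length(shared) == 0L) stop("no shared SNPs between the two traits")
  t1 <- trait1[match(shared, trait1$snp), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$snp), , drop = FALSE]
  flip <- rep(1, length(shared))
  if (all(c("ea", "oa") %in% names(t1)) && all(c("ea", "oa") %in% names(t2))) {
    same <- t1$ea == t2$ea & t1$oa == t2$oa
    swap <- t1$ea == t2$oa & t1$oa == t2$ea
    keep <- same | swap
    t1 <- t1[keep, , drop = FALSE]
    t2 <- t2[keep, , drop = FALSE]
    flip <- ifelse(swap[keep], -1, 1)
  }
  if (nrow(t1) == 0L) stop("no allele-compatible shared SNPs")
  data.frame(snp = t1$snp, beta1 = t1$beta, se1 = t1$se, p1v = t1$p,
             beta2 = flip * t2$beta, se2 = t2$se,
             stringsAsFactors = FALSE)
}

#' Single-causal-variant colocalization from marginal statistics
#'
#' Enumerates the five hypotheses (H0: no association; H1/H2: one trait
#' only; H3: both, distinct causal variants; H4: both, shared causal
#' variant) from per-SNP approximate Bayes factors of the two traits,
#' assuming at most one causal variant per trait in the region.
#'
#' @param trait1,trait2 Canonical summary-statistics data frames sharing
#'   SNP ids (trait 1 is the GWAS, trait 2 the eQTL, by convention).
#' @param params [abf_params()].
#' @param type1,type2 `"quant"` or `"cc"` per trait, selecting the prior SD.
#' @return A `"coloc_result"`: `pph` (PPH0..PPH4, summing to 1),
#'   `per_snp_h4` (posterior share of each SNP being the shared variant
#'   under H4), `snps`, `n_snps`, `mode = "abf"`.
#' @export
coloc_abf <- function(trait1, trait2, params = abf_params(),
                      type1 = "quant", type2 = "quant") {
  m <- align_traits(trait1, trait2)
  sd1 <- if (type1 == "cc") params$prior_sd_cc else params$prior_sd_quant
  sd2 <- if (type2 == "cc") params$prior_sd_cc else params$prior_sd_quant
  labf1 <- log_abf(m$beta1, m$se1, sd1)
  labf2 <- log_abf(m$beta2, m$se2, sd2)
  new_coloc_result(coloc_enumerate(labf1, labf2, params), m$snp, "abf",
                   trait1_p = stats::setNames(m$p1v, m$snp))
}

#' Credible-set-pairwise colocalization from fine-mapping fits
#'
#' For every pair of surviving credible sets (one per trait), the
#' hypothesis enumeration of [coloc_abf()] is run on the per-effect
#' single-effect log Bayes factors of the corresponding fine-mapping
#' effects, so each causal signal is tested for sharing separately. Both
#' fits must be over the same SNP universe in the same order.
#'
#' @param fit1,fit2 [susie_rss()] fits for trait 1 and trait 2.
#' @param sets1,sets2 [credible_sets()] output for each fit.
#' @param params [abf_params()].
#' @param trait1_p Optional named per-SNP trait-1 p-values (tie-breaks in
#'   [top_causal_snp()]).
#' @return List of `"coloc_result"` objects (mode `"susie"`), one per
#'   credible-set pair, each with `signal_pair = c(set index 1, set
#'   index 2)`; empty list when either side has no credible set.
#' @export
coloc_susie <- function(fit1, sets1, fit2, sets2, params = abf_params(),
                        trait1_p = NULL) {
  if (length(sets1) == 0L || length(sets2) == 0L) return(list())
  if (ncol(fit1$alpha) != ncol(fit2$alpha))
    stop("fits must share one SNP universe")
  snps <- fit1$snps
  if (is.null(snps)) snps <- as.character(seq_len(ncol(fit1$alpha)))
  out <- list()
  for (i in seq_along(sets1)) {
    for (j in seq_along(sets2)) {
      l1 <- fit1$lbf[sets1[[i]]$effect, ]
      l2 <- fit2$lbf[sets2[[j]]$effect, ]
      res <- new_coloc_result(coloc_enumerate(l1, l2, params), snps, "susie",
                              signal_pair = c(i, j), trait1_p = trait1_p)
      out[[length(out) + 1L]] <- res
    }
  }
  out
}

#' Classify a colocalization result
#'
#' @param result A `"coloc_result"`.
#' @param threshold PPH4 must strictly exceed this (default 0.8).
#' @return `TRUE` iff `PPH4 > threshold`.
#' @export
classify_coloc <- function(result, threshold = 0.8) {
  stopifnot(inherits(result, "coloc_result"))
  isTRUE(unname(result$pph["PPH4"]) > threshold)
}

#' Putative shared causal variant of a colocalized region
#'
#' Returns the SNP maximizing the per-SNP H4 posterior; exact ties are
#' broken by the smaller trait-1 p-value, then lexicographic SNP id.
#' Calling this on a non-colocalized result is a usage error.
#'
#' @param result A `"coloc_result"` that passes [classify_coloc()].
#' @param threshold Classification threshold (default 0.8).
#' @return SNP id (character scalar).
#' @export
top_causal_snp <- function(result, threshold = 0.8) {
  if (!classify_coloc(result, threshold))
    stop("top_causal_snp() called on a non-colocalized result")
  h4 <- result$per_snp_h4
  best <- which(h4 == max(h4))
  if (length(best) > 1L && !is.null(result$trait1_p)) {
    pv <- result$trait1_p[names(h4)[best]]
    pv[is.na(pv)] <- Inf
    best <- best[pv == min(pv)]
  }
  sort(names(h4)[best])[1]
}
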