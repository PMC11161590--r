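# Instrument selection and quality control for one exposure-outcome pair
# within one cell-type context. Fixed stage order:
#   select_candidates -> confounder_filter -> ld_clump -> proxy_substitute
#   -> harmonize -> radial_outlier_filter -> instrument_strength
# Every stage returns its kept records plus a log of what was dropped and
# why, so kept + dropped always accounts for the input.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

flip_strand <- function(allele) {
  chartr("ACGT", "TGCA", allele)
}

is_palindromic <- function(ea, oa) flip_strand(ea) == oa

#' Select exposure-significant candidate instruments
#'
#' Pools colocalized causal SNPs (union across genes of one context) and
#' keeps those strongly associated with the exposure.
#'
#' @param coloc_snps Character vector of causal SNP ids for one context
#'   (duplicates allowed; union semantics).
#' @param exposure Canonical exposure summary statistics.
#' @param p_thresh Relevance threshold (default 5e-8, genome-wide
#'   significance).
#' @return Exposure records of the retained candidates, with a
#'   `"drop_log"` attribute.
#' @export
select_candidates <- function(coloc_snps, exposure, p_thresh = 5e-8) {
  snps <- unique(coloc_snps)
  hit <- exposure[match(snps, exposure$snp), , drop = FALSE]
  missing <- snps[is.na(hit$snp)]
  hit <- hit[!is.na(hit$snp), , drop = FALSE]
  weak <- hit$snp[hit$p >= p_thresh]
  out <- hit[hit$p < p_thresh, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- list(not_in_exposure = missing, above_p_thresh = weak)
  out
}

#' Drop candidates associated with confounders
#'
#' A candidate is removed when it, or any proxy in LD with it at
#' `r^2 > r2_proxy`, appears in the confounder-association table at
#' `p < p_conf`. Candidates without LD coverage are treated as having no
#' proxies (logged).
#'
#' @param candidates Candidate exposure records (from
#'   [select_candidates()]).
#' @param table Confounder table: columns `snp`, `confounder`, `p`.
#' @param ld LD matrix used for proxy lookup (searched within this matrix
#'   only).
#' @param r2_proxy Proxy r-squared threshold (default 0.8).
#' @param p_conf Confounder-association significance threshold.
#' @return Filtered candidates with a `"drop_log"` attribute naming each
#'   removed SNP and the confounder hit responsible.
#' @export
confounder_filter <- function(candidates, table, ld, r2_proxy = 0.8,
                              p_conf = 5e-8) {
  if (is.null(table) || nrow(table) == 0L || nrow(candidates) == 0L) {
    attr(candidates, "drop_log") <- list(confounder_hits = character(0),
                                         no_ld_coverage = character(0))
    return(candidates)
  }
  hits <- table$snp[table$p < p_conf]
  no_ld <- character(0)
  dropped <- character(0)
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- candidates$snp[i]
    linked <- s
    if (s %in% rownames(ld)) {
      r2 <- ld[s, ]^2
      linked <- unique(c(s, colnames(ld)[r2 > r2_proxy]))
    } else {
      no_ld <- c(no_ld, s)
    }
    if (any(linked %in% hits)) {
      dropped <- c(dropped, s)
      keep[i] <- FALSE
    } else keep[i] <- TRUE
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- list(confounder_hits = dropped, no_ld_coverage = no_ld)
  out
}

#' Greedy LD clumping
#'
#' Iterates candidates by ascending exposure p-value (ties: position, then
#' id) and keeps a SNP iff no already-kept SNP within `window_kb` on the
#' same chromosome has `r^2 > r2` with it. Pairs without an LD entry are
#' treated as unlinked.
#'
#' @param candidates Candidate records with `snp`, `chr`, `pos`, `p`.
#' @param ld LD matrix.
#' @param r2 Clumping r-squared threshold (default 0.001).
#' @param window_kb Window size in kb (default 10000).
#' @param p_thresh Index-SNP p-value threshold (default 5e-8).
#' @return Index-SNP records, ordered by p; `"drop_log"` lists clumped
#'   SNPs and the index SNP each was clumped to.
#' @export
ld_clump <- function(candidates, ld, r2 = 0.001, window_kb = 10000,
                     p_thresh = 5e-8) {
  x <- candidates[candidates$p < p_thresh, , drop = FALSE]
  x <- x[order(x$p, x$pos, x$snp), , drop = FALSE]
  kept <- integer(0)
  clumped <- character(0)
  clumped_to <- character(0)
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (j in kept) {
      if (x$chr[j] != x$chr[i]) next
      if (abs(x$pos[j] - x$pos[i]) > window_kb * 1000) next
      rij <- if (x$snp[i] %in% rownames(ld) && x$snp[j] %in% rownames(ld))
        ld[x$snp[i], x$snp[j]] else 0
      if (rij^2 > r2) {
        ok <- FALSE
        clumped <- c(clumped, x$snp[i])
        clumped_to <- c(clumped_to, x$snp[j])
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- x[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- list(clumped = stats::setNames(clumped_to, clumped))
  out
}

#' Substitute proxies for index SNPs absent from the outcome
#'
#' Index SNPs present in the outcome pass through unchanged (provenance
#' `"original"`). An absent SNP is replaced by its highest-r^2 proxy with
#' `r^2 > r2` that is present in both datasets and passes the exposure
#' p-value threshold; unresolvable SNPs are dropped.
#'
#' @param index_snps Index-SNP exposure records.
#' @param exposure,outcome Canonical summary statistics.
#' @param ld LD matrix (proxies are searched within it only).
#' @param r2 Proxy threshold (default 0.8).
#' @param p_thresh Exposure significance required of a proxy.
#' @return Exposure records with `provenance`, `proxy_of`, `proxy_r2`
#'   columns; `"drop_log"` lists unresolvable SNPs.
#' @export
proxy_substitute <- function(index_snps, exposure, outcome, ld, r2 = 0.8,
                             p_thresh = 5e-8) {
  rows <- list()
  dropped <- character(0)
  for (i in seq_len(nrow(index_snps))) {
    rec <- index_snps[i, , drop = FALSE]
    rec$provenance <- "original"
    rec$proxy_of <- NA_character_
    rec$proxy_r2 <- NA_real_
    if (rec$snp %in% outcome$snp) {
      rows[[length(rows) + 1L]] <- rec
      next
    }
    if (!(rec$snp %in% rownames(ld))) {
      dropped <- c(dropped, rec$snp)
      next
    }
    r2v <- ld[rec$snp, ]^2
    cand <- names(r2v)[r2v > r2 & names(r2v) != rec$snp]
    cand <- cand[cand %in% outcome$snp & cand %in% exposure$snp]
    if (length(cand)) {
      pexp <- exposure$p[match(cand, exposure$snp)]
      cand <- cand[pexp < p_thresh]
    }
    if (length(cand) == 0L) {
      dropped <- c(dropped, rec$snp)
      next
    }
    best <- cand[order(-r2v[cand], cand)][1]
    sub <- exposure[match(best, exposure$snp), , drop = FALSE]
    sub$provenance <- "proxy"
    sub$proxy_of <- rec$snp
    sub$proxy_r2 <- unname(r2v[best])
    rows[[length(rows) + 1L]] <- sub
  }
  out <- if (length(rows)) do.call(rbind, rows) else index_snps[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- list(unresolvable = dropped)
  out
}

#' Harmonize exposure and outcome effects to shared alleles
#'
#' For each SNP present in both tables: identical alleles pass through;
#' swapped alleles negate the outcome beta and flip its frequency; alleles
#' matching after strand complementation are flipped then aligned (only
#' attempted for non-palindromic pairs); palindromic variants (A/T or C/G)
#' with intermediate allele frequency (minor-allele frequency > `palindrome_af`,
#' i.e. EAF inside (`palindrome_af`, 1 - `palindrome_af`)) in either
#' dataset, or with a missing frequency, are removed as strand-ambiguous;
#' remaining palindromes are resolved by frequency matching. Harmonization
#' is involutive: re-harmonizing its output is the identity.
#'
#' @param exposure,outcome Canonical summary statistics (exposure rows may
#'   carry `provenance` columns from [proxy_substitute()]).
#' @param palindrome_af Ambiguity threshold on the minor-allele frequency
#'   (default 0.42).
#' @param context Optional context label stored on the instruments.
#' @return A data.frame of class `"instruments"` with columns `snp`, `ea`,
#'   `oa`, `beta_exp`, `se_exp`, `p_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `context`, `provenance`; `"drop_log"` maps dropped SNPs to
#'   reason codes.
#' @export
harmonize <- function(exposure, outcome, palindrome_af = 0.42, context = NA_character_) {
  shared <- intersect(exposure$snp, outcome$snp)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp), , drop = FALSE]
  rows <- list()
  dropped <- character(0)
  reason <- character(0)
  for (i in seq_along(shared)) {
    ea <- ex$ea[i]; oa <- ex$oa[i]
    bo <- ou$beta[i]; fo <- ou$eaf[i]
    eo <- ou$ea[i]; oo <- ou$oa[i]
    pal <- is_palindromic(ea, oa)
    if (pal) {
      # letters cannot resolve strand; frequencies must
      maf_ex <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_ou <- min(fo, 1 - fo)
      if (is.na(ex$eaf[i]) || is.na(fo) ||
          maf_ex > palindrome_af || maf_ou > palindrome_af) {
        dropped <- c(dropped, shared[i])
        reason <- c(reason, "palindromic_ambiguous")
        next
      }
      if (!((eo == ea & oo == oa) || (eo == oa & oo == ea))) {
        dropped <- c(dropped, shared[i])
        reason <- c(reason, "incompatible_alleles")
        next
      }
      aligned_same <- (eo == ea)
      if (!aligned_same) { bo <- -bo; fo <- 1 - fo }
      # frequency check: opposite minor-allele side means the strands differ
      if ((ex$eaf[i] - 0.5) * (fo - 0.5) < 0) { bo <- -bo; fo <- 1 - fo }
    } else {
      if (eo == ea && oo == oa) {
        # as-is
      } else if (eo == oa && oo == ea) {
        bo <- -bo; fo <- 1 - fo
      } else if (flip_strand(eo) == ea && flip_strand(oo) == oa) {
        # strand flip, aligned
      } else if (flip_strand(eo) == oa && flip_strand(oo) == ea) {
        bo <- -bo; fo <- 1 - fo
      } else {
        dropped <- c(dropped, shared[i])
        reason <- c(reason, "incompatible_alleles")
        next
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp = shared[i], ea = ea, oa = oa,
      beta_exp = ex$beta[i], se_exp = ex$se[i], p_exp = ex$p[i],
      eaf_exp = ex$eaf[i],
      beta_out = bo, se_out = ou$se[i], eaf_out = fo,
      context = context,
      provenance = if ("provenance" %in% names(ex)) ex$provenance[i] else "original",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(0), ea = character(0), oa = character(0),
               beta_exp = numeric(0), se_exp = numeric(0), p_exp = numeric(0),
               eaf_exp = numeric(0), beta_out = numeric(0), se_out = numeric(0),
               eaf_out = numeric(0), context = character(0),
               provenance = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("instruments", "data.frame")
  attr(out, "drop_log") <- stats::setNames(reason, dropped)
  out
}

# Radial per-SNP statistics shared by the outlier filter and Q statistics.
# First-order radial weights w_j = beta_exp^2 / se_out^2; ratio estimates
# beta_j = beta_out / beta_exp.
radial_stats <- function(instr) {
  w <- instr$beta_exp^2 / instr$se_out^2
  list(ratio = instr$beta_out / instr$beta_exp, w = w,
       x = sqrt(w), y = sqrt(w) * instr$beta_out / instr$beta_exp)
}

#' Remove pleiotropic outliers on the radial scale
#'
#' Fits radial IVW (origin-constrained) and radial Egger (with intercept)
#' regressions of `sqrt(w) * ratio` on `sqrt(w)` with first-order weights
#' `w = beta_exp^2/se_out^2`, refers each SNP's Q contribution to
#' chi-square(1), and removes the union of SNPs significant at `alpha`
#' under either fit (single pass by default; `iterate = TRUE` repeats
#' until none remain). Fewer than 3 instruments pass through unchanged.
#'
#' @param instr An `"instruments"` data frame.
#' @param alpha Outlier significance level (default 0.05).
#' @param tol Convergence tolerance kept for interface compatibility with
#'   iteratively reweighted variants; first-order weights need one pass.
#' @param iterate Repeat removal until no outlier remains.
#' @return List: `instruments` (kept), `removed` (data frame with per-test
#'   Q p-values and which test flagged each SNP), `q_ivw`, `q_egger`
#'   (total Q statistics of the final fit).
#' @export
radial_outlier_filter <- function(instr, alpha = 0.05, tol = 1e-4,
                                  iterate = FALSE) {
  removed <- data.frame(snp = character(0), p_ivw = numeric(0),
                        p_egger = numeric(0), test = character(0),
                        stringsAsFactors = FALSE)
  zero <- instr$beta_exp == 0
  if (any(zero)) {
    removed <- rbind(removed, data.frame(snp = instr$snp[zero], p_ivw = NA,
                                         p_egger = NA, test = "zero_exposure_beta",
                                         stringsAsFactors = FALSE))
    instr <- instr[!zero, , drop = FALSE]
  }
  repeat {
    k <- nrow(instr)
    if (k < 3) break
    rs <- radial_stats(instr)
    beta_ivw <- sum(rs$x * rs$y) / sum(rs$x^2)
    q_ivw_j <- (rs$y - beta_ivw * rs$x)^2
    fit_e <- stats::lm.fit(cbind(1, rs$x), rs$y)
    q_egg_j <- fit_e$residuals^2
    p_ivw <- stats::pchisq(q_ivw_j, df = 1, lower.tail = FALSE)
    p_egg <- stats::pchisq(q_egg_j, df = 1, lower.tail = FALSE)
    out <- p_ivw < alpha | p_egg < alpha
    if (any(out)) {
      test <- ifelse(p_ivw < alpha & p_egg < alpha, "both",
                     ifelse(p_ivw < alpha, "ivw_radial", "egger_radial"))
      removed <- rbind(removed, data.frame(snp = instr$snp[out],
                                           p_ivw = p_ivw[out],
                                           p_egger = p_egg[out],
                                           test = test[out],
                                           stringsAsFactors = FALSE))
      instr <- instr[!out, , drop = FALSE]
    }
    if (!iterate || !any(out)) break
  }
  rownames(instr) <- NULL
  rs <- if (nrow(instr) >= 2) radial_stats(instr) else NULL
  q_ivw <- q_egger <- NA_real_
  if (!is.null(rs)) {
    b <- sum(rs$x * rs$y) / sum(rs$x^2)
    q_ivw <- sum((rs$y - b * rs$x)^2)
    if (nrow(instr) >= 3)
      q_egger <- sum(stats::lm.fit(cbind(1, rs$x), rs$y)$residuals^2)
  }
  list(instruments = instr, removed = removed, q_ivw = q_ivw, q_egger = q_egger)
}

#' Instrument strength (F-statistic)
#'
#' Per-SNP explained variance `R2_i = beta_i^2 / (beta_i^2 + se_i^2 * N)`,
#' summed over instruments, and `F = R2 (N - k - 1) / (k (1 - R2))`.
#' Instruments with `F < 10` are conventionally considered weak.
#'
#' @param instr An `"instruments"` data frame (uses `beta_exp`, `se_exp`).
#' @param n_exposure Exposure GWAS sample size, `> k + 1`.
#' @return List of class `"f_stats"`: `r2_per_snp`, `r2_total`, `k`, `n`,
#'   `f`, `weak`.
#' @export
instrument_strength <- function(instr, n_exposure) {
  k <- nrow(instr)
  stopifnot(k >= 1)
  if (n_exposure <= k + 1) stop("n_exposure must exceed k + 1")
  r2 <- instr$beta_exp^2 / (instr$beta_exp^2 + instr$se_exp^2 * n_exposure)
  r2t <- sum(r2)
  f <- r2t * (n_exposure - k - 1) / (k * (1 - r2t))
  structure(list(r2_per_snp = stats::setNames(r2, instr$snp), r2_total = r2t,
                 k = k, n = n_exposure, f = f, weak = f < 10),
            class = "f_stats")
}

#' @export
print.f_stats <- function(x, ...) {
  cat("Instrument strength: k =", x$k, ", N =", x$n,
      ", R2 =", signif(x$r2_total, 4), ", F =", signif(x$f, 5),
      if (x$weak) "(WEAK: F < 10)" else "", "\n")
  invisible(x)
}
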