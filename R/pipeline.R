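# End-to-end orchestration: per-context colocalization of every gene
# region against the exposure GWAS, instrument selection and QC per
# outcome, the MR suite with method selection, and Bonferroni-corrected
# reporting.

#' Pipeline stage parameters
#'
#' Collects every tunable threshold with its default: PPH4 > 0.8 declares
#' colocalization; exposure relevance at p < 5e-8; clumping at r^2 0.001
#' within 10,000 kb; proxies at r^2 > 0.8; palindrome ambiguity above
#' minor-allele frequency 0.42; radial outlier removal at alpha 0.05;
#' weak-instrument flag at F < 10; credible sets at coverage 0.9 and
#' purity 0.5 over L = 10 effects; cis regions flanked 100 kb; coloc
#' priors p1 = p2 = 1e-4, p12 = 1e-5.
#'
#' @param pph4,p_exposure,clump_r2,clump_kb,proxy_r2,palindrome_af
#'   Selection thresholds (see above).
#' @param radial_alpha,f_min QC thresholds.
#' @param coverage,min_purity,L Fine-mapping settings.
#' @param flank Region flank in bases.
#' @param p1,p2,p12 Colocalization priors.
#' @param gwas_type,eqtl_type `"quant"` or `"cc"` for the prior effect SD.
#' @param p_confounder Confounder-association threshold.
#' @param alpha Family-wise level for the Bonferroni threshold and the
#'   decision tree.
#' @param n_boot,n_presso Simulation sizes inside [mr_fit()].
#' @param min_region_snps Minimum shared SNPs to attempt colocalization.
#' @return Named list of class `"pipeline_params"`.
#' @export
pipeline_params <- function(pph4 = 0.8, p_exposure = 5e-8, clump_r2 = 0.001,
                            clump_kb = 10000, proxy_r2 = 0.8,
                            palindrome_af = 0.42, radial_alpha = 0.05,
                            f_min = 10, coverage = 0.9, min_purity = 0.5,
                            L = 10, flank = 1e5, p1 = 1e-4, p2 = 1e-4,
                            p12 = 1e-5, gwas_type = "quant",
                            eqtl_type = "quant", p_confounder = 5e-8,
                            alpha = 0.05, n_boot = 1000, n_presso = 1000,
                            min_region_snps = 5) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Bonferroni threshold for the outcome-by-context test family
#'
#' The family is outcomes x contexts per exposure (e.g. 18 outcomes and
#' 8 cell types + 2 tissues give 180 tests and a threshold of 2.78e-4).
#'
#' @param n_outcomes,n_contexts Family dimensions (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return `alpha / (n_outcomes * n_contexts)`.
#' @export
bonferroni_adjust <- function(n_outcomes, n_contexts, alpha = 0.05) {
  stopifnot(n_outcomes >= 1, n_contexts >= 1)
  alpha / (n_outcomes * n_contexts)
}

#' Colocalize one gene's region against the exposure GWAS
#'
#' Fine-maps both traits over their shared SNPs with [susie_rss()] and
#' runs credible-set-pairwise colocalization; when either trait yields no
#' credible set the single-causal-variant enumeration of [coloc_abf()] is
#' used instead (the fallback is visible as `mode = "abf"` in the
#' results).
#'
#' @param exposure Canonical GWAS records for the region.
#' @param eqtl_gene Canonical eQTL records of one gene in one context.
#' @param ld LD matrix covering the shared SNPs.
#' @param params [pipeline_params()].
#' @return List of `"coloc_result"` objects, or NULL when fewer than
#'   `params$min_region_snps` SNPs are shared.
#' @export
colocalize_region <- function(exposure, eqtl_gene, ld,
                              params = pipeline_params()) {
  shared <- intersect(intersect(exposure$snp, eqtl_gene$snp), rownames(ld))
  if (length(shared) < params$min_region_snps) return(NULL)
  ex <- exposure[match(shared, exposure$snp), , drop = FALSE]
  eq <- eqtl_gene[match(shared, eqtl_gene$snp), , drop = FALSE]
  R <- ld_submatrix(ld, shared)
  ab <- abf_params(p1 = params$p1, p2 = params$p2, p12 = params$p12)
  t1p <- stats::setNames(ex$p, ex$snp)
  fit1 <- susie_rss(ex$beta / ex$se, R, L = params$L)
  fit2 <- susie_rss(eq$beta / eq$se, R, L = params$L)
  s1 <- credible_sets(fit1, R, coverage = params$coverage,
                      min_purity = params$min_purity)
  s2 <- credible_sets(fit2, R, coverage = params$coverage,
                      min_purity = params$min_purity)
  if (length(s1) && length(s2)) {
    return(coloc_susie(fit1, s1, fit2, s2, params = ab, trait1_p = t1p))
  }
  list(coloc_abf(ex, eq, params = ab, type1 = params$gwas_type,
                 type2 = params$eqtl_type))
}

#' Run the full cell-stratified MR pipeline
#'
#' For every context: each gene's cis region (span of its tested SNPs
#' plus the flank, MHC excluded) is colocalized with the exposure GWAS
#' (fine-mapping mode with single-causal-variant fallback); the top
#' shared causal variants of colocalized genes are pooled (union) into
#' the context's candidate instruments; per outcome, the instrument
#' pipeline (relevance filter, confounder filter, LD clumping, proxy
#' substitution, harmonization, radial outlier removal, F-statistic) and
#' the MR suite with method selection are run. Rows are flagged
#' significant at the Bonferroni threshold over outcomes x contexts.
#' Deterministic under a fixed seed.
#'
#' @param exposure Canonical exposure GWAS data frame (or path).
#' @param eqtl Canonical eQTL data frame with `gene` and `context` (or
#'   path).
#' @param outcomes Named list of canonical outcome data frames (or
#'   paths).
#' @param ld LD matrix covering the analysed SNPs.
#' @param confounders Optional confounder table (`snp`, `confounder`,
#'   `p`).
#' @param contexts Contexts to analyse (default: all in `eqtl`).
#' @param params [pipeline_params()].
#' @param n_exposure Exposure GWAS sample size for the F-statistic
#'   (default: median `n` of the exposure table).
#' @param seed RNG seed governing all stochastic steps.
#' @param outdir Optional directory for [write_report()].
#' @param exposure_name Label used in the result table.
#' @return Object of class `"mrstrat_result"`: `results` (one row per
#'   outcome x context), `fits` (the underlying `"mr_fit"` objects),
#'   `coloc` (per-context colocalized SNPs), `threshold`, `log`.
#' @export
run_pipeline <- function(exposure, eqtl, outcomes, ld, confounders = NULL,
                         contexts = NULL, params = pipeline_params(),
                         n_exposure = NULL, seed = 1, outdir = NULL,
                         exposure_name = "exposure") {
  if (is.character(exposure)) exposure <- read_sumstats(exposure)
  if (is.character(eqtl)) eqtl <- read_sumstats(eqtl, kind = "eqtl")
  outcomes <- lapply(outcomes, function(o)
    if (is.character(o)) read_sumstats(o) else o)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes))))
    names(outcomes) <- paste0("outcome", seq_along(outcomes))
  if (is.null(contexts)) contexts <- sort(unique(eqtl$context))
  if (is.null(n_exposure)) n_exposure <- stats::median(exposure$n)
  set.seed(seed)
  exposure <- exclude_mhc(exposure)
  eqtl <- exclude_mhc(eqtl)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  coloc_by_ctx <- list()
  for (cx in contexts) {
    ecx <- eqtl[eqtl$context == cx, , drop = FALSE]
    if (nrow(ecx) == 0L) {
      note("context ", cx, ": empty eQTL table, skipped")
      coloc_by_ctx[[cx]] <- character(0)
      next
    }
    snps_cx <- character(0)
    for (g in unique(ecx$gene)) {
      eg <- ecx[ecx$gene == g, , drop = FALSE]
      reg <- region(eg$chr[1], min(eg$pos), max(eg$pos), flank = params$flank)
      ex_reg <- extract_region(exposure, reg)
      eg_reg <- extract_region(eg, reg)
      res <- colocalize_region(ex_reg, eg_reg, ld, params)
      if (is.null(res)) next
      if (any(vapply(res, function(r) r$mode == "abf", logical(1))) &&
          length(res) == 1L)
        note("context ", cx, " gene ", g,
             ": single-causal-variant fallback (no credible set pair)")
      hits <- Filter(function(r) classify_coloc(r, params$pph4), res)
      if (length(hits) > 1L)
        note("context ", cx, " gene ", g, ": ", length(hits),
             " colocalized signal pairs (multiplicity flagged)")
      for (h in hits) snps_cx <- c(snps_cx, top_causal_snp(h, params$pph4))
    }
    coloc_by_ctx[[cx]] <- unique(snps_cx)
    note("context ", cx, ": ", length(unique(snps_cx)),
         " colocalized causal SNP(s)")
  }

  threshold <- bonferroni_adjust(length(outcomes), length(contexts),
                                 params$alpha)
  rows <- list()
  fits <- list()
  task <- 0L
  for (cx in contexts) {
    cand <- select_candidates(coloc_by_ctx[[cx]], exposure,
                              p_thresh = params$p_exposure)
    cand <- confounder_filter(cand, confounders, ld,
                              r2_proxy = params$proxy_r2,
                              p_conf = params$p_confounder)
    cand <- ld_clump(cand, ld, r2 = params$clump_r2,
                     window_kb = params$clump_kb,
                     p_thresh = params$p_exposure)
    for (oc in names(outcomes)) {
      task <- task + 1L
      row <- data.frame(exposure = exposure_name, outcome = oc, context = cx,
                        status = "ok", n_iv = 0L, chosen_method = NA_character_,
                        beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        f_stat = NA_real_, weak_instruments = NA,
                        q_p = NA_real_, q_prime_p = NA_real_,
                        egger_intercept_p = NA_real_, presso_p = NA_real_,
                        n_outliers_removed = NA_integer_,
                        loo_flag = NA, significant = FALSE,
                        stringsAsFactors = FALSE)
      if (nrow(cand) == 0L) {
        row$status <- "no-instruments"
        rows[[task]] <- row
        note("context ", cx, " outcome ", oc, ": no candidate instruments")
        next
      }
      idx <- proxy_substitute(cand, exposure, outcomes[[oc]], ld,
                              r2 = params$proxy_r2,
                              p_thresh = params$p_exposure)
      instr <- harmonize(idx, outcomes[[oc]],
                         palindrome_af = params$palindrome_af, context = cx)
      note("context ", cx, " outcome ", oc, ": ", nrow(cand),
           " candidates -> ", nrow(idx), " in outcome -> ", nrow(instr),
           " harmonized")
      if (nrow(instr) == 0L) {
        row$status <- "no-instruments"
        rows[[task]] <- row
        next
      }
      rad <- radial_outlier_filter(instr, alpha = params$radial_alpha)
      instr <- rad$instruments
      row$n_outliers_removed <- nrow(rad$removed)
      if (nrow(instr) == 0L) {
        row$status <- "no-instruments"
        rows[[task]] <- row
        next
      }
      fs <- instrument_strength(instr, n_exposure)
      fit <- mr_fit(instr, n_boot = params$n_boot,
                    n_presso = params$n_presso, alpha = params$alpha,
                    seed = seed + 17L * task)
      fits[[paste(cx, oc, sep = ".")]] <- fit
      main <- fit$estimates[[fit$choice$chosen]]
      if (is.null(main)) main <- fit$estimates[[1]]
      row$n_iv <- fit$n_iv
      row$chosen_method <- fit$choice$chosen
      row$beta <- main$beta; row$se <- main$se
      row$ci_low <- main$ci_low; row$ci_high <- main$ci_high
      row$p <- main$pvalue
      row$f_stat <- fs$f; row$weak_instruments <- fs$weak
      if (!is.null(fit$heterogeneity)) {
        row$q_p <- fit$heterogeneity$q_p
        row$q_prime_p <- fit$heterogeneity$q_prime_p
      }
      if (!is.null(fit$intercept_test)) row$egger_intercept_p <- fit$intercept_test$p
      if (!is.null(fit$presso)) row$presso_p <- fit$presso$p_global
      row$loo_flag <- if (!is.null(fit$loo)) any(fit$loo$flag) else NA
      row$significant <- isTRUE(row$p < threshold)
      rows[[task]] <- row
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- structure(list(results = results, fits = fits,
                        coloc = coloc_by_ctx, threshold = threshold,
                        log = log, seed = seed),
                   class = "mrstrat_result")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

#' @export
print.mrstrat_result <- function(x, ...) {
  cat("Cell-stratified MR results (Bonferroni threshold ",
      signif(x$threshold, 3), "):\n", sep = "")
  cols <- c("outcome", "context", "status", "n_iv", "chosen_method",
            "beta", "se", "p", "significant")
  print(format(x$results[, cols], digits = 4), row.names = FALSE)
  invisible(x)
}

#' Write the pipeline report files
#'
#' Writes `results.tsv` (main table), `diagnostics.tsv` (per-method
#' estimates, all pleiotropy tests, leave-one-out flags and the
#' method recommendation, one block per outcome x context) and
#' `run_log.txt` with stable column order.
#'
#' @param x An `"mrstrat_result"`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(x, outdir) {
  stopifnot(inherits(x, "mrstrat_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  main <- file.path(outdir, "results.tsv")
  utils::write.table(x$results, main, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  diag_rows <- list()
  for (key in names(x$fits)) {
    fit <- x$fits[[key]]
    tab <- estimates_table(fit)
    tab <- cbind(task = key, tab,
                 q_p = if (!is.null(fit$heterogeneity)) fit$heterogeneity$q_p else NA,
                 q_prime_p = if (!is.null(fit$heterogeneity)) fit$heterogeneity$q_prime_p else NA,
                 egger_intercept_p = if (!is.null(fit$intercept_test)) fit$intercept_test$p else NA,
                 presso_p = if (!is.null(fit$presso)) fit$presso$p_global else NA,
                 loo_flag = if (!is.null(fit$loo)) any(fit$loo$flag) else NA,
                 recommendation = fit$choice$chosen,
                 rationale = fit$choice$rationale)
    diag_rows[[key]] <- tab
  }
  diag <- file.path(outdir, "diagnostics.tsv")
  if (length(diag_rows))
    utils::write.table(do.call(rbind, diag_rows), diag, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  logf <- file.path(outdir, "run_log.txt")
  writeLines(c(paste("seed:", x$seed),
               paste("bonferroni_threshold:", format(x$threshold, digits = 10)),
               x$log), logf)
  invisible(c(main, diag, logf))
}
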