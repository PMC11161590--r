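# Pleiotropy / heterogeneity diagnostics and the main-method decision tree.

#' Cochran's Q and Rucker's Q' heterogeneity statistics
#'
#' Q measures residual heterogeneity of the fixed-effect IVW fit (radial
#' weights, chi-square with k-1 df); Q' measures residual heterogeneity of
#' the Egger fit (k-2 df). Q >= Q' since the Egger model nests IVW on the
#' oriented radial scale. Non-positive df yields an NA p-value (flagged).
#'
#' @param instr Instruments data frame (k >= 2).
#' @return List of class `"mr_heterogeneity"`: `q`, `q_df`, `q_p`,
#'   `q_prime`, `q_prime_df`, `q_prime_p`.
#' @export
heterogeneity_stats <- function(instr) {
  check_instruments(instr, 2, "heterogeneity")
  k <- nrow(instr)
  iv <- mr_ivw(instr)
  qp <- qp_p <- NA_real_
  if (k >= 3) {
    eg <- mr_egger(instr)
    qp <- eg$q_prime
    qp_p <- eg$q_prime_p
  }
  structure(list(q = iv$q, q_df = iv$q_df, q_p = iv$q_p,
                 q_prime = qp, q_prime_df = k - 2, q_prime_p = qp_p),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran Q = %.4g (df %d, p = %.3g); Rucker Q' = %.4g (df %d, p = %.3g)\n",
              x$q, x$q_df, x$q_p, x$q_prime, x$q_prime_df, x$q_prime_p))
  invisible(x)
}

#' Egger intercept test for directional pleiotropy
#'
#' @param instr Instruments data frame (k >= 3).
#' @return List: `intercept`, `se`, `p` (t reference, k-2 df).
#' @export
egger_intercept_test <- function(instr) {
  eg <- mr_egger(instr)
  list(intercept = eg$intercept, se = eg$intercept_se, p = eg$intercept_p)
}

# Leave-one-out IVW slopes from sufficient statistics, vectorized over j.
loo_ivw_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' Global test for horizontal pleiotropy (simulation-based)
#'
#' Observed statistic: weighted residual sum of squares with each SNP's
#' expected outcome effect taken from the IVW fit that excludes it,
#' `RSS = sum_j w_j (beta_out_j - beta_{-j} * beta_exp_j)^2`,
#' `w_j = 1/se_out_j^2`. The null distribution is built by parametric
#' simulation: exposure and outcome effects are redrawn from normals
#' centered on the leave-one-out fitted expectations with the reported
#' SEs, and the statistic recomputed. `p = (1 + #(RSS* >= RSS_obs)) /
#' (n_sim + 1)`, never exactly 0.
#'
#' @param instr Instruments data frame (k >= 4).
#' @param n_sim Simulated null draws (default 1000).
#' @param seed Optional RNG seed (stored in the result).
#' @return List of class `"presso_result"`: `rss_obs`, `p_global`,
#'   `n_sim`, `seed`.
#' @export
presso_global <- function(instr, n_sim = 1000, seed = NULL) {
  check_instruments(instr, 4, "presso_global")
  if (!is.null(seed)) set.seed(seed)
  x <- instr$beta_exp; y <- instr$beta_out
  sx <- instr$se_exp; sy <- instr$se_out
  w <- 1 / sy^2
  k <- length(x)
  b_loo <- loo_ivw_slopes(x, y, w)
  rss_obs <- sum(w * (y - b_loo * x)^2)
  # simulate under the no-pleiotropy model implied by the LOO fits
  xs <- matrix(stats::rnorm(k * n_sim, x, sx), k, n_sim)
  ys <- matrix(stats::rnorm(k * n_sim, b_loo * x, sy), k, n_sim)
  sxy <- colSums(w * xs * ys)
  sxx <- colSums(w * xs^2)
  b_loo_s <- (matrix(sxy, k, n_sim, byrow = TRUE) - w * xs * ys) /
    (matrix(sxx, k, n_sim, byrow = TRUE) - w * xs^2)
  rss_sim <- colSums(w * (ys - b_loo_s * xs)^2)
  structure(list(rss_obs = rss_obs,
                 p_global = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1),
                 n_sim = n_sim, seed = seed),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("Global pleiotropy test: RSS = %.4g, p = %.4g (%d simulations)\n",
              x$rss_obs, x$p_global, x$n_sim))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate with each instrument excluded in turn and
#' flags exclusions that flip the sign of the estimate or move its p-value
#' across the significance threshold relative to the full fit.
#'
#' @param instr Instruments data frame (k >= 3).
#' @param sig_thresh Significance threshold for the crossing flag.
#' @return Data frame: `excluded_snp`, `beta`, `se`, `pvalue`,
#'   `sign_change`, `crosses_threshold`, `flag`.
#' @export
leave_one_out <- function(instr, sig_thresh = 0.05) {
  check_instruments(instr, 3, "leave_one_out")
  full <- mr_ivw(instr)
  rows <- lapply(seq_len(nrow(instr)), function(j) {
    e <- mr_ivw(instr[-j, , drop = FALSE])
    data.frame(excluded_snp = instr$snp[j], beta = e$beta, se = e$se,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sign_change <- sign(out$beta) != sign(full$beta)
  out$crosses_threshold <- (out$pvalue < sig_thresh) != (full$pvalue < sig_thresh)
  out$flag <- out$sign_change | out$crosses_threshold
  attr(out, "full_estimate") <- full
  out
}

#' Choose the main MR method from the pleiotropy diagnostics
#'
#' Decision tree: (1) a single instrument uses the Wald ratio; (2) no
#' directional pleiotropy detected — Cochran Q, Egger intercept and the
#' global pleiotropy test all at p > alpha — uses IVW; (3) pleiotropy
#' detected but Rucker Q' p > alpha uses MR-Egger; (4) pleiotropy detected
#' and Q' p < alpha uses the weighted median (preferred over the weighted
#' mode for power). A diagnostic that could not be computed (NA/NULL) is
#' treated as non-significant, and the choice is marked
#' diagnostic-incomplete; a diagnostic required by the branch actually
#' reached (Q' in branches 3/4) that is missing is an error.
#'
#' @param n_iv Number of instruments.
#' @param heterogeneity [heterogeneity_stats()] result (or NULL when
#'   `n_iv == 1`).
#' @param intercept_test [egger_intercept_test()] result or NULL.
#' @param presso [presso_global()] result or NULL.
#' @param alpha Significance level of every test (default 0.05).
#' @return List of class `"method_choice"`: `chosen`, `branch`,
#'   `rationale`, `diagnostics` (the triggering p-values), `incomplete`.
#' @export
select_main_method <- function(n_iv, heterogeneity = NULL,
                               intercept_test = NULL, presso = NULL,
                               alpha = 0.05) {
  if (n_iv == 1) {
    return(structure(list(chosen = "wald", branch = 1L,
                          rationale = "single instrument: Wald ratio",
                          diagnostics = numeric(0), incomplete = FALSE),
                     class = "method_choice"))
  }
  q_p <- if (!is.null(heterogeneity)) heterogeneity$q_p else NA_real_
  int_p <- if (!is.null(intercept_test)) intercept_test$p else NA_real_
  pr_p <- if (!is.null(presso)) presso$p_global else NA_real_
  d <- c(cochran_q_p = q_p, egger_intercept_p = int_p, presso_p = pr_p)
  incomplete <- any(is.na(d))
  sig <- !is.na(d) & d < alpha
  if (!any(sig)) {
    return(structure(list(chosen = "ivw", branch = 2L,
                          rationale = paste0("no directional pleiotropy detected (all p > ",
                                             alpha, ")",
                                             if (incomplete) "; diagnostic-incomplete"),
                          diagnostics = d, incomplete = incomplete),
                     class = "method_choice"))
  }
  qp_p <- if (!is.null(heterogeneity)) heterogeneity$q_prime_p else NA_real_
  if (is.na(qp_p))
    stop("pleiotropy detected but Rucker Q' is unavailable; cannot choose between Egger and weighted median")
  d <- c(d, rucker_q_prime_p = qp_p)
  if (qp_p > alpha) {
    structure(list(chosen = "egger", branch = 3L,
                   rationale = paste0("pleiotropy detected (",
                                      paste(names(which(sig)), collapse = ", "),
                                      ") and Rucker Q' p > ", alpha,
                                      if (incomplete) "; diagnostic-incomplete"),
                   diagnostics = d, incomplete = incomplete),
              class = "method_choice")
  } else {
    structure(list(chosen = "wmedian", branch = 4L,
                   rationale = paste0("pleiotropy detected (",
                                      paste(names(which(sig)), collapse = ", "),
                                      ") and Rucker Q' p <= ", alpha,
                                      "; weighted median preferred over weighted mode",
                                      if (incomplete) "; diagnostic-incomplete"),
                   diagnostics = d, incomplete = incomplete),
              class = "method_choice")
  }
}

#' @export
print.method_choice <- function(x, ...) {
  cat("Main MR method:", x$chosen, "(branch", paste0(x$branch, ")"), "-",
      x$rationale, "\n")
  if (length(x$diagnostics))
    cat("  triggering p-values:",
        paste(names(x$diagnostics), signif(x$diagnostics, 3), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}
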