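# The central model-fitting interface: mr_fit() runs every applicable
# estimator on a harmonized instrument table, attaches the pleiotropy and
# sensitivity diagnostics, and selects the main method by the decision
# tree. The returned object carries the classic S3 surface (print,
# summary, coef, confint, plot, residuals).

#' Fit the two-sample MR estimator suite
#'
#' Runs every estimator the instrument count admits (Wald ratio for k = 1;
#' IVW for k >= 2; MR-Egger, weighted median, weighted mode, robust
#' adjusted profile score for k >= 3), computes Cochran's Q, Rucker's Q',
#' the Egger intercept test, the simulation-based global pleiotropy test
#' (k >= 4) and the leave-one-out sensitivity table, and selects the main
#' method with [select_main_method()].
#'
#' @param instruments An `"instruments"` data frame (see [harmonize()]),
#'   or any data frame with `snp`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out` columns.
#' @param n_boot Bootstrap replicates for the median/mode SEs.
#' @param n_presso Null simulations for the global pleiotropy test.
#' @param alpha Significance level used by the decision tree.
#' @param seed Optional RNG seed governing the bootstrap and the
#'   pleiotropy simulation.
#' @return Object of class `"mr_fit"`: `estimates` (list of
#'   `"mr_estimate"`), `heterogeneity`, `intercept_test`, `presso`, `loo`,
#'   `choice`, `instruments`, `n_iv`.
#' @export
mr_fit <- function(instruments, n_boot = 1000, n_presso = 1000,
                   alpha = 0.05, seed = NULL) {
  k <- nrow(instruments)
  if (k < 1) stop("no instruments to fit")
  est <- list()
  if (k == 1) {
    est$wald <- mr_wald_ratio(instruments)
  } else {
    est$ivw <- mr_ivw(instruments)
  }
  if (k >= 3) {
    est$egger <- mr_egger(instruments)
    est$wmedian <- mr_weighted_median(instruments, n_boot = n_boot,
                                      seed = if (is.null(seed)) NULL else seed + 1L)
    est$wmode <- mr_weighted_mode(instruments, n_boot = n_boot,
                                  seed = if (is.null(seed)) NULL else seed + 2L)
    est$raps <- tryCatch(mr_raps(instruments),
                         error = function(e) NULL, warning = function(w) NULL)
    if (is.null(est$raps)) est["raps"] <- NULL
  }
  het <- if (k >= 2) heterogeneity_stats(instruments) else NULL
  itest <- if (k >= 3) egger_intercept_test(instruments) else NULL
  presso <- if (k >= 4)
    presso_global(instruments, n_sim = n_presso,
                  seed = if (is.null(seed)) NULL else seed + 3L) else NULL
  loo <- if (k >= 3) leave_one_out(instruments, sig_thresh = alpha) else NULL
  choice <- tryCatch(
    select_main_method(k, het, itest, presso, alpha = alpha),
    error = function(e) structure(list(chosen = NA_character_, branch = NA_integer_,
                                       rationale = conditionMessage(e),
                                       diagnostics = numeric(0), incomplete = TRUE),
                                  class = "method_choice"))
  structure(list(estimates = est, heterogeneity = het, intercept_test = itest,
                 presso = presso, loo = loo, choice = choice,
                 instruments = instruments, n_iv = k),
            class = "mr_fit")
}

# One row per estimator, as a data frame.
estimates_table <- function(x) {
  do.call(rbind, lapply(x$estimates, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               n_iv = e$n_iv, stringsAsFactors = FALSE)
  }))
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit,", x$n_iv, "instruments\n")
  tab <- estimates_table(x)
  main <- x$choice$chosen
  tab$main <- ifelse(tab$method == main, "*", "")
  print(format(tab, digits = digits), row.names = FALSE)
  print(x$choice)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object, table = estimates_table(object)),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$fit$heterogeneity)) print(x$fit$heterogeneity)
  if (!is.null(x$fit$intercept_test))
    cat(sprintf("Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                x$fit$intercept_test$intercept, x$fit$intercept_test$se,
                x$fit$intercept_test$p))
  if (!is.null(x$fit$presso)) print(x$fit$presso)
  if (!is.null(x$fit$loo) && any(x$fit$loo$flag))
    cat("Leave-one-out flags:",
        paste(x$fit$loo$excluded_snp[x$fit$loo$flag], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, method = NULL, ...) {
  if (is.null(method)) method <- object$choice$chosen
  if (is.na(method)) method <- names(object$estimates)[1]
  e <- object$estimates[[method]]
  if (is.null(e)) stop("estimator '", method, "' not available in this fit")
  stats::setNames(e$beta, method)
}

#' @export
confint.mr_fit <- function(object, parm = NULL, level = 0.95, ...) {
  tab <- estimates_table(object)
  if (level != 0.95)
    warning("only the 95% intervals computed at fit time are stored")
  m <- as.matrix(tab[, c("ci_low", "ci_high")])
  rownames(m) <- tab$method
  if (!is.null(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
residuals.mr_fit <- function(object, method = NULL, ...) {
  if (is.null(method)) method <- object$choice$chosen
  if (is.na(method)) method <- names(object$estimates)[1]
  beta <- object$estimates[[method]]$beta
  instr <- object$instruments
  stats::setNames((instr$beta_out - beta * instr$beta_exp) / instr$se_out,
                  instr$snp)
}

#' Scatter plot of a two-sample MR fit
#'
#' Plots per-SNP outcome against exposure effects with +/- 1 SE bars and
#' the fitted lines of the available estimators (IVW through the origin,
#' Egger with intercept, weighted median/mode slopes).
#'
#' @param x An `"mr_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  instr <- x$instruments
  s <- ifelse(instr$beta_exp < 0, -1, 1)
  bx <- s * instr$beta_exp; by <- s * instr$beta_out
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19,
                 xlim = range(0, bx + instr$se_exp, bx - instr$se_exp), ...)
  graphics::segments(bx, by - instr$se_out, bx, by + instr$se_out, col = "grey60")
  graphics::segments(bx - instr$se_exp, by, bx + instr$se_exp, by, col = "grey60")
  cols <- c(ivw = "black", egger = "firebrick", wmedian = "steelblue",
            wmode = "darkgreen", raps = "orange", wald = "black")
  shown <- character(0)
  for (m in names(x$estimates)) {
    e <- x$estimates[[m]]
    a <- if (m == "egger") e$intercept else 0
    graphics::abline(a = a, b = e$beta, col = cols[[m]],
                     lty = if (m == "egger") 2 else 1)
    shown <- c(shown, m)
  }
  graphics::legend("topleft", legend = shown, col = cols[shown],
                   lty = ifelse(shown == "egger", 2, 1), bty = "n")
  invisible(x)
}
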