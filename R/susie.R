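# Sum-of-single-effects (SuSiE-style) fine-mapping from z-scores and an LD
# matrix. The model is the standard regional summary-statistic model
#   z ~ N(R b, R),  b = sum_l b_l,  b_l = gamma_l * beta_l,
# with gamma_l a single indicator drawn from the prior weights and
# beta_l ~ N(0, sigma0_sq[l]). Fitting is coordinate ascent over the L
# single effects: each update is an exact Bayesian single-effect regression
# on the residualized z-scores, with the per-effect prior variance set by
# maximizing the single-effect marginal likelihood (floored at 0, so a null
# effect collapses to its uniform prior and cannot spawn a phantom credible
# set). The variational objective (ELBO) is tracked per iteration and is
# non-decreasing.

# Single-effect regression on residual z-scores.
# With unit-diagonal R the per-SNP "bhat" is the residual z itself with
# sampling variance 1, so log BF_j = -log(1+s0)/2 + z_j^2/2 * s0/(1+s0).
ser_lbf <- function(z_res, s0sq) {
  r <- s0sq / (1 + s0sq)
  -0.5 * log1p(s0sq) + 0.5 * z_res^2 * r
}

# log of the SER marginal likelihood (up to a constant): logsumexp over
# prior-weighted Bayes factors.
ser_loglik <- function(s0sq, z_res, log_pi) {
  lbf <- ser_lbf(z_res, s0sq)
  m <- max(lbf + log_pi)
  m + log(sum(exp(lbf + log_pi - m)))
}

# Maximize the SER likelihood over the prior variance; returns 0 when the
# null is not beaten (within a small slack to avoid chasing noise).
estimate_prior_variance <- function(z_res, log_pi) {
  upper <- max(4, max(z_res^2))
  opt <- stats::optimize(function(s) ser_loglik(exp(s), z_res, log_pi),
                         interval = c(log(1e-4), log(upper)), maximum = TRUE)
  if (opt$objective > ser_loglik(0, z_res, log_pi) + 1e-10) exp(opt$maximum) else 0
}

#' Fine-map a region with the sum-of-single-effects model
#'
#' @param z Per-SNP z-scores (beta/se), no missing values.
#' @param ld LD matrix over the same SNPs (unit diagonal), as from
#'   [as_ld_matrix()].
#' @param L Maximum number of causal signals modelled.
#' @param prior_weights Per-SNP prior inclusion probabilities (default
#'   uniform).
#' @param max_iter Maximum coordinate-ascent sweeps.
#' @param tol Convergence tolerance on the change in the objective.
#' @param ridge Diagonal regularization added to `ld` when it is not
#'   positive semi-definite within tolerance.
#' @return An object of class `"susie_fit"`: `alpha` (L x p posterior
#'   inclusion probabilities per effect, rows sum to 1), `mu`/`mu2`
#'   (posterior first/second moments of the effect sizes), `lbf` (L x p
#'   per-effect single-effect log Bayes factors at convergence),
#'   `sigma0_sq` (per-effect prior variances), `pip` (per-SNP posterior
#'   inclusion probability `1 - prod_l(1 - alpha[l,])`), `elbo_trace`,
#'   `converged`, `niter`, `snps`.
#' @export
susie_rss <- function(z, ld, L = 10, prior_weights = NULL, max_iter = 100,
                      tol = 1e-3, ridge = 1e-6) {
  p <- length(z)
  if (any(!is.finite(z))) stop("z-scores contain missing or non-finite values")
  if (nrow(ld) != p) stop("length(z) must equal dim(ld)")
  stopifnot(L >= 1, max_iter >= 1)
  R <- unname(as.matrix(ld))
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    if (ev_min < -0.1)
      stop("LD matrix is far from positive semi-definite (min eigenvalue ",
           signif(ev_min, 3), "); check z/LD consistency or increase ridge")
    R <- R + diag(ridge - ev_min, p)
    R <- R / sqrt(diag(R) %o% diag(R))
  }
  pi0 <- if (is.null(prior_weights)) rep(1 / p, p) else prior_weights / sum(prior_weights)
  log_pi <- log(pi0)

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  mu2 <- matrix(0, L, p)
  lbf <- matrix(0, L, p)
  s0 <- numeric(L)
  kl <- numeric(L)
  Rb <- matrix(0, L, p)   # R %*% (alpha_l * mu_l) per effect
  zz <- sum(z^2)          # constant offset in the objective

  elbo <- -Inf
  elbo_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (l in seq_len(L)) {
      z_res <- z - (colSums(Rb) - Rb[l, ])
      s0[l] <- estimate_prior_variance(z_res, log_pi)
      if (s0[l] == 0) {
        alpha[l, ] <- pi0
        mu[l, ] <- 0
        mu2[l, ] <- 0
        lbf[l, ] <- 0
        kl[l] <- 0
        Rb[l, ] <- 0
        next
      }
      lbf[l, ] <- ser_lbf(z_res, s0[l])
      w <- lbf[l, ] + log_pi
      w <- exp(w - max(w))
      alpha[l, ] <- w / sum(w)
      shrink <- s0[l] / (1 + s0[l])          # posterior variance (sampling var = 1)
      mu[l, ] <- shrink * z_res
      mu2[l, ] <- mu[l, ]^2 + shrink
      b <- alpha[l, ] * mu[l, ]
      Rb[l, ] <- drop(R %*% b)
      # KL(q_l || prior_l) for the ELBO
      lp <- ifelse(alpha[l, ] > 0, log(alpha[l, ] / pi0), 0)
      kl[l] <- sum(alpha[l, ] * (lp + 0.5 * (log(s0[l] / shrink) +
                                               (shrink + mu[l, ]^2) / s0[l] - 1)))
    }
    bbar <- colSums(alpha * mu)
    cross <- sum(bbar * drop(R %*% bbar)) -
      sum(vapply(seq_len(L), function(l) sum((alpha[l, ] * mu[l, ]) * Rb[l, ]), 0))
    fit_term <- zz - 2 * sum(bbar * z) + cross + sum(alpha * mu2)
    new_elbo <- -0.5 * fit_term - sum(kl)
    elbo_trace <- c(elbo_trace, new_elbo)
    if (is.finite(elbo) && abs(new_elbo - elbo) < tol) {
      converged <- TRUE
      elbo <- new_elbo
      break
    }
    elbo <- new_elbo
  }
  pip <- 1 - apply(1 - alpha, 2, prod)
  structure(list(alpha = alpha, mu = mu, mu2 = mu2, lbf = lbf,
                 sigma0_sq = s0, pip = pip, elbo_trace = elbo_trace,
                 converged = converged, niter = length(elbo_trace),
                 snps = rownames(ld)),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat("Sum-of-single-effects fit:", ncol(x$alpha), "SNPs,",
      nrow(x$alpha), "effects (", sum(x$sigma0_sq > 0), "active ),",
      x$niter, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  top <- order(x$pip, decreasing = TRUE)[seq_len(min(5, length(x$pip)))]
  lab <- if (is.null(x$snps)) top else x$snps[top]
  cat("Top PIPs:", paste0(lab, "=", signif(x$pip[top], 3), collapse = ", "), "\n")
  invisible(x)
}

#' Extract credible sets from a fine-mapping fit
#'
#' For each active effect, SNPs are ranked by posterior inclusion
#' probability and the smallest prefix reaching the coverage target forms
#' the set. Sets whose purity (minimum absolute pairwise LD among members)
#' falls below `min_purity` are discarded, as are effects whose prior
#' variance collapsed to zero; duplicated memberships are reported once.
#'
#' @param fit A [susie_rss()] fit.
#' @param ld LD matrix over the fitted SNPs.
#' @param coverage Target cumulative inclusion mass (default 0.9).
#' @param min_purity Minimum purity to report a set (default 0.5).
#' @return List of credible sets: `effect`, `snps` (indices), `snp_ids`,
#'   `coverage_attained`, `purity`.
#' @export
credible_sets <- function(fit, ld, coverage = 0.9, min_purity = 0.5) {
  stopifnot(inherits(fit, "susie_fit"), coverage > 0, coverage <= 1)
  R <- as.matrix(ld)
  sets <- list()
  seen <- character(0)
  for (l in seq_len(nrow(fit$alpha))) {
    if (fit$sigma0_sq[l] == 0) next
    ord <- order(fit$alpha[l, ], decreasing = TRUE)
    mass <- cumsum(fit$alpha[l, ord])
    ntake <- which(mass >= coverage - 1e-12)[1]
    if (is.na(ntake)) ntake <- length(ord)   # coverage 1 with rounding
    if (coverage >= 1) ntake <- sum(fit$alpha[l, ] > 0)
    members <- sort(ord[seq_len(ntake)])
    pur <- if (length(members) == 1) 1 else min(abs(R[members, members]))
    if (pur < min_purity) next
    key <- paste(members, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sets[[length(sets) + 1L]] <- list(
      effect = l, snps = members,
      snp_ids = if (is.null(fit$snps)) as.character(members) else fit$snps[members],
      coverage_attained = sum(fit$alpha[l, members]),
      purity = pur)
  }
  sets
}
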