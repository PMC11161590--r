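# Two-sample MR estimators. All operate on an "instruments" data frame
# (columns beta_exp, se_exp, beta_out, se_out, snp) and return an
# "mr_estimate": method, beta, se, ci_low, ci_high, pvalue, n_iv, plus
# method-specific extras. Ratio-estimate variances use first-order delta
# approximations throughout; 95% CIs are normal-theory except for the
# bootstrap-based weighted median/mode, which use percentile intervals.

new_mr_estimate <- function(method, beta, se, n_iv, ci = NULL, ...) {
  z975 <- stats::qnorm(0.975)
  if (is.null(ci)) ci <- c(beta - z975 * se, beta + z975 * se)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci[1], ci_high = ci[2],
                 pvalue = 2 * stats::pnorm(-abs(beta / se)),
                 n_iv = n_iv, ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g, k = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_iv))
  invisible(x)
}

check_instruments <- function(instr, min_k, method) {
  if (nrow(instr) < min_k)
    stop(method, " requires at least ", min_k, " instruments (got ",
         nrow(instr), ")")
  if (any(instr$se_out <= 0) || any(instr$se_exp < 0))
    stop("standard errors must be positive")
  invisible(TRUE)
}

#' Wald ratio estimator (single instrument)
#'
#' `beta = beta_out/beta_exp`, `se = se_out/|beta_exp|` (first-order delta
#' method), normal-theory p-value.
#'
#' @param instr Instruments data frame with exactly one row.
#' @return `"mr_estimate"` with method `"wald"`.
#' @export
mr_wald_ratio <- function(instr) {
  if (nrow(instr) != 1L) stop("wald ratio requires exactly 1 instrument")
  if (instr$beta_exp == 0) stop("beta_exp is zero; ratio undefined")
  new_mr_estimate("wald", instr$beta_out / instr$beta_exp,
                  instr$se_out / abs(instr$beta_exp), 1L)
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' Origin-constrained weighted regression of outcome on exposure effects
#' with weights `1/se_out^2`. Residual heterogeneity (Cochran's Q with
#' first-order radial weights) scales the fixed-effect SE by
#' `max(1, sqrt(Q/(k-1)))` (multiplicative random-effects model). With one
#' instrument this reduces exactly to the Wald ratio.
#'
#' @param instr Instruments data frame (k >= 2; k = 1 defers to
#'   [mr_wald_ratio()]).
#' @return `"mr_estimate"` with method `"ivw"` and fields `q`, `q_df`,
#'   `q_p`.
#' @export
mr_ivw <- function(instr) {
  if (nrow(instr) == 1L) return(mr_wald_ratio(instr))
  check_instruments(instr, 2, "ivw")
  x <- instr$beta_exp; y <- instr$beta_out; w <- 1 / instr$se_out^2
  beta <- sum(w * x * y) / sum(w * x^2)
  se_fixed <- sqrt(1 / sum(w * x^2))
  k <- length(x)
  q <- sum(w * (y - beta * x)^2)   # = radial Q: sum w_r (ratio - beta)^2
  se <- se_fixed * max(1, sqrt(q / (k - 1)))
  new_mr_estimate("ivw", beta, se, k, q = q, q_df = k - 1,
                  q_p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

# Orient instruments so all exposure effects are positive (Egger convention).
egger_orient <- function(instr) {
  s <- ifelse(instr$beta_exp < 0, -1, 1)
  data.frame(x = s * instr$beta_exp, y = s * instr$beta_out,
             w = 1 / instr$se_out^2)
}

#' MR-Egger regression
#'
#' Weighted regression with intercept of (sign-oriented) outcome on
#' exposure effects, weights `1/se_out^2`. The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. Rucker's Q' from the residuals scales the SEs
#' multiplicatively as in [mr_ivw()]. The intercept p-value uses a t
#' reference with k-2 df.
#'
#' @param instr Instruments data frame (k >= 3).
#' @return `"mr_estimate"` with method `"egger"` and fields `intercept`,
#'   `intercept_se`, `intercept_p`, `q_prime`, `q_prime_df`, `q_prime_p`.
#' @export
mr_egger <- function(instr) {
  check_instruments(instr, 3, "mr_egger")
  d <- egger_orient(instr)
  X <- cbind(1, d$x)
  fit <- stats::lm.wfit(X, d$y, d$w)
  k <- nrow(instr)
  qp <- sum(d$w * fit$residuals^2)
  XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(d$w))))
  scale <- max(1, sqrt(qp / (k - 2)))
  se_int <- sqrt(XtWX_inv[1, 1]) * scale
  se_slope <- sqrt(XtWX_inv[2, 2]) * scale
  intercept <- unname(fit$coefficients[1])
  new_mr_estimate("egger", unname(fit$coefficients[2]), se_slope, k,
                  intercept = intercept, intercept_se = se_int,
                  intercept_p = 2 * stats::pt(-abs(intercept / se_int), k - 2),
                  q_prime = qp, q_prime_df = k - 2,
                  q_prime_p = if (k > 2)
                    stats::pchisq(qp, k - 2, lower.tail = FALSE) else NA_real_)
}

# Weighted 50th percentile with the midpoint (cumulative weight - w/2)
# convention and linear interpolation between bracketing order statistics.
weighted_percentile <- function(values, weights, q = 0.5) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  cs <- (cumsum(w) - w / 2) / sum(w)
  if (q <= cs[1]) return(v[1])
  if (q >= cs[length(cs)]) return(v[length(v)])
  below <- max(which(cs < q))
  if (cs[below + 1] == cs[below]) return(v[below])
  v[below] + (v[below + 1] - v[below]) * (q - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted median estimator
#'
#' Weighted 50th percentile of the per-SNP ratio estimates with
#' first-order inverse-variance weights `beta_exp^2/se_out^2`; consistent
#' when at least half the total weight comes from valid instruments. SE by
#' seeded parametric bootstrap; percentile-bootstrap 95% CI.
#'
#' @param instr Instruments data frame (k >= 3).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @return `"mr_estimate"` with method `"wmedian"`.
#' @export
mr_weighted_median <- function(instr, n_boot = 1000, seed = NULL) {
  check_instruments(instr, 3, "weighted median")
  est <- function(bx, by) {
    r <- by / bx
    w <- bx^2 / instr$se_out^2
    weighted_percentile(r, w, 0.5)
  }
  beta <- est(instr$beta_exp, instr$beta_out)
  boot <- boot_ratio_estimator(instr, est, n_boot, seed)
  new_mr_estimate("wmedian", beta, stats::sd(boot), nrow(instr),
                  ci = unname(stats::quantile(boot, c(0.025, 0.975))))
}

# Parametric bootstrap over the instrument summary statistics.
boot_ratio_estimator <- function(instr, est, n_boot, seed) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(instr)
  vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, instr$beta_exp, instr$se_exp)
    by <- stats::rnorm(k, instr$beta_out, instr$se_out)
    est(bx, by)
  }, numeric(1))
}

# Weighted kernel-density mode of the ratio estimates. The bandwidth is
# bandwidth_factor times a weighted-MAD scale (modified Silverman rule);
# exact ties in the smoothed density break toward the smaller ratio.
weighted_mode_point <- function(ratio, w, bandwidth_factor = 1, n_grid = 1024) {
  w <- w / sum(w)
  med <- weighted_percentile(ratio, w, 0.5)
  scale <- 1.4826 * weighted_percentile(abs(ratio - med), w, 0.5)
  if (scale == 0)   # > 50% of weight on one exact ratio: fall back to the SD
    scale <- sqrt(sum(w * (ratio - sum(w * ratio))^2))
  h <- bandwidth_factor * 0.9 * scale * length(ratio)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(min(ratio))   # all ratios identical
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  dens <- drop(w %*% stats::dnorm(outer(ratio, grid, "-") / h))
  grid[which.max(dens)]   # which.max takes the first (= smaller ratio) on ties
}

#' Weighted mode estimator
#'
#' Mode of the kernel-smoothed, inverse-variance-weighted density of the
#' per-SNP ratio estimates; consistent when the largest group of
#' instruments is valid. SE by seeded parametric bootstrap;
#' percentile-bootstrap 95% CI.
#'
#' @param instr Instruments data frame (k >= 3).
#' @param bandwidth_factor Multiplier on the weighted-MAD bandwidth
#'   (default 1).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @return `"mr_estimate"` with method `"wmode"`.
#' @export
mr_weighted_mode <- function(instr, bandwidth_factor = 1, n_boot = 1000,
                             seed = NULL) {
  check_instruments(instr, 3, "weighted mode")
  est <- function(bx, by) {
    weighted_mode_point(by / bx, bx^2 / instr$se_out^2, bandwidth_factor)
  }
  beta <- est(instr$beta_exp, instr$beta_out)
  boot <- boot_ratio_estimator(instr, est, n_boot, seed)
  new_mr_estimate("wmode", beta, stats::sd(boot), nrow(instr),
                  ci = unname(stats::quantile(boot, c(0.025, 0.975))))
}

huber_psi <- function(t, c = 1.345) pmax(pmin(t, c), -c)

# E[psi(T) T] for T ~ N(0,1): consistency constant of the overdispersion
# moment equation. For the Huber score this is 2*Phi(c) - 1; for L2 it is 1.
huber_delta <- function(c = 1.345) 2 * stats::pnorm(c) - 1

#' Robust adjusted profile score estimator
#'
#' Solves the profile-score estimating equations in the causal effect
#' `beta` and (optionally) an overdispersion variance `tau2 >= 0`:
#' standardized residuals
#' `t_j = (beta_out_j - beta*beta_exp_j)/sqrt(se_out_j^2 + beta^2 se_exp_j^2 + tau2)`
#' enter a psi-weighted score `sum psi(t_j) * beta_exp_j / sigma_j = 0`
#' with the Huber score (tuning constant 1.345) or the identity (`loss =
#' "l2"`); `tau2` solves the companion moment equation
#' `sum (psi(t_j) t_j - delta)/sigma_j^2 = 0`. The SE comes from the
#' sandwich variance of the profile score.
#'
#' @param instr Instruments data frame (k >= 3).
#' @param overdispersion Estimate `tau2` (default TRUE); otherwise fixed 0.
#' @param loss `"huber"` (default) or `"l2"`.
#' @param max_iter Maximum alternations between the two equations.
#' @return `"mr_estimate"` with method `"raps"` and field `tau2`.
#' @export
mr_raps <- function(instr, overdispersion = TRUE, loss = c("huber", "l2"),
                    max_iter = 100) {
  check_instruments(instr, 3, "mr_raps")
  loss <- match.arg(loss)
  cc <- 1.345
  psi <- if (loss == "huber") function(t) huber_psi(t, cc) else function(t) t
  delta <- if (loss == "huber") huber_delta(cc) else 1
  x <- instr$beta_exp; y <- instr$beta_out
  vx <- instr$se_exp^2; vy <- instr$se_out^2

  # adjusted profile score: the second term corrects for measurement error
  # in the exposure effects (E[psi(T)T] = delta keeps it unbiased)
  score_beta_j <- function(beta, tau2) {
    sig2 <- vy + beta^2 * vx + tau2
    sig <- sqrt(sig2)
    t <- (y - beta * x) / sig
    psi(t) * x / sig + (psi(t) * t - delta) * beta * vx / sig2
  }
  score_beta <- function(beta, tau2) sum(score_beta_j(beta, tau2))
  score_tau <- function(tau2, beta) {
    sig2 <- vy + beta^2 * vx + tau2
    t <- (y - beta * x) / sqrt(sig2)
    sum((psi(t) * t - delta) / sig2)
  }
  solve_beta <- function(tau2, start) {
    span <- 10 * (abs(start) + 1)
    for (tries in 1:6) {
      lo <- start - span; hi <- start + span
      flo <- score_beta(lo, tau2); fhi <- score_beta(hi, tau2)
      if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0)
        return(stats::uniroot(score_beta, c(lo, hi), tau2 = tau2,
                              tol = 1e-12)$root)
      span <- span * 4
    }
    stop("mr_raps: could not bracket a root of the profile score")
  }
  beta <- mr_ivw(instr)$beta
  tau2 <- 0
  for (it in seq_len(max_iter)) {
    beta_new <- solve_beta(tau2, beta)
    tau2_new <- 0
    if (overdispersion) {
      if (score_tau(0, beta_new) > 0) {
        up <- stats::var(y - beta_new * x) + max(vy)
        for (tries in 1:6) {
          if (score_tau(up, beta_new) < 0) break
          up <- up * 4
        }
        tau2_new <- stats::uniroot(score_tau, c(0, up), beta = beta_new,
                                   tol = 1e-12)$root
      }
    }
    done <- abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-10
    beta <- beta_new; tau2 <- tau2_new
    if (done) break
  }
  if (it == max_iter && !done)
    warning("mr_raps did not converge in ", max_iter, " iterations")
  # sandwich variance of the profile score in beta
  B <- sum(score_beta_j(beta, tau2)^2)
  h <- 1e-6 * (abs(beta) + 1)
  A <- (score_beta(beta + h, tau2) - score_beta(beta - h, tau2)) / (2 * h)
  se <- sqrt(B / A^2)
  new_mr_estimate("raps", beta, se, nrow(instr), tau2 = tau2)
}
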