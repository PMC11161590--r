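# Estimator correctness against independent oracles, exact reductions,
# and sign-flip equivariance.

test_that("the Wald ratio follows the delta-method closed form", {
  i <- make_instr(0.1, 0.3, se_out = 0.05)
  w <- mr_wald_ratio(i)
  expect_equal(w$beta, 3)
  expect_equal(w$se, 0.5)
  expect_equal(w$ci_low, 3 - qnorm(0.975) * 0.5)
  expect_equal(mr_wald_ratio(make_instr(0.1, 0))$beta, 0)
  # negative exposure effect flips the sign, not the SE
  wneg <- mr_wald_ratio(make_instr(-0.1, 0.3, se_out = 0.05))
  expect_equal(wneg$beta, -3)
  expect_equal(wneg$se, 0.5)
  expect_error(mr_wald_ratio(make_instr(0, 0.3)), "zero")
})

test_that("IVW matches the weighted normal-equations oracle to 1e-10", {
  i <- make_instr(c(0.05, 0.08, 0.12), c(0.02, 0.02, 0.035),
                  se_out = c(0.01, 0.02, 0.015))
  e <- mr_ivw(i)
  orc <- wls_oracle(i$beta_exp, i$beta_out, 1 / i$se_out^2)
  expect_equal(e$beta, unname(orc), tolerance = 1e-10)
  # homogeneous ratios: beta = c, Q = 0, fixed-effect SE
  ih <- make_instr(c(0.05, 0.1, 0.2), 0.4 * c(0.05, 0.1, 0.2))
  eh <- mr_ivw(ih)
  expect_equal(eh$beta, 0.4)
  expect_equal(eh$q, 0, tolerance = 1e-20)
  expect_equal(eh$se, sqrt(1 / sum(ih$beta_exp^2 / ih$se_out^2)))
  # duplicating every instrument keeps beta, doubles Q
  i2 <- rbind(i, i)
  expect_equal(mr_ivw(i2)$beta, e$beta)
  expect_equal(mr_ivw(i2)$q, 2 * e$q, tolerance = 1e-10)
  # single instrument reduces exactly to the Wald ratio
  expect_equal(mr_ivw(i[1, ])$beta, mr_wald_ratio(i[1, ])$beta)
  expect_equal(mr_ivw(i[1, ])$se, mr_wald_ratio(i[1, ])$se)
})

test_that("Egger regression matches the WLS oracle and recovers planted pleiotropy", {
  # exact line through the origin
  x <- c(0.05, 0.1, 0.15, 0.2)
  i0 <- make_instr(x, 0.5 * x)
  e0 <- mr_egger(i0)
  expect_equal(e0$beta, 0.5, tolerance = 1e-12)
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  expect_equal(e0$q_prime, 0, tolerance = 1e-16)
  # planted intercept and slope recovered exactly without noise
  i1 <- make_instr(x, 0.1 + 0.3 * x, se_out = c(0.01, 0.02, 0.03, 0.01))
  e1 <- mr_egger(i1)
  expect_equal(e1$beta, 0.3, tolerance = 1e-10)
  expect_equal(e1$intercept, 0.1, tolerance = 1e-10)
  orc <- wls_oracle(i1$beta_exp, i1$beta_out, 1 / i1$se_out^2, intercept = TRUE)
  expect_equal(c(e1$intercept, e1$beta), unname(orc), tolerance = 1e-10)
  # 3 points leave one residual df for Q'
  e3 <- mr_egger(make_instr(x[1:3], c(0.02, 0.05, 0.04)))
  expect_equal(e3$q_prime_df, 1)
  expect_error(mr_egger(make_instr(x[1:2], x[1:2])), "at least 3")
})

test_that("the weighted median matches the brute-force percentile oracle", {
  # equal weights on ratios {1, 2, 9}: ordinary median
  i <- make_instr(rep(0.1, 3), 0.1 * c(1, 2, 9))
  expect_equal(mr_weighted_median(i, n_boot = 50, seed = 1)$beta, 2)
  # majority weight on one SNP gives that SNP's ratio
  im <- make_instr(c(0.1, 0.3, 0.1), c(0.1 * 1, 0.3 * 2, 0.1 * 9))
  expect_equal(mr_weighted_median(im, n_boot = 50, seed = 1)$beta, 2)
  # outlier-robust
  io <- make_instr(rep(0.1, 10), c(rep(0.03, 9), 0.5))
  expect_equal(mr_weighted_median(io, n_boot = 50, seed = 1)$beta, 0.3,
               tolerance = 1e-10)
  # random fixtures against the loop-based oracle
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(3:20, 1)
    ir <- make_instr(runif(k, 0.02, 0.2), rnorm(k, 0.1, 0.2),
                     se_out = runif(k, 0.01, 0.1))
    est <- mr_weighted_median(ir, n_boot = 2, seed = 1)$beta
    orc <- percentile_oracle(ir$beta_out / ir$beta_exp,
                             ir$beta_exp^2 / ir$se_out^2)
    expect_equal(est, orc, tolerance = 1e-10)
  }
})

test_that("the weighted mode finds the dominant ratio cluster", {
  ic <- make_instr(rep(0.1, 3), rep(0.03, 3))
  expect_equal(mr_weighted_mode(ic, n_boot = 20, seed = 1)$beta, 0.3)
  # cluster of 7 at 0.3 plus 3 spread outliers
  i7 <- make_instr(rep(0.1, 10),
                   c(rep(0.03, 7), 0.12, -0.08, 0.3))
  est <- mr_weighted_mode(i7, n_boot = 20, seed = 1)$beta
  expect_lt(abs(est - 0.3), 0.05)
  orc <- mode_oracle(i7$beta_out / i7$beta_exp, i7$beta_exp^2 / i7$se_out^2)
  expect_lt(abs(est - orc), 0.01)   # grid resolution
  # bimodal with equal mass: tie broken toward the smaller ratio
  ib <- make_instr(rep(0.1, 6), c(rep(0.02, 3), rep(0.08, 3)))
  expect_lt(mr_weighted_mode(ib, n_boot = 20, seed = 1)$beta, 0.5)
})

test_that("the profile-score estimator solves its estimating equations", {
  # noiseless data with negligible exposure-side noise: exact recovery
  # (the adjusted score's measurement-error term vanishes with se_exp)
  x <- runif(5, 0.05, 0.2)
  i0 <- make_instr(x, 0.3 * x, se_exp = 1e-8)
  r0 <- mr_raps(i0)
  expect_equal(r0$beta, 0.3, tolerance = 1e-8)
  expect_equal(r0$tau2, 0)
  # squared loss with tau2 fixed 0 equals the independently-found root of
  # the plain profile score on a 3-IV toy
  i3 <- make_instr(c(0.05, 0.1, 0.15), c(0.02, 0.028, 0.05),
                   se_exp = 0.01, se_out = 0.02)
  r3 <- mr_raps(i3, overdispersion = FALSE, loss = "l2")
  score <- function(b) {
    sig2 <- i3$se_out^2 + b^2 * i3$se_exp^2
    t <- (i3$beta_out - b * i3$beta_exp) / sqrt(sig2)
    sum(t * i3$beta_exp / sqrt(sig2) + (t^2 - 1) * b * i3$se_exp^2 / sig2)
  }
  root <- uniroot(score, c(-5, 5), tol = 1e-14)$root
  expect_equal(r3$beta, root, tolerance = 1e-8)
  # simulation: recovers the truth within 2 Monte-Carlo SEs under
  # balanced pleiotropy
  set.seed(5)
  est <- replicate(500, {
    s <- simulate_mr_dataset(k = 50, true_beta = 0.3,
                             pleiotropy = "balanced", tau = 0.05)
    mr_raps(s$instruments)$beta
  })
  expect_lt(abs(mean(est) - 0.3), 2 * sd(est) / sqrt(length(est)))
})

test_that("estimators are equivariant under per-SNP sign flips", {
  set.seed(13)
  sim <- simulate_mr_dataset(k = 12, true_beta = 0.4, seed = 13)
  i <- sim$instruments
  flip <- sample(c(1, -1), nrow(i), replace = TRUE)
  i2 <- i
  i2$beta_exp <- flip * i$beta_exp
  i2$beta_out <- flip * i$beta_out
  expect_equal(mr_ivw(i2)$beta, mr_ivw(i)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(i2)$beta, mr_egger(i)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(i2, n_boot = 2, seed = 1)$beta,
               mr_weighted_median(i, n_boot = 2, seed = 1)$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(i2, n_boot = 2, seed = 1)$beta,
               mr_weighted_mode(i, n_boot = 2, seed = 1)$beta,
               tolerance = 1e-9)
  expect_equal(mr_raps(i2)$beta, mr_raps(i)$beta, tolerance = 1e-8)
})

test_that("under directional pleiotropy satisfying InSIDE, Egger is unbiased where IVW is not", {
  set.seed(17)
  res <- t(replicate(200, {
    s <- simulate_mr_dataset(k = 30, true_beta = 0.3,
                             pleiotropy = "directional", delta = 0.02,
                             tau = 0.01)
    c(ivw = mr_ivw(s$instruments)$beta, egger = mr_egger(s$instruments)$beta)
  }))
  # IVW biased upward (positive direct effects), Egger centred on truth
  expect_gt(mean(res[, "ivw"]) - 0.3, 0.1)
  expect_lt(abs(mean(res[, "egger"]) - 0.3),
            3 * sd(res[, "egger"]) / sqrt(nrow(res)))
})
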