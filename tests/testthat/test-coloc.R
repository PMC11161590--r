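mk_trait <- function(beta, se, snp = paste0("rs", seq_along(beta)),
                     p = 2 * pnorm(-abs(beta / se))) {
  data.frame(snp = snp, chr = "1", pos = seq_along(beta) * 1000,
             ea = "A", oa = "G", eaf = 0.3, beta = beta, se = se, p = p,
             n = 1e4, stringsAsFactors = FALSE)
}

test_that("log_abf matches the closed form and its limits", {
  # W = 0: point-null prior, BF = 1 exactly
  expect_equal(log_abf(0.3, 0.1, 0), 0)
  # z = 0: only the shrinkage term survives
  V <- 0.02^2; W <- 0.15^2
  expect_equal(log_abf(0, 0.02, 0.15), 0.5 * log(V / (V + W)))
  # independent evaluation of the closed form
  beta <- 0.1; se <- 0.02
  r <- W / (V + W)
  expect_equal(log_abf(beta, se, 0.15),
               0.5 * log(1 - r) + r * (beta / se)^2 / 2, tolerance = 1e-14)
  expect_error(log_abf(0.1, 0, 0.15), "positive")
})

test_that("a single shared strong SNP gives dominant PPH4 matching 1-SNP enumeration", {
  t1 <- mk_trait(10 * 0.02, 0.02)
  t2 <- mk_trait(10 * 0.05, 0.05)
  res <- coloc_abf(t1, t2)
  expect_equal(sum(res$pph), 1, tolerance = 1e-8)
  expect_gt(res$pph[["PPH4"]], 0.99)
  # closed-form single-SNP enumeration (H3 impossible with one SNP)
  bf1 <- exp(log_abf(t1$beta, t1$se, 0.15))
  bf2 <- exp(log_abf(t2$beta, t2$se, 0.15))
  orc <- coloc_enum_oracle(bf1, bf2)
  expect_equal(unname(res$pph), unname(orc), tolerance = 1e-10)
  expect_equal(res$pph[["PPH3"]], 0)
  expect_equal(top_causal_snp(res), "rs1")
})

test_that("a null region gives PPH0 > 0.99 and distinct causal SNPs favour PPH3", {
  t1 <- mk_trait(rep(0, 100), 0.02)
  t2 <- mk_trait(rep(0, 100), 0.05)
  expect_gt(coloc_abf(t1, t2)$pph[["PPH0"]], 0.99)
  # 3-SNP toy: trait 1 causal at a, trait 2 at b, uncorrelated
  t1 <- mk_trait(c(0.2, 0, 0), 0.02)
  t2 <- mk_trait(c(0, 0.5, 0), 0.05)
  res <- coloc_abf(t1, t2)
  expect_equal(names(which.max(res$pph)), "PPH3")
  bf1 <- exp(log_abf(t1$beta, t1$se, 0.15))
  bf2 <- exp(log_abf(t2$beta, t2$se, 0.15))
  expect_equal(unname(res$pph), unname(coloc_enum_oracle(bf1, bf2)),
               tolerance = 1e-10)
})

test_that("posteriors stay normalized and stable at extreme z, and per-SNP H4 is shift-invariant", {
  t1 <- mk_trait(c(40 * 0.02, 0.001, -0.002), 0.02)
  t2 <- mk_trait(c(40 * 0.05, 0.002, 0.001), 0.05)
  res <- coloc_abf(t1, t2)
  expect_equal(sum(res$pph), 1, tolerance = 1e-8)
  expect_true(all(is.finite(res$pph)))
  expect_equal(sum(res$per_snp_h4), 1, tolerance = 1e-8)
  # rescaling all Bayes factors shifts every hypothesis mass it touches but
  # leaves the per-SNP H4 attribution untouched
  e1 <- mrstrat:::coloc_enumerate(log_abf(t1$beta, t1$se, 0.15),
                                  log_abf(t2$beta, t2$se, 0.15), abf_params())
  e2 <- mrstrat:::coloc_enumerate(log_abf(t1$beta, t1$se, 0.15) + 50,
                                  log_abf(t2$beta, t2$se, 0.15) + 30, abf_params())
  expect_equal(e1$per_snp_h4, e2$per_snp_h4, tolerance = 1e-10)
})

test_that("allele orientation of trait 2 is aligned before enumeration", {
  t1 <- mk_trait(c(0.2, 0.01), 0.02)
  t2 <- mk_trait(c(0.5, 0.01), 0.05)
  t2_swapped <- t2
  t2_swapped$ea <- t1$oa
  t2_swapped$oa <- t1$ea
  t2_swapped$beta <- -t2$beta
  expect_equal(coloc_abf(t1, t2)$pph, coloc_abf(t1, t2_swapped)$pph)
  expect_error(coloc_abf(t1, mk_trait(0.1, 0.02, snp = "other")), "shared")
})

test_that("classification is strict at the threshold", {
  res <- structure(list(pph = c(PPH0 = 0, PPH1 = 0, PPH2 = 0, PPH3 = 0.2,
                                PPH4 = 0.8)), class = "coloc_result")
  expect_false(classify_coloc(res))
  res$pph <- c(PPH0 = 0, PPH1 = 0, PPH2 = 0, PPH3 = 0.15, PPH4 = 0.85)
  expect_true(classify_coloc(res))
  res$pph <- c(PPH0 = 0, PPH1 = 0, PPH2 = 0, PPH3 = 0, PPH4 = 1)
  expect_true(classify_coloc(res))
})

test_that("top_causal_snp takes the argmax with p-value then lexicographic tie-breaks", {
  mk_res <- function(h4, p1 = NULL) {
    structure(list(pph = c(PPH0 = 0, PPH1 = 0, PPH2 = 0, PPH3 = 0.05,
                           PPH4 = 0.95),
                   per_snp_h4 = h4, trait1_p = p1), class = "coloc_result")
  }
  expect_equal(top_causal_snp(mk_res(c(a = 0.7, b = 0.2, c = 0.1))), "a")
  expect_equal(top_causal_snp(mk_res(c(a = 0.5, b = 0.5),
                                     p1 = c(a = 1e-8, b = 1e-10))), "b")
  expect_equal(top_causal_snp(mk_res(c(b = 0.5, a = 0.5))), "a")
  res_null <- mk_res(c(a = 1))
  res_null$pph <- c(PPH0 = 1, PPH1 = 0, PPH2 = 0, PPH3 = 0, PPH4 = 0)
  expect_error(top_causal_snp(res_null), "non-colocalized")
})

test_that("credible-set-pairwise mode reduces to the single-effect enumeration", {
  set.seed(31)
  sim <- simulate_region_sumstats(n_snps = 40, rho = 0.6, seed = 31)
  eq <- sim$eqtl[sim$eqtl$context == "cellA", ]
  R <- sim$ld
  f1 <- susie_rss(sim$gwas$beta / sim$gwas$se, R, L = 5)
  f2 <- susie_rss(eq$beta / eq$se, R, L = 5)
  s1 <- credible_sets(f1, R)
  s2 <- credible_sets(f2, R)
  expect_gte(length(s1), 1)
  expect_gte(length(s2), 1)
  res <- coloc_susie(f1, s1, f2, s2)
  expect_equal(length(res), length(s1) * length(s2))
  expect_equal(res[[1]]$signal_pair, c(1, 1))
  # agreement with the generic enumeration run on the same per-effect BFs
  direct <- mrstrat:::coloc_enumerate(f1$lbf[s1[[1]]$effect, ],
                                      f2$lbf[s2[[1]]$effect, ], abf_params())
  expect_equal(res[[1]]$pph, direct$pph, tolerance = 1e-8)
  expect_gt(res[[1]]$pph[["PPH4"]], 0.8)
})

test_that("disjoint unlinked credible sets give PPH3-dominant pairs and empty sets an empty list", {
  set.seed(32)
  R <- simulate_ld(60, rho = 0.9, block_size = 30)
  z1t <- numeric(60); z1t[10] <- 10
  z2t <- numeric(60); z2t[45] <- 10
  z1 <- drop(unclass(R) %*% z1t) + drop(crossprod(chol(unclass(R) + diag(1e-8, 60)), rnorm(60)))
  z2 <- drop(unclass(R) %*% z2t) + drop(crossprod(chol(unclass(R) + diag(1e-8, 60)), rnorm(60)))
  f1 <- susie_rss(z1, R, L = 5)
  f2 <- susie_rss(z2, R, L = 5)
  s1 <- credible_sets(f1, R); s2 <- credible_sets(f2, R)
  res <- coloc_susie(f1, s1, f2, s2)
  for (r in res)
    expect_gt(r$pph[["PPH3"]], r$pph[["PPH4"]])
  expect_equal(coloc_susie(f1, list(), f2, s2), list())
})
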