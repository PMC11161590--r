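mk_exposure <- function(snp, p, chr = "1", pos = seq_along(snp) * 1e5,
                        beta = 0.05, eaf = 0.3, ea = "A", oa = "G") {
  data.frame(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = 0.005, p = p, n = 1e5,
             stringsAsFactors = FALSE)
}

test_that("candidate selection applies the relevance threshold with union semantics", {
  exposure <- mk_exposure(c("rs1", "rs2", "rs3"), c(6.99e-40, 1e-7, 1e-9))
  out <- select_candidates(c("rs1", "rs2", "rs1", "rs4"), exposure)
  expect_equal(out$snp, "rs1")
  log <- attr(out, "drop_log")
  expect_equal(log$above_p_thresh, "rs2")
  expect_equal(log$not_in_exposure, "rs4")
})

test_that("confounder filter removes direct and proxy hits above r2 0.8", {
  exposure <- mk_exposure(c("rs1", "rs2", "rs3"), rep(1e-10, 3))
  ld <- as_ld_matrix(matrix(c(1, sqrt(0.9), sqrt(0.4),
                              sqrt(0.9), 1, 0,
                              sqrt(0.4), 0, 1), 3, 3),
                     c("rs1", "rsProxy", "rsWeak"))
  conf <- data.frame(snp = c("rs2", "rsProxy", "rsWeak"),
                     confounder = c("smoking", "education", "drinking"),
                     p = c(1e-9, 1e-9, 1e-9), stringsAsFactors = FALSE)
  out <- confounder_filter(exposure, conf, ld)
  # rs2: direct hit; rs1: proxy rsProxy at r2 0.9; rs3 has no LD row -> kept
  expect_equal(out$snp, "rs3")
  expect_setequal(attr(out, "drop_log")$confounder_hits, c("rs1", "rs2"))
  expect_equal(attr(out, "drop_log")$no_ld_coverage, c("rs2", "rs3"))
  # proxy at r2 = 0.4 with a hit is retained
  conf2 <- conf[conf$snp == "rsWeak", ]
  expect_true("rs1" %in% confounder_filter(exposure, conf2, ld)$snp)
})

test_that("greedy clumping keeps the strongest SNP per window and is order-independent", {
  cand <- mk_exposure(c("A", "B", "C"), c(1e-10, 1e-9, 1e-9),
                      pos = c(1e6, 1e6 + 5e4, 1e6 + 1e5))
  ld <- as_ld_matrix(matrix(c(1, sqrt(0.5), sqrt(4e-4),
                              sqrt(0.5), 1, 0,
                              sqrt(4e-4), 0, 1), 3, 3), c("A", "B", "C"))
  out <- ld_clump(cand, ld)
  expect_setequal(out$snp, c("A", "C"))
  expect_equal(names(attr(out, "drop_log")$clumped), "B")
  # permuted input gives the same index set
  out2 <- ld_clump(cand[c(3, 1, 2), ], ld)
  expect_setequal(out2$snp, out$snp)
  # outside the 10,000 kb window high r2 does not clump
  far <- mk_exposure(c("D", "E"), c(1e-10, 1e-9), pos = c(1e6, 1e6 + 2e10 / 1e3))
  ld2 <- as_ld_matrix(matrix(c(1, 0.9, 0.9, 1), 2, 2), c("D", "E"))
  expect_equal(nrow(ld_clump(far, ld2)), 2)
  # single candidate kept; sub-threshold p excluded
  expect_equal(ld_clump(cand[1, ], ld)$snp, "A")
  weak <- mk_exposure("F", 1e-6)
  expect_equal(nrow(ld_clump(weak, ld)), 0)
})

test_that("proxy substitution replaces missing SNPs by their best strong proxy", {
  exposure <- mk_exposure(c("rs1", "rs2", "prox95", "prox70"),
                          c(1e-10, 1e-12, 1e-9, 1e-9),
                          pos = c(1e6, 2e6, 1.01e6, 2.01e6))
  outcome <- mk_exposure(c("rs1", "prox95", "prox70"), rep(0.5, 3))
  ld <- as_ld_matrix(matrix(c(1, 0, 0, 0,
                              0, 1, sqrt(0.95), sqrt(0.70),
                              0, sqrt(0.95), 1, 0,
                              0, sqrt(0.70), 0, 1), 4, 4),
                     c("rs1", "rs2", "prox95", "prox70"))
  idx <- exposure[1:2, ]
  out <- proxy_substitute(idx, exposure, outcome, ld)
  expect_equal(out$snp, c("rs1", "prox95"))
  expect_equal(out$provenance, c("original", "proxy"))
  expect_equal(out$proxy_of[2], "rs2")
  expect_equal(out$proxy_r2[2], 0.95, tolerance = 1e-12)
  # best remaining proxy below r2 0.8 -> dropped
  out2 <- proxy_substitute(idx[2, , drop = FALSE], exposure,
                           mk_exposure("prox70", 0.5), ld)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "drop_log")$unresolvable, "rs2")
})

test_that("harmonization handles swaps, strand flips and palindromes", {
  expo <- mk_exposure("rs1", 1e-10, ea = "A", oa = "G")
  expo$beta <- 0.1
  # swapped alleles negate the outcome beta
  outc <- mk_exposure("rs1", 0.5, ea = "G", oa = "A")
  outc$beta <- 0.3
  outc$eaf <- 0.7
  h <- harmonize(expo, outc)
  expect_equal(h$beta_out, -0.3)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$ea, "A")
  # identical orientation passes through
  outc2 <- mk_exposure("rs1", 0.5, ea = "A", oa = "G")
  outc2$beta <- 0.3
  expect_equal(harmonize(expo, outc2)$beta_out, 0.3)
  # complementary-strand coding resolved via non-palindromic alleles
  outc3 <- mk_exposure("rs1", 0.5, ea = "T", oa = "C")
  outc3$beta <- 0.3
  expect_equal(harmonize(expo, outc3)$beta_out, 0.3)
  outc3b <- mk_exposure("rs1", 0.5, ea = "C", oa = "T")
  outc3b$beta <- 0.3
  expect_equal(harmonize(expo, outc3b)$beta_out, -0.3)
  # irreconcilable alleles dropped with a reason
  outc4 <- mk_exposure("rs1", 0.5, ea = "A", oa = "C")
  h4 <- harmonize(expo, outc4)
  expect_equal(nrow(h4), 0)
  expect_equal(unname(attr(h4, "drop_log")), "incompatible_alleles")
})

test_that("intermediate-frequency and frequency-less palindromes are removed", {
  expo <- mk_exposure("rs1", 1e-10, ea = "A", oa = "T", eaf = 0.5)
  outc <- mk_exposure("rs1", 0.5, ea = "A", oa = "T", eaf = 0.5)
  h <- harmonize(expo, outc)
  expect_equal(nrow(h), 0)
  expect_equal(unname(attr(h, "drop_log")), "palindromic_ambiguous")
  # MAF just below the 0.42 bound survives, resolved by frequency matching
  expo$eaf <- 0.3; outc$eaf <- 0.3
  expect_equal(harmonize(expo, outc)$beta_out, outc$beta)
  # opposite-strand coding of the same palindrome detected via frequency
  outc_f <- outc; outc_f$eaf <- 0.7
  expect_equal(harmonize(expo, outc_f)$beta_out, -outc$beta)
  # missing frequency cannot be resolved
  expo_na <- expo; expo_na$eaf <- NA_real_
  expect_equal(nrow(harmonize(expo_na, outc)), 0)
})

test_that("harmonization is involutive", {
  set.seed(77)
  sim <- simulate_mr_dataset(k = 30, palindrome_frac = 0.4, seed = 77)
  h1 <- harmonize(sim$exposure, sim$outcome)
  # feed the harmonized outcome back through
  out2 <- data.frame(snp = h1$snp, chr = "1", pos = seq_len(nrow(h1)),
                     ea = h1$ea, oa = h1$oa, eaf = h1$eaf_out,
                     beta = h1$beta_out, se = h1$se_out, p = 0.5, n = 1e4,
                     stringsAsFactors = FALSE)
  h2 <- harmonize(sim$exposure[match(h1$snp, sim$exposure$snp), ], out2)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$eaf_out, h1$eaf_out)
  expect_equal(h2$ea, h1$ea)
})

test_that("radial filtering removes planted outliers and accounts per-SNP Q exactly", {
  # perfect homogeneity: nothing removed, zero Q
  instr <- make_instr(rep(0.1, 10), rep(0.03, 10))
  rf <- radial_outlier_filter(instr)
  expect_equal(nrow(rf$removed), 0)
  expect_equal(rf$q_ivw, 0, tolerance = 1e-20)
  # planted heterogeneous ratio
  instr2 <- make_instr(rep(0.1, 10), c(rep(0.03, 9), 0.3), se_out = 0.01)
  rf2 <- radial_outlier_filter(instr2)
  expect_true("rs10" %in% rf2$removed$snp)
  # brute-force per-SNP Q for the planted SNP
  w <- instr2$beta_exp^2 / instr2$se_out^2
  ratio <- instr2$beta_out / instr2$beta_exp
  bhat <- sum(w * ratio) / sum(w)
  q10 <- w[10] * (ratio[10] - bhat)^2
  expect_gt(q10, qchisq(0.95, 1))
  # radial total Q equals the sum of per-SNP contributions
  expect_equal(sum(w * (ratio - bhat)^2),
               sum(sapply(seq_len(10), function(j) w[j] * (ratio[j] - bhat)^2)),
               tolerance = 1e-10)
  # fewer than 3 instruments pass through unchanged
  rf3 <- radial_outlier_filter(instr2[1:2, ])
  expect_equal(nrow(rf3$instruments), 2)
  # zero exposure beta dropped pre-fit with a reason code
  instr4 <- instr2
  instr4$beta_exp[1] <- 0
  rf4 <- radial_outlier_filter(instr4)
  expect_true(any(rf4$removed$test == "zero_exposure_beta"))
})

test_that("the F-statistic follows both printed formulas", {
  instr <- make_instr(0.05, 0.02, se_exp = 0.005)
  fs <- instrument_strength(instr, 1e5)
  # independent evaluation
  r2 <- 0.05^2 / (0.05^2 + 0.005^2 * 1e5)
  f <- r2 * (1e5 - 1 - 1) / (1 * (1 - r2))
  expect_equal(fs$r2_total, r2, tolerance = 1e-14)
  expect_equal(fs$f, f, tolerance = 1e-12)
  expect_false(fs$weak)
  # null instrument: R2 = 0, F = 0, weak
  instr0 <- make_instr(0, 0.02)
  fs0 <- instrument_strength(instr0, 1e5)
  expect_equal(fs0$f, 0)
  expect_true(fs0$weak)
  # per-SNP R2 sums to the total; sample-size guard
  instr2 <- make_instr(c(0.05, 0.03), c(0.02, 0.01))
  fs2 <- instrument_strength(instr2, 1e5)
  expect_equal(sum(fs2$r2_per_snp), fs2$r2_total)
  expect_error(instrument_strength(instr2, 3), "exceed")
})
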