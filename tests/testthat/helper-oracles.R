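# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-arithmetic reimplementations at tiny n.

# Weighted-least-squares slope/intercept via the normal equations.
wls_oracle <- function(x, y, w, intercept = FALSE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)[, 1]
}

# Brute-force weighted percentile (midpoint convention, linear
# interpolation), written as an explicit loop.
percentile_oracle <- function(values, weights, q = 0.5) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord] / sum(weights)
  cs <- numeric(length(w))
  run <- 0
  for (i in seq_along(w)) {
    cs[i] <- run + w[i] / 2
    run <- run + w[i]
  }
  if (q <= cs[1]) return(v[1])
  if (q >= cs[length(cs)]) return(v[length(v)])
  i <- max(which(cs < q))
  v[i] + (v[i + 1] - v[i]) * (q - cs[i]) / (cs[i + 1] - cs[i])
}

# Fine-grid weighted kernel-density argmax with the same bandwidth rule,
# evaluated pointwise in a loop on a much finer grid.
mode_oracle <- function(ratio, w, bandwidth_factor = 1, n_grid = 20001) {
  w <- w / sum(w)
  med <- percentile_oracle(ratio, w, 0.5)
  scale <- 1.4826 * percentile_oracle(abs(ratio - med), w, 0.5)
  if (scale == 0) {
    mu <- sum(w * ratio)
    scale <- sqrt(sum(w * (ratio - mu)^2))
  }
  h <- bandwidth_factor * 0.9 * scale * length(ratio)^(-1 / 5)
  if (h <= 0) return(min(ratio))
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  dens <- numeric(n_grid)
  for (i in seq_len(n_grid))
    dens[i] <- sum(w * dnorm((grid[i] - ratio) / h))
  grid[which.max(dens)]
}

# Direct (non-log-space) enumeration of the five colocalization
# hypothesis masses from per-SNP Bayes factors, for toys with moderate z.
coloc_enum_oracle <- function(bf1, bf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  s1 <- sum(bf1)
  s2 <- sum(bf2)
  s12 <- sum(bf1 * bf2)
  m <- c(H0 = 1, H1 = p1 * s1, H2 = p2 * s2,
         H3 = p1 * p2 * (s1 * s2 - s12), H4 = p12 * s12)
  m / sum(m)
}

# A minimal instruments table.
make_instr <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                       snp = paste0("rs", seq_along(beta_exp))) {
  k <- length(beta_exp)
  data.frame(snp = snp, ea = rep("A", k), oa = rep("C", k),
             beta_exp = beta_exp, se_exp = rep(se_exp, length.out = k),
             p_exp = 2 * pnorm(-abs(beta_exp / rep(se_exp, length.out = k))),
             eaf_exp = 0.3, beta_out = beta_out,
             se_out = rep(se_out, length.out = k), eaf_out = 0.3,
             context = "test", provenance = "original",
             stringsAsFactors = FALSE)
}

write_temp_sumstats <- function(df, ...) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  f
}
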