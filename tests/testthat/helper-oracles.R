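# Independent oracles, kept deliberately naive so they stay independent of
# the implementation paths they check.

# Benjamini-Hochberg step-up by the definition: sort ascending, multiply by
# m/i, enforce monotonicity from the largest rank down, cap at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Pearson r and its two-sided p from the closed-form definitions.
pearsonOracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Equal-variance two-sided t-test from the pooled-variance formula.
tTestOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}

# A tiny hand-specifiable study: Ct and gene matrices built directly from
# given group means, no randomness.
tinySheet <- function(nDonors = 2, nHep = 2, nLsec = 2) {
  donors <- sprintf("D%d", seq_len(nDonors))
  rbind(
    data.frame(sample_id = c(paste0("qHSC_", donors), paste0("aHSC_", donors)),
               cell_type = "HSC",
               state = rep(c("quiescent", "activated"), each = nDonors),
               donor_id = rep(donors, 2)),
    data.frame(sample_id = sprintf("HEP_%d", seq_len(nHep)),
               cell_type = "hepatocyte", state = NA, donor_id = "H"),
    data.frame(sample_id = sprintf("LSEC_%d", seq_len(nLsec)),
               cell_type = "LSEC", state = NA, donor_id = "L"))
}

defaultTestParams <- function(...) simParams(...)
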