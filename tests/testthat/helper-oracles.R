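# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately literal re-statements of the definitions and share
# no code with the package internals.

# Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(m * p[ord][i:m] / (i:m), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Greedy clumping, literal: repeatedly take the lowest-p unassigned SNP
# (ties: position, then id), prune unassigned SNPs within the window AND at
# r2 >= threshold.
clump_oracle <- function(snp, pos, p, r2_mat, r2_thresh, window_bp) {
  unassigned <- rep(TRUE, length(snp))
  out <- character()
  while (any(unassigned)) {
    cand <- which(unassigned)
    cand <- cand[order(p[cand], pos[cand], snp[cand])]
    i <- cand[1]
    out <- c(out, snp[i])
    unassigned[i] <- FALSE
    for (j in which(unassigned)) {
      if (abs(pos[j] - pos[i]) <= window_bp &&
          r2_mat[snp[i], snp[j]] >= r2_thresh) {
        unassigned[j] <- FALSE
      }
    }
  }
  out
}

# Direct (non-log) evaluation of the five-hypothesis posteriors; only valid
# for moderate |labf|, which is all the tests feed it.
coloc_oracle <- function(l1, l2, p1, p2, p12) {
  L1 <- sum(exp(l1))
  L2 <- sum(exp(l2))
  L12 <- sum(exp(l1 + l2))
  u <- c(1, p1 * L1, p2 * L2,
         if (length(l1) > 1) p1 * p2 * (L1 * L2 - L12) else 0,
         p12 * L12)
  u / sum(u)
}

# Simulated genotypes + phenotype for the COJO-vs-OLS oracle: a small region
# with two causal SNPs, returning everything a summary-level analysis needs
# alongside the raw data.
simulate_cojo_region <- function(seed, n = 2000, n_snp = 20) {
  set.seed(seed)
  panel <- simulate_haplotype_panel(300, n_snp, maf_range = c(0.1, 0.5),
                                    ld_decay = 0.7, seed = seed)
  hap <- panel$haplotypes
  g <- hap[sample.int(nrow(hap), n, replace = TRUE), ] +
    hap[sample.int(nrow(hap), n, replace = TRUE), ]
  causal <- c(5, 15)
  y <- 0.25 * g[, causal[1]] + 0.2 * g[, causal[2]] + rnorm(n)
  # Marginal per-SNP simple regressions via lm (independent of the package).
  marg <- t(apply(g, 2, function(x) {
    f <- summary(stats::lm(y ~ x))$coefficients
    f["x", c("Estimate", "Std. Error", "Pr(>|t|)")]
  }))
  ss <- as_sumstats(tibble::tibble(
    snp = panel$snps$snp, chr = panel$snps$chr, pos = panel$snps$pos,
    ea = panel$snps$ea, nea = panel$snps$nea,
    eaf = colMeans(g) / 2, beta = marg[, 1], se = marg[, 2],
    p = pmax(marg[, 3], 1e-320), n = n), validate = FALSE)
  list(g = g, y = y, ss = ss, ld = stats::cor(g),
       var_x = stats::setNames(apply(g, 2, stats::var), panel$snps$snp),
       causal = panel$snps$snp[causal])
}

# A tiny hand-made sumstats tibble for fixture-style tests.
toy_sumstats <- function(df, ...) {
  defaults <- tibble::tibble(
    snp = sprintf("s%d", seq_len(nrow(df))), chr = "1",
    pos = seq_len(nrow(df)) * 1000L, ea = "A", nea = "G",
    eaf = 0.3, beta = 0.1, se = 0.05, p = NA_real_, n = 10000)
  out <- defaults
  for (nm in names(df)) out[[nm]] <- df[[nm]]
  if (all(is.na(out$p))) {
    out$p <- 2 * pnorm(-abs(out$beta / out$se))
  }
  as_sumstats(out, ..., validate = FALSE)
}
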