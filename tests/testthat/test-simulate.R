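test_that("null quantitative traits are calibrated", {
  # ~10,000 null SNP draws: genome-wide hits should be essentially absent.
  hits <- 0
  for (s in 1:4) {
    panel <- simulate_haplotype_panel(300, 2500, ld_decay = 0, seed = s)
    ss <- simulate_quant_sumstats(panel, numeric(), n = 5000,
                                  mode = "analytic", seed = s)
    hits <- hits + sum(ss$p < 5e-8)
  }
  expect_lte(hits, 1)
})

test_that("single-causal F-statistic matches the noncentrality oracle", {
  n <- 10000
  hsq <- 0.05
  lambda <- n * hsq / (1 - hsq)
  f_obs <- sapply(1:200, function(s) {
    panel <- simulate_haplotype_panel(300, 5, maf_range = c(0.28, 0.32),
                                      ld_decay = 0.2, seed = 5000 + s)
    beta <- sqrt(hsq) / sqrt(2 * panel$snps$eaf[3] *
                               (1 - panel$snps$eaf[3]))
    ss <- simulate_quant_sumstats(
      panel, stats::setNames(beta, panel$snps$snp[3]), n = n,
      mode = "genotype_level", seed = 6000 + s)
    (ss$beta[3] / ss$se[3])^2
  })
  # E[F] ~ 1 + lambda, Var[F] ~ 2 + 4*lambda (noncentral chi-square).
  se_mean <- sqrt(2 + 4 * lambda) / sqrt(200)
  expect_lt(abs(mean(f_obs) - (1 + lambda)), 3 * se_mean)
})

test_that("genotype-level and analytic modes agree", {
  panel <- simulate_haplotype_panel(3000, 50, ld_decay = 0.8, seed = 11)
  causal <- stats::setNames(
    c(0.15, -0.1), panel$snps$snp[c(15, 35)])
  n <- 50000
  sa <- simulate_quant_sumstats(panel, causal, n = n, mode = "analytic",
                                seed = 12)
  sg <- simulate_quant_sumstats(panel, causal, n = n,
                                mode = "genotype_level", seed = 13)
  # At the causal variants the two marginal estimates agree within the
  # combined sampling noise; across the region they are strongly coherent.
  for (cs in names(causal)) {
    i <- match(cs, sa$snp)
    expect_lt(abs(sa$beta[i] - sg$beta[i]),
              3 * sqrt(sa$se[i]^2 + sg$se[i]^2))
  }
  expect_gt(cor(sa$beta, sg$beta), 0.9)
})

test_that("null case-control statistics have unit inflation", {
  panel <- simulate_haplotype_panel(400, 2000, ld_decay = 0, seed = 21)
  ss <- simulate_cc_sumstats(panel, numeric(), n_case = 2000,
                             n_control = 2000, seed = 22)
  z2 <- (ss$beta / ss$se)^2
  expect_lt(abs(mean(z2) - 1), 0.1)
})

test_that("case-control estimator recovers a causal log OR", {
  panel <- simulate_haplotype_panel(400, 10, maf_range = c(0.28, 0.32),
                                    ld_decay = 0.1, seed = 23)
  ss <- simulate_cc_sumstats(panel,
                             stats::setNames(0.15, panel$snps$snp[5]),
                             n_case = 20000, n_control = 20000, seed = 24)
  expect_lt(abs(ss$beta[5] - 0.15), 3 * ss$se[5])
  expect_lt(ss$p[5], 5e-8)
})

test_that("the exact logistic fit is used at small n and agrees with glm", {
  panel <- simulate_haplotype_panel(200, 6, maf_range = c(0.2, 0.4),
                                    seed = 25)
  ss <- simulate_cc_sumstats(panel,
                             stats::setNames(0.4, panel$snps$snp[2]),
                             n_case = 400, n_control = 400,
                             exact_n_max = 2000, seed = 26)
  # SEs from a logistic fit at n = 800 are moderate and finite.
  expect_true(all(is.finite(ss$se) & ss$se > 0))
  expect_lt(abs(ss$beta[2] - 0.4), 4 * ss$se[2])
})

test_that("simulators are deterministic and validate their inputs", {
  panel <- simulate_haplotype_panel(200, 10, seed = 31)
  a <- simulate_quant_sumstats(panel, numeric(), n = 500,
                               mode = "genotype_level", seed = 5)
  b <- simulate_quant_sumstats(panel, numeric(), n = 500,
                               mode = "genotype_level", seed = 5)
  expect_identical(a, b)
  d <- simulate_cc_sumstats(panel, numeric(), 100, 100, seed = 6)
  e <- simulate_cc_sumstats(panel, numeric(), 100, 100, seed = 6)
  expect_identical(d, e)

  big <- stats::setNames(10, panel$snps$snp[1]) # variance >= 1
  expect_error(simulate_quant_sumstats(panel, big, n = 1000),
               class = "mrcoco_parameter_error")
  expect_error(simulate_quant_sumstats(panel, numeric(), n = 10),
               class = "mrcoco_parameter_error")
  expect_error(simulate_cc_sumstats(panel, numeric(), 10, 1000),
               class = "mrcoco_parameter_error")
  expect_error(simulate_cc_sumstats(panel, numeric(), 100, 100,
                                    prevalence = 0),
               class = "mrcoco_parameter_error")
  expect_error(
    simulate_quant_sumstats(panel, stats::setNames(0.1, "nope"), n = 100),
    class = "mrcoco_parameter_error")
})

test_that("marginal effects at an isolated causal SNP are recovered", {
  ok <- sapply(1:25, function(s) {
    panel <- simulate_haplotype_panel(300, 20, ld_decay = 0.5,
                                      seed = 7000 + s)
    i <- 10
    beta <- 0.2
    ss <- simulate_quant_sumstats(
      panel, stats::setNames(beta, panel$snps$snp[i]), n = 8000,
      mode = "analytic", seed = 7100 + s)
    abs(ss$beta[i] - beta) < 3 * ss$se[i]
  })
  expect_gte(mean(ok), 0.9)
})
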