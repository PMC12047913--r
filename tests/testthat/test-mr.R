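test_that("wald_ratio reproduces hand-computed values", {
  w <- wald_ratio(0.5, 0.05, -0.06, 0.02)
  expect_equal(w$wald_beta, -0.12, tolerance = 1e-12)
  expect_equal(w$wald_se, 0.04, tolerance = 1e-12)
  expect_equal(exp(w$wald_beta), 0.8869204, tolerance = 1e-6)

  # zero exposure SE: second order collapses to first order
  w1 <- wald_ratio(0.5, 0, -0.06, 0.02, se_order = "first")
  w2 <- wald_ratio(0.5, 0, -0.06, 0.02, se_order = "second")
  expect_equal(w2$wald_se, w1$wald_se, tolerance = 1e-12)

  expect_error(wald_ratio(0, 0.05, 0.1, 0.02),
               class = "mrcoco_parameter_error")
})

test_that("delta-method SE matches a parametric bootstrap of the ratio", {
  set.seed(77)
  for (i in 1:5) {
    beta_exp <- runif(1, 0.3, 1)
    se_exp <- runif(1, 0.01, 0.05)
    beta_out <- runif(1, -0.2, 0.2)
    se_out <- runif(1, 0.01, 0.05)
    draws <- rnorm(1e5, beta_out, se_out) / rnorm(1e5, beta_exp, se_exp)
    w <- wald_ratio(beta_exp, se_exp, beta_out, se_out,
                    se_order = "second")
    expect_equal(w$wald_se, sd(draws), tolerance = 0.05)
  }
})

test_that("or_with_ci exponentiates the Wald interval", {
  null_or <- or_with_ci(0, 0.1)
  expect_equal(null_or$or_point, 1)
  expect_equal(null_or$ci_low * null_or$ci_high, 1, tolerance = 1e-12)

  # a protective effect of typical reported magnitude
  orci <- or_with_ci(-0.1165, 0.0229)
  z <- qnorm(0.975)
  expect_equal(orci$or_point, exp(-0.1165), tolerance = 1e-12)
  expect_equal(orci$ci_low, exp(-0.1165 - z * 0.0229), tolerance = 1e-12)
  expect_equal(orci$ci_high, exp(-0.1165 + z * 0.0229), tolerance = 1e-12)
  expect_equal(round(c(orci$or_point, orci$ci_low, orci$ci_high), 2),
               c(0.89, 0.85, 0.93))

  # alpha = 0.32 gives approximately a +/- 1 SE interval
  o32 <- or_with_ci(0.2, 0.1, alpha = 0.32)
  expect_equal(log(o32$ci_high), 0.2 + qnorm(0.84) * 0.1,
               tolerance = 1e-12)
  expect_equal(log(o32$ci_high), 0.3, tolerance = 0.01)
})

test_that("bh_fdr reproduces the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(5)
  p <- runif(500)^2
  expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 0)), class = "mrcoco_parameter_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mrcoco_parameter_error")
  # q-values are monotone in the ranked p-values
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("wald_ratio is sign-equivariant and scale-consistent", {
  set.seed(9)
  be <- runif(10, 0.1, 1)
  se_e <- runif(10, 0.01, 0.1)
  bo <- rnorm(10, 0, 0.2)
  se_o <- runif(10, 0.01, 0.1)
  w <- wald_ratio(be, se_e, bo, se_o)
  w_neg <- wald_ratio(be, se_e, -bo, se_o)
  expect_equal(w_neg$wald_beta, -w$wald_beta)
  expect_equal(exp(w_neg$wald_beta), 1 / exp(w$wald_beta))
  expect_equal(w_neg$pvalue, w$pvalue)

  # rescaling the exposure by c rescales the ratio by 1/c, p unchanged
  cst <- 2.7
  w_scaled <- wald_ratio(cst * be, cst * se_e, bo, se_o)
  expect_equal(w_scaled$wald_beta, w$wald_beta / cst)
  expect_equal(w_scaled$pvalue, w$pvalue)
})

test_that("mr_screen assembles per-outcome results with FDR control", {
  study <- simulate_study(n_genes = 6, kinds = c("shared", "null"),
                          n_profiles = 2, n_snp = 150, n_ref = 150,
                          seed = 31)
  res <- mr_screen(study$exposures, study$outcomes, study$genes,
                   study$gene_map, study$ld)
  expect_s3_class(res, "mr_screen")
  expect_true(all(c("wald_beta", "fdr_q", "significant") %in% names(res)))
  expect_true(all(res$fdr_q >= res$pvalue - 1e-12))
  expect_true(all(res$or_point == exp(res$wald_beta)))
  expect_true(all(res$ci_low < res$or_point & res$or_point < res$ci_high))
  g <- glance(res)
  expect_equal(g$n_tests, nrow(res))

  # empty input: warning plus empty tibble
  expect_warning(
    empty <- mr_screen(list(), study$outcomes, study$genes,
                       study$gene_map, study$ld),
    "no instruments")
  expect_equal(nrow(empty), 0)
})
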