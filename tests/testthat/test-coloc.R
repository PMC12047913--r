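test_that("wakefield_labf reproduces hand-computed values", {
  expect_equal(wakefield_labf(0, 0.1, 0.2), 0.5 * log(0.01 / 0.05),
               tolerance = 1e-12)
  expect_equal(wakefield_labf(0.5, 0.1, 0.2),
               0.5 * (log(0.01 / 0.05) + 25 * 0.04 / 0.05),
               tolerance = 1e-12)
  # prior mass collapsing to the null: labf -> 0 for any z
  expect_lt(abs(wakefield_labf(0.3, 0.1, 1e-9)), 1e-12)
  expect_error(wakefield_labf(0.1, 0, 0.2),
               class = "mrcoco_parameter_error")
  expect_error(wakefield_labf(0.1, 0.1, 0),
               class = "mrcoco_parameter_error")
})

test_that("coloc priors are validated", {
  expect_error(coloc_priors(p12 = 1e-4), class = "mrcoco_parameter_error")
  expect_error(coloc_priors(p1 = 0), class = "mrcoco_parameter_error")
  pr <- coloc_priors()
  expect_equal(c(pr$p1, pr$p2, pr$p12), c(1e-5, 1e-5, 1e-7))
})

test_that("posteriors match the direct closed-form evaluation", {
  # flat evidence over a realistic window: H0 dominates
  n <- 1621
  post <- coloc_posteriors(rep(0, n), rep(0, n))
  want <- coloc_oracle(rep(0, n), rep(0, n), 1e-5, 1e-5, 1e-7)
  expect_equal(unlist(post[1, 1:5], use.names = FALSE), want,
               tolerance = 1e-12)
  expect_equal(which.max(want), 1)
  expect_gt(post$h0, 0.95)

  # one overwhelming shared variant: H4 ~ 1
  l <- rep(-10, 100)
  l[40] <- 20
  post4 <- coloc_posteriors(l, l)
  expect_gt(post4$h4, 0.99)
  want4 <- coloc_oracle(l, l, 1e-5, 1e-5, 1e-7)
  expect_equal(unlist(post4[1, 1:5], use.names = FALSE), want4,
               tolerance = 1e-10)
})

test_that("posteriors always normalise, even for extreme inputs", {
  set.seed(3)
  for (i in 1:100) {
    n <- sample(2:50, 1)
    l1 <- rnorm(n, 0, 50) # |labf| into the hundreds
    l2 <- rnorm(n, 0, 50)
    post <- coloc_posteriors(l1, l2)
    expect_lt(abs(sum(post[1, 1:5]) - 1), 1e-10)
    expect_true(all(post[1, 1:5] >= 0 & post[1, 1:5] <= 1))
  }
})

test_that("permuting the SNP order leaves the posteriors unchanged", {
  set.seed(4)
  l1 <- rnorm(30, 0, 5)
  l2 <- rnorm(30, 0, 5)
  perm <- sample(30)
  expect_equal(tibble::as_tibble(coloc_posteriors(l1, l2)),
               tibble::as_tibble(coloc_posteriors(l1[perm], l2[perm])))
})

test_that("h4 is non-decreasing in the shared prior", {
  set.seed(6)
  l1 <- rnorm(40, 0, 3)
  l2 <- l1 + rnorm(40, 0, 1)
  h4s <- sapply(c(1e-8, 1e-7, 1e-6, 5e-6),
                function(p12) coloc_posteriors(l1, l2,
                                               coloc_priors(p12 = p12))$h4)
  expect_true(all(diff(h4s) >= -1e-12))
})

test_that("a single-SNP region forces h3 to zero", {
  post <- coloc_posteriors(5, 7)
  expect_identical(post$h3, 0)
  expect_lt(abs(sum(post[1, 1:5]) - 1), 1e-10)
})

test_that("coloc_abf aligns datasets and uses trait-type prior SDs", {
  sc <- make_scenario("shared", n_snp = 200, n_ref = 150,
                      outcome_hsq = 0.02, seed = 8)
  post <- coloc_abf(sc$exposures[[1]], sc$outcome)
  expect_equal(post$n_snps, 200)
  expect_gt(post$h4, 0.5)
  # explicit prior SDs reproduce the default
  post2 <- coloc_abf(sc$exposures[[1]], sc$outcome,
                     prior_sd1 = 0.2, prior_sd2 = 0.15)
  expect_equal(tibble::as_tibble(post2), tibble::as_tibble(post))
  expect_equal(tidy(post)$posterior,
               unlist(post[1, 1:5], use.names = FALSE))
})

test_that("expected_signal_counts is the linear expectation", {
  e <- expected_signal_counts(coloc_priors(), 1621)
  expect_equal(e$e_trait1, 1621 * (1e-5 + 1e-7), tolerance = 1e-12)
  expect_equal(e$e_trait1, 0.0163721, tolerance = 1e-6)
  expect_equal(e$e_shared, 1.621e-4, tolerance = 1e-12)
  # no shared prior mass, no expected shared signals
  e0 <- expected_signal_counts(list(p1 = 1e-5, p2 = 1e-5, p12 = 0), 100)
  expect_equal(e0$e_shared, 0)
  # linearity in the window size
  e2 <- expected_signal_counts(coloc_priors(), 3242)
  expect_equal(unlist(e2), 2 * unlist(e), tolerance = 1e-12)
})
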