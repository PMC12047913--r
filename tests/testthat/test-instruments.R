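test_that("cis_filter uses closed-interval boundaries", {
  gene <- tibble::tibble(gene = "g", chr = "1", start = 1000000L,
                         end = 1020000L)
  ss <- toy_sumstats(tibble::tibble(
    snp = c("a", "b", "c", "d"),
    pos = c(1000000L - 500000L,      # exactly on the lower boundary
            1000000L - 500001L,      # one bp outside
            1010000L,                # inside the gene body
            1020000L + 500000L)))    # exactly on the upper boundary
  kept <- cis_filter(ss, gene, window = 5e5)
  expect_setequal(kept$snp, c("a", "c", "d"))
  # degenerate window: gene body only
  expect_equal(cis_filter(ss, gene, window = 0)$snp, "c")
  # wrong chromosome: nothing
  gene2 <- dplyr::mutate(gene, chr = "2")
  expect_equal(nrow(cis_filter(ss, gene2, window = 5e5)), 0)
})

test_that("ld_clump implements the greedy index rule", {
  # two SNPs 5 kb apart in moderate LD: only the lower p survives
  ss <- toy_sumstats(tibble::tibble(
    snp = c("x", "y"), pos = c(10000L, 15000L), p = c(1e-12, 1e-9)))
  ld <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(ld_clump(ss, ld, r2_thresh = 0.001, window_bp = 1e4), "x")
  # far apart (outside the window): both retained even in high LD
  ss2 <- toy_sumstats(tibble::tibble(
    snp = c("x", "y"), pos = c(10000L, 40000L), p = c(1e-12, 1e-9)))
  expect_equal(ld_clump(ss2, ld, 0.001, 1e4), c("x", "y"))
  # single SNP: itself
  expect_equal(ld_clump(ss[1, ], ld, 0.001, 1e4), "x")
  # missing from the LD matrix: lookup error naming the variant
  ss3 <- toy_sumstats(tibble::tibble(snp = "zz", pos = 1L))
  expect_error(ld_clump(ss3, ld, 0.001, 1e4), "zz",
               class = "mrcoco_data_error")
})

test_that("ld_clump matches a brute-force greedy oracle and its invariant", {
  for (s in 1:25) {
    panel <- simulate_haplotype_panel(150, 50, ld_decay = 0.7,
                                      region_span = 3e5, seed = 800 + s)
    set.seed(900 + s)
    ss <- toy_sumstats(tibble::tibble(
      snp = panel$snps$snp, pos = panel$snps$pos,
      p = 10^-runif(50, 2, 15)))
    ld <- ld_from_panel(panel)
    got <- ld_clump(ss, ld, r2_thresh = 0.1, window_bp = 5e4)
    want <- clump_oracle(ss$snp, ss$pos, ss$p, ld^2, 0.1, 5e4)
    expect_identical(got, want)
    # invariant: no two retained indices both within the window and in LD
    r2 <- ld[got, got, drop = FALSE]^2
    pos <- ss$pos[match(got, ss$snp)]
    for (i in seq_along(got)) {
      for (j in seq_along(got)) {
        if (i != j) {
          expect_false(abs(pos[i] - pos[j]) <= 5e4 && r2[i, j] >= 0.1)
        }
      }
    }
  }
})

test_that("f_statistic is the squared z-score", {
  expect_equal(f_statistic(0.3, 0.03), 100)
  expect_equal(f_statistic(0, 0.1), 0)
  set.seed(1)
  b <- rnorm(20)
  s <- runif(20, 0.01, 1)
  expect_equal(f_statistic(b, s), (b / s)^2)
  expect_error(f_statistic(0.1, 0), class = "mrcoco_parameter_error")
})

test_that("steiger_test compares explained variances with a strict rule", {
  e <- toy_sumstats(tibble::tibble(snp = "s1", beta = 1, se = 0.1,
                                   n = 100))
  o <- toy_sumstats(tibble::tibble(snp = "s1", beta = 0.00316,
                                   se = 0.00316, n = 100000))
  st <- steiger_test(e, o)
  expect_equal(st$r2_exposure, 100 / (100 + 98), tolerance = 1e-6)
  expect_equal(st$r2_outcome, 1 / (1 + 99998), tolerance = 1e-3)
  expect_true(st$steiger_pass)

  # exact tie on r2 fails (strict inequality)
  st_tie <- steiger_test(e, e)
  expect_false(st_tie$steiger_pass)

  # case-control outcome uses the effective sample size
  occ <- toy_sumstats(tibble::tibble(snp = "s1", beta = 1, se = 0.1,
                                     n = 40000, n_case = 20000,
                                     n_control = 20000),
                      trait_type = "case_control")
  st_cc <- steiger_test(e, occ)
  expect_equal(st_cc$r2_outcome, 100 / (100 + 40000 - 2), tolerance = 1e-9)
})

test_that("select_instrument applies the filter chain with strict gates", {
  gene <- tibble::tibble(gene = "g", chr = "1", start = 1L, end = 1e6L)
  ld <- diag(2)
  dimnames(ld) <- list(c("s1", "s2"), c("s1", "s2"))

  # p exactly above the genome-wide threshold: no instrument
  z <- abs(qnorm(3e-8)) # two-sided p = 6e-8
  e <- toy_sumstats(tibble::tibble(snp = c("s1", "s2"),
                                   beta = c(z * 0.05, 0.01),
                                   se = c(0.05, 0.05)))
  o <- toy_sumstats(tibble::tibble(snp = c("s1", "s2"), beta = 0,
                                   se = 0.01, n = 1e6))
  expect_null(select_instrument(e, o, gene, ld))

  # weak top SNP (F < 10) is excluded and the next eligible SNP used
  cfg <- instrument_config(p_threshold = 1e-2, f_min = 10)
  e2 <- toy_sumstats(tibble::tibble(
    snp = c("s1", "s2"),
    beta = c(sqrt(9.9) * 0.05, sqrt(16) * 0.05), se = 0.05))
  inst <- select_instrument(e2, o, gene, ld, cfg)
  expect_equal(inst$snp, "s2")
  expect_gte(inst$f_stat, 10)
  excl <- attr(inst, "exclusions")
  expect_true(any(excl$snp == "s1" & excl$reason == "weak_instrument_f"))
})

test_that("the instrument recovers the causal SNP in shared scenarios", {
  hits <- sapply(1:30, function(s) {
    sc <- make_scenario("shared", n_snp = 300, n_ref = 200,
                        seed = 1200 + s)
    inst <- select_instrument(sc$exposures[[1]], sc$outcome, sc$gene,
                              sc$ld)
    !is.null(inst) && inst$snp == names(sc$truth$causal_exposure)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("raising the p threshold never changes the selected instrument", {
  for (s in 1:5) {
    sc <- make_scenario("shared", n_snp = 200, n_ref = 150,
                        seed = 1500 + s)
    strict <- select_instrument(sc$exposures[[1]], sc$outcome, sc$gene,
                                sc$ld, instrument_config(p_threshold = 5e-8))
    loose <- select_instrument(sc$exposures[[1]], sc$outcome, sc$gene,
                               sc$ld, instrument_config(p_threshold = 1e-5))
    if (!is.null(strict)) {
      expect_equal(loose$snp, strict$snp)
    }
  }
})
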