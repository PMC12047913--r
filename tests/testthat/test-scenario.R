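small <- function(kind, ...) {
  make_scenario(kind, n_snp = 150, n_ref = 150, ...)
}

panel_sd_for <- function(sc, ids) {
  i <- match(ids, sc$panel$snps$snp)
  sqrt(2 * sc$panel$snps$eaf[i] * (1 - sc$panel$snps$eaf[i]))
}

test_that("scenario kinds define the stated causal configurations", {
  null_sc <- small("null", seed = 1)
  expect_length(null_sc$truth$causal_outcome, 0)
  expect_length(null_sc$truth$causal_exposure, 1)

  sh <- small("shared", seed = 2)
  expect_identical(names(sh$truth$causal_exposure),
                   names(sh$truth$causal_outcome))
  expect_equal(sh$truth$wald_true,
               unname(sh$truth$causal_outcome /
                        sh$truth$causal_exposure))

  ss <- small("secondary_shared", seed = 3)
  expect_length(ss$truth$causal_exposure, 2)
  expect_length(ss$truth$causal_outcome, 1)
  # exactly the secondary (weaker) exposure signal is shared
  expect_identical(names(ss$truth$causal_outcome),
                   names(ss$truth$causal_exposure)[2])
  v <- ss$truth$causal_exposure *
    panel_sd_for(ss, names(ss$truth$causal_exposure))
  expect_gt(v[1]^2, v[2]^2) # primary explains more variance

  di <- small("distinct", seed = 4)
  a <- names(di$truth$causal_exposure)
  b <- names(di$truth$causal_outcome)
  expect_false(a == b)
  expect_lt(di$ld[a, b]^2, 0.01)
})

test_that("unattainable distinct-causal LD cap raises a generation error", {
  expect_error(
    make_scenario("distinct", n_snp = 8, n_ref = 150,
                  maf_range = c(0.3, 0.32), ld_decay = 0.999,
                  region_span = 1e4, distinct_r2_cap = 1e-4, seed = 5),
    class = "mrcoco_generation_error")
})

test_that("scenarios are deterministic and carry consistent datasets", {
  a <- small("shared", n_profiles = 3, seed = 9)
  b <- small("shared", n_profiles = 3, seed = 9)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$outcome, b$outcome)
  expect_length(a$exposures, 3)
  expect_length(a$truth$profile_multipliers, 3)
  # causal effect scales with the profile multiplier: profile-2 top signal
  cs <- names(a$truth$causal_exposure)
  expect_equal(trait_type(a$outcome), "case_control")
  expect_true(all(sapply(a$exposures, function(e) cs %in% e$snp)))
})

test_that("shared scenarios put a genome-wide signal under both traits", {
  sc <- make_scenario("shared", n_snp = 300, n_ref = 200,
                      outcome_hsq = 0.02, seed = 10)
  cs <- names(sc$truth$causal_exposure)
  expect_lt(sc$exposures[[1]]$p[match(cs, sc$exposures[[1]]$snp)], 5e-8)
  expect_lt(sc$outcome$p[match(cs, sc$outcome$snp)], 5e-8)
})

test_that("multi-tissue fixture respects degenerate probabilities", {
  ids <- sprintf("v%02d", 1:20)
  all_sig <- make_multitissue_fixture(ids, n_tissues = 6,
                                      share_probability = 1,
                                      absent_probability = 0,
                                      presence_probability = 1, seed = 1)
  expect_true(all(all_sig$p < 5e-8))
  expect_equal(nrow(all_sig), 120)

  none_sig <- make_multitissue_fixture(ids, n_tissues = 6,
                                       share_probability = 0,
                                       absent_probability = 0,
                                       presence_probability = 1, seed = 2)
  expect_true(all(none_sig$p >= 5e-8))
})

test_that("tissue-sharing rate matches the binomial oracle", {
  ids <- sprintf("v%03d", 1:200)
  tab <- make_multitissue_fixture(ids, n_tissues = 50,
                                  share_probability = 0.64, seed = 3)
  prop <- mean(tab$p < 5e-8)
  se <- sqrt(0.64 * 0.36 / nrow(tab))
  expect_lt(abs(prop - 0.64), 3 * se)
  # some SNPs absent entirely, exercising proxy lookup downstream
  expect_lt(dplyr::n_distinct(tab$snp), 200)
})
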