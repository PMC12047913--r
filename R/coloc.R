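# Bayesian colocalisation via Wakefield approximate Bayes factors.

#' Colocalisation priors
#'
#' Per-SNP prior probabilities: `p1`/`p2` that a variant is causal for
#' trait 1/trait 2 alone, `p12` that it is causal for both. The defaults
#' (1e-5, 1e-5, 1e-7) are calibrated for windows of roughly 1,600 variants,
#' giving about 0.016 expected causal variants per trait per window (see
#' [expected_signal_counts()]).
#'
#' @param p1,p2,p12 Per-SNP priors; must satisfy
#'   `0 < p12 <= min(p1, p2) < 1`.
#' @return A list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-5, p2 = 1e-5, p12 = 1e-7) {
  assert_scalar_prob(p1, "p1")
  assert_scalar_prob(p2, "p2")
  assert_scalar_prob(p12, "p12")
  if (p12 > min(p1, p2)) {
    param_error("`p12` must not exceed min(p1, p2)")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a `N(0, prior_sd^2)`
#' effect prior, with `z = beta/se` and `W = prior_sd^2`:
#' `labf = 0.5 * (log(se^2 / (se^2 + W)) + z^2 * W / (se^2 + W))`.
#'
#' @param beta,se Estimate and standard error (vectorised; `se > 0`).
#' @param prior_sd Prior SD of the true effect; 0.2 is the conventional
#'   choice for standardised quantitative traits and 0.15 on the log-odds
#'   scale for case-control traits.
#' @return Numeric vector of log approximate Bayes factors.
#' @examples
#' wakefield_labf(0.5, 0.1, 0.2) # z = 5
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) param_error("`se` must be > 0")
  if (any(prior_sd <= 0)) param_error("`prior_sd` must be > 0")
  z2 <- (beta / se)^2
  W <- prior_sd^2
  v <- se^2
  0.5 * (log(v / (v + W)) + z2 * W / (v + W))
}

default_prior_sd <- function(ss) {
  if (trait_type(ss) == "case_control") {
    0.15
  } else {
    0.2 * (attr(ss, "trait_sd") %||% 1)
  }
}

#' Posterior probabilities of the five colocalisation hypotheses
#'
#' Combines per-variant log ABFs for two traits over one harmonised region
#' into posteriors for H0 (no causal variant for either trait), H1/H2
#' (causal for one trait only), H3 (both, different variants) and H4 (both,
#' same variant). With `L1 = sum(exp(labf1))`, `L2 = sum(exp(labf2))` and
#' `L12 = sum(exp(labf1 + labf2))`, the unnormalised weights are `1`,
#' `p1*L1`, `p2*L2`, `p1*p2*(L1*L2 - L12)` and `p12*L12`; everything is
#' accumulated in log space so |labf| in the hundreds is safe. A single-SNP
#' region has no distinct-variant configuration, so H3 is exactly 0.
#'
#' @param labf1,labf2 Equal-length vectors of log ABFs on a common variant
#'   ordering.
#' @param priors A [coloc_priors()].
#' @return One-row tibble of class `coloc_result`: `h0`..`h4`, `n_snps`.
#' @export
coloc_posteriors <- function(labf1, labf2, priors = coloc_priors()) {
  stopifnot(length(labf1) == length(labf2))
  n <- length(labf1)
  if (n == 0) param_error("empty labf vectors")
  lL1 <- logsumexp(labf1)
  lL2 <- logsumexp(labf2)
  lL12 <- logsumexp(labf1 + labf2)
  lu <- c(h0 = 0,
          h1 = log(priors$p1) + lL1,
          h2 = log(priors$p2) + lL2,
          h3 = -Inf,
          h4 = log(priors$p12) + lL12)
  if (n > 1) {
    # log(L1*L2 - L12), with L1*L2 >= L12 always (all terms positive).
    diff <- -expm1(lL12 - lL1 - lL2)
    if (diff > 0) {
      lu["h3"] <- log(priors$p1) + log(priors$p2) + lL1 + lL2 + log(diff)
    }
  }
  h <- exp(lu - logsumexp(lu))
  out <- tibble::tibble(h0 = h[["h0"]], h1 = h[["h1"]], h2 = h[["h2"]],
                        h3 = h[["h3"]], h4 = h[["h4"]], n_snps = n)
  structure(out, class = c("coloc_result", class(out)), priors = priors)
}

#' Colocalise two summary datasets over a shared region
#'
#' Convenience wrapper: aligns the two datasets on their common variants
#' (assumed already harmonised to the same effect alleles), computes
#' Wakefield log ABFs for each side, and calls [coloc_posteriors()].
#' Effect priors default to 0.2 x trait SD for quantitative traits and 0.15
#' for case-control traits.
#'
#' @param ds1,ds2 `sumstats` tibbles.
#' @param priors A [coloc_priors()].
#' @param prior_sd1,prior_sd2 Effect-prior SDs; `NULL` = trait-type
#'   default.
#' @return A `coloc_result` (see [coloc_posteriors()]).
#' @export
coloc_abf <- function(ds1, ds2, priors = coloc_priors(),
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  common <- intersect(ds1$snp, ds2$snp)
  if (length(common) == 0) {
    abort("no shared variants to colocalise", class = "mrcoco_empty_dataset")
  }
  a <- ds1[match(common, ds1$snp), , drop = FALSE]
  b <- ds2[match(common, ds2$snp), , drop = FALSE]
  l1 <- wakefield_labf(a$beta, a$se, prior_sd1 %||% default_prior_sd(ds1))
  l2 <- wakefield_labf(b$beta, b$se, prior_sd2 %||% default_prior_sd(ds2))
  coloc_posteriors(l1, l2, priors)
}

#' Expected causal-variant counts implied by colocalisation priors
#'
#' Linear expectations over a window of `n_snps` variants: trait-1 count
#' `n_snps * (p1 + p12)`, trait-2 count `n_snps * (p2 + p12)`, shared count
#' `n_snps * p12`. Useful for checking that priors are sensible for the
#' window size (the defaults give ~0.016 and ~1.6e-4 at 1,621 variants).
#'
#' @param priors A [coloc_priors()].
#' @param n_snps Number of variants in the window (>= 1).
#' @return One-row tibble: `e_trait1`, `e_trait2`, `e_shared`.
#' @examples
#' expected_signal_counts(coloc_priors(), 1621)
#' @export
expected_signal_counts <- function(priors, n_snps) {
  if (!is.numeric(n_snps) || n_snps < 1) param_error("`n_snps` must be >= 1")
  tibble::tibble(e_trait1 = n_snps * (priors$p1 + priors$p12),
                 e_trait2 = n_snps * (priors$p2 + priors$p12),
                 e_shared = n_snps * priors$p12)
}
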