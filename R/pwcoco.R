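#' Pairwise conditional colocalisation of two summary datasets
#'
#' Decomposes each trait's regional association into conditionally
#' independent signals with [cojo_stepwise()]; for a trait with `k > 1`
#' signals, builds `k` conditional datasets (each signal's association
#' conditioned on all the *other* selected signals) alongside the marginal
#' dataset. Every cross-trait pair of (marginal + conditional) datasets is
#' then colocalised with [coloc_abf()], and the evidence for a shared
#' variant is summarised by the maximum H4 over pairs. With one signal per
#' trait this reduces exactly to a single marginal x marginal
#' colocalisation.
#'
#' @param exposure,outcome `sumstats` tibbles harmonised to the same
#'   effect alleles over one region.
#' @param ld LD correlation matrix covering the region.
#' @param priors A [coloc_priors()].
#' @param p_entry Stepwise entry threshold (default 5e-8).
#' @param collinearity_r2 COJO collinearity mask threshold (default 0.9).
#' @param ref_eaf Optional reference allele frequencies (see
#'   [cojo_conditional()]).
#' @param h4_threshold Posterior threshold declaring colocalisation
#'   (default 0.8).
#' @param prior_sd_exposure,prior_sd_outcome ABF effect-prior SDs; `NULL`
#'   uses the trait-type defaults (0.2 x SD quantitative, 0.15 log-odds).
#' @return An object of class `pwcoco_result`: list with `pairs` (tibble of
#'   `exposure_version`, `outcome_version`, `h0`..`h4`, `n_snps`),
#'   `max_h4`, `colocalises` (`max_h4 > h4_threshold`),
#'   `signals_exposure`, `signals_outcome` (stepwise tibbles), `priors`.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' sc <- make_scenario("shared", n_snp = 300, n_ref = 200, seed = 7)
#' res <- pwcoco(sc$exposures[[1]], sc$outcome, sc$ld)
#' glance(res)
#' @export
pwcoco <- function(exposure, outcome, ld, priors = coloc_priors(),
                   p_entry = 5e-8, collinearity_r2 = 0.9, ref_eaf = NULL,
                   h4_threshold = 0.8,
                   prior_sd_exposure = NULL, prior_sd_outcome = NULL) {
  common <- intersect(exposure$snp, outcome$snp)
  if (length(common) == 0) {
    abort("no shared variants between the two datasets",
          class = "mrcoco_empty_dataset")
  }
  e <- restat(exposure[match(common, exposure$snp), , drop = FALSE],
              exposure)
  o <- restat(outcome[match(common, outcome$snp), , drop = FALSE], outcome)
  psd_e <- prior_sd_exposure %||% default_prior_sd(exposure)
  psd_o <- prior_sd_outcome %||% default_prior_sd(outcome)

  versions <- function(ss) {
    sel <- cojo_stepwise(ss, ld, p_entry = p_entry,
                         collinearity_r2 = collinearity_r2,
                         ref_eaf = ref_eaf)
    v <- list(marginal = ss)
    if (nrow(sel) > 1) {
      for (i in seq_len(nrow(sel))) {
        others <- sel$snp[-i]
        v[[paste0("signal_", sel$snp[i])]] <-
          cojo_conditional(ss, ld, others,
                           ref_eaf = ref_eaf,
                           collinearity_r2 = collinearity_r2)
      }
    }
    list(versions = v, signals = sel)
  }
  ve <- versions(e)
  vo <- versions(o)

  grid <- tidyr::expand_grid(exposure_version = names(ve$versions),
                             outcome_version = names(vo$versions))
  pairs <- purrr::pmap_dfr(grid, function(exposure_version,
                                          outcome_version) {
    post <- coloc_abf(ve$versions[[exposure_version]],
                      vo$versions[[outcome_version]],
                      priors = priors,
                      prior_sd1 = psd_e, prior_sd2 = psd_o)
    dplyr::bind_cols(tibble::tibble(exposure_version = exposure_version,
                                    outcome_version = outcome_version),
                     tibble::as_tibble(post))
  })
  max_h4 <- max(pairs$h4)
  structure(list(pairs = pairs, max_h4 = max_h4,
                 colocalises = max_h4 > h4_threshold,
                 signals_exposure = ve$signals,
                 signals_outcome = vo$signals,
                 priors = priors, h4_threshold = h4_threshold),
            class = "pwcoco_result")
}

#' @export
print.pwcoco_result <- function(x, ...) {
  cat(sprintf(
    "<pwcoco_result> %d pair(s); signals: %d exposure, %d outcome; max H4 = %.3f (%scolocalises at H4 > %.2f)\n",
    nrow(x$pairs), nrow(x$signals_exposure), nrow(x$signals_outcome),
    x$max_h4, if (x$colocalises) "" else "does not ", x$h4_threshold))
  print(x$pairs)
  invisible(x)
}
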