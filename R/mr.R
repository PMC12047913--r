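# Single-SNP Wald-ratio MR with delta-method SEs, OR scaling and BH-FDR.

#' Wald-ratio causal estimate with delta-method standard error
#'
#' `wald_beta = beta_out / beta_exp`. The first-order delta-method SE is
#' `se_out / |beta_exp|`; the second-order form adds the exposure
#' uncertainty: `sqrt(se_out^2/beta_exp^2 +
#' beta_out^2 * se_exp^2 / beta_exp^4)`. The p-value is two-sided normal on
#' `wald_beta / wald_se`.
#'
#' @param beta_exp,se_exp Exposure association and SE (per effect allele,
#'   SD units).
#' @param beta_out,se_out Outcome association and SE (log odds).
#' @param se_order `"first"` (default) or `"second"` delta-method order.
#' @return Tibble with `wald_beta`, `wald_se`, `pvalue` (vectorised).
#' @examples
#' wald_ratio(0.5, 0.05, -0.06, 0.02)
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  if (any(beta_exp == 0)) {
    param_error("`beta_exp` must be nonzero for a Wald ratio")
  }
  wald_beta <- beta_out / beta_exp
  wald_se <- if (se_order == "first") {
    se_out / abs(beta_exp)
  } else {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  }
  tibble::tibble(wald_beta = wald_beta, wald_se = wald_se,
                 pvalue = z_to_p(wald_beta / wald_se))
}

#' Odds ratio with confidence interval from a log-odds estimate
#'
#' @param wald_beta Log odds ratio (per SD of the exposure).
#' @param wald_se Its standard error (> 0).
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return Tibble with `or_point`, `ci_low`, `ci_high`.
#' @examples
#' or_with_ci(-0.1165, 0.0229)
#' @export
or_with_ci <- function(wald_beta, wald_se, alpha = 0.05) {
  if (any(wald_se <= 0)) param_error("`wald_se` must be > 0")
  z <- qnorm(1 - alpha / 2)
  tibble::tibble(or_point = exp(wald_beta),
                 ci_low = exp(wald_beta - z * wald_se),
                 ci_high = exp(wald_beta + z * wald_se))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} m * p_(j) / j` mapped back to input order and
#' capped at 1.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values in input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) {
    return(numeric())
  }
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    param_error("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Transcriptome-wide Wald-ratio MR screen
#'
#' Runs instrument selection and Wald-ratio estimation for every gene x
#' profile exposure against every outcome, then applies Benjamini-Hochberg
#' correction. By default the correction family is per outcome (each
#' outcome GWAS is its own screen); set `fdr_family = "global"` to correct
#' across all outcomes jointly.
#'
#' @param exposures Named list of exposure `sumstats`, one per gene x
#'   profile; each must carry a `gene` entry in `gene_map`.
#' @param outcomes Named list of outcome `sumstats`.
#' @param genes Gene annotation tibble (`gene`, `chr`, `start`, `end`).
#' @param gene_map Named character vector mapping exposure names to gene
#'   ids.
#' @param ld Either one LD matrix or a named list of matrices keyed by
#'   gene id.
#' @param config An [instrument_config()].
#' @param fdr_level Significance level on the q-value (default 0.05).
#' @param fdr_family `"per_outcome"` or `"global"`.
#' @param se_order Delta-method order for [wald_ratio()].
#' @return A tibble of class `mr_screen` with one row per gene x profile x
#'   outcome for which an instrument was found: identification columns,
#'   instrument statistics, `wald_beta`, `wald_se`, `pvalue`, `or_point`,
#'   `ci_low`, `ci_high`, `fdr_q`, `significant`. Empty (with a warning)
#'   when no instruments survive.
#' @export
mr_screen <- function(exposures, outcomes, genes, gene_map, ld,
                      config = instrument_config(), fdr_level = 0.05,
                      fdr_family = c("per_outcome", "global"),
                      se_order = c("first", "second")) {
  fdr_family <- match.arg(fdr_family)
  se_order <- match.arg(se_order)
  stopifnot(length(exposures) == 0 || !is.null(names(exposures)),
            !is.null(names(outcomes)))
  rows <- list()
  for (out_name in names(outcomes)) {
    outcome <- outcomes[[out_name]]
    for (exp_name in names(exposures)) {
      g_id <- unname(gene_map[[exp_name]])
      gene <- genes[genes$gene == g_id, , drop = FALSE]
      ld_g <- if (is.list(ld)) ld[[g_id]] else ld
      inst <- select_instrument(exposures[[exp_name]], outcome, gene, ld_g,
                                config)
      if (is.null(inst)) next
      w <- wald_ratio(inst$beta_exp, inst$se_exp, inst$beta_out,
                      inst$se_out, se_order)
      orci <- or_with_ci(w$wald_beta, w$wald_se)
      rows[[length(rows) + 1]] <-
        dplyr::bind_cols(inst, w, orci,
                         tibble::tibble(outcome = out_name))
    }
  }
  if (length(rows) == 0) {
    warn("mr_screen: no instruments found; returning empty result")
    res <- tibble::tibble(gene = character(), profile = character(),
                          outcome = character(), snp = character(),
                          wald_beta = numeric(), wald_se = numeric(),
                          pvalue = numeric(), or_point = numeric(),
                          ci_low = numeric(), ci_high = numeric(),
                          fdr_q = numeric(), significant = logical())
    return(structure(res, class = c("mr_screen", class(res))))
  }
  res <- dplyr::bind_rows(rows)
  res <- if (fdr_family == "per_outcome") {
    res |>
      dplyr::group_by(.data$outcome) |>
      dplyr::mutate(fdr_q = bh_fdr(.data$pvalue)) |>
      dplyr::ungroup()
  } else {
    dplyr::mutate(res, fdr_q = bh_fdr(.data$pvalue))
  }
  res <- dplyr::mutate(res, significant = .data$fdr_q < fdr_level)
  structure(res, class = c("mr_screen", class(res)))
}
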