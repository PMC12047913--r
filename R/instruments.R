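# cis-instrument selection: window filter, p threshold, LD clumping,
# F-statistic and Steiger direction filters.

#' Instrument-selection configuration
#'
#' Defaults follow standard cis-MR practice: variants inside the gene body
#' +/- 500 kb, association p < 5e-8, greedy LD clumping at r^2 < 0.001
#' within a 10 kb window, weak instruments excluded at F < 10, and Steiger
#' direction filtering enabled.
#'
#' @param cis_window Window in bp either side of the gene body.
#' @param p_threshold Exposure association threshold (strict `<`).
#' @param clump_r2 LD r^2 above which a variant is pruned against an index.
#' @param clump_window Clumping window in bp.
#' @param f_min Minimum single-SNP F-statistic.
#' @param steiger Apply the Steiger direction filter?
#' @param palindrome_window Allele-frequency ambiguity half-width used when
#'   harmonising (see [harmonise()]).
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(cis_window = 5e5, p_threshold = 5e-8,
                              clump_r2 = 0.001, clump_window = 1e4,
                              f_min = 10, steiger = TRUE,
                              palindrome_window = 0.08) {
  if (cis_window < 0 || clump_window < 0 || f_min < 0) {
    param_error("windows and f_min must be non-negative")
  }
  assert_scalar_prob(p_threshold, "p_threshold")
  assert_scalar_prob(clump_r2, "clump_r2")
  structure(list(cis_window = cis_window, p_threshold = p_threshold,
                 clump_r2 = clump_r2, clump_window = clump_window,
                 f_min = f_min, steiger = steiger,
                 palindrome_window = palindrome_window),
            class = "instrument_config")
}

#' Restrict summary statistics to a gene's cis window
#'
#' Keeps records with position in the closed interval
#' `[gene start - window, gene end + window]` on the gene's chromosome.
#'
#' @param x A `sumstats` tibble.
#' @param gene One-row data frame with `gene`, `chr`, `start`, `end`.
#' @param window Flank size in bp (default 500 kb).
#' @return The filtered `sumstats` tibble (possibly empty).
#' @export
cis_filter <- function(x, gene, window = 5e5) {
  stopifnot(nrow(gene) == 1)
  keep <- x$chr == as.character(gene$chr) &
    x$pos >= gene$start - window & x$pos <= gene$end + window
  restat(x[keep, , drop = FALSE], x)
}

#' Greedy LD clumping of associated variants
#'
#' Repeatedly takes the lowest-p unassigned variant as an index and removes
#' every unassigned variant that lies within `window_bp` of it *and* has
#' `r^2 >= r2_thresh` with it (both conditions must hold for pruning).
#' Ties on p are broken by smaller position, then lexicographic id.
#'
#' @param x A `sumstats` tibble (typically already thresholded on p).
#' @param ld LD correlation matrix covering every variant in `x`.
#' @param r2_thresh Pruning r^2 threshold.
#' @param window_bp Pruning window in bp.
#' @return Character vector of index-variant ids, ordered by ascending p.
#' @export
ld_clump <- function(x, ld, r2_thresh = 0.001, window_bp = 1e4) {
  if (nrow(x) == 0) {
    return(character())
  }
  missing_ld <- setdiff(x$snp, rownames(ld))
  if (length(missing_ld) > 0) {
    data_error(sprintf("variant(s) missing from LD matrix: %s",
                       paste(head(missing_ld, 5), collapse = ", ")))
  }
  ord <- order(x$p, x$pos, x$snp)
  snp <- x$snp[ord]
  pos <- x$pos[ord]
  r2 <- ld[snp, snp, drop = FALSE]^2
  assigned <- rep(FALSE, length(snp))
  keep <- character()
  for (i in seq_along(snp)) {
    if (assigned[i]) next
    keep <- c(keep, snp[i])
    prune <- !assigned & abs(pos - pos[i]) <= window_bp & r2[i, ] >= r2_thresh
    assigned[prune] <- TRUE
    assigned[i] <- TRUE
  }
  keep
}

#' Single-SNP instrument F-statistic
#'
#' For a one-variant instrument the F-statistic equals the squared z-score
#' of the exposure association, `(beta/se)^2`.
#'
#' @param beta,se Effect estimate and standard error (vectorised).
#' @return Numeric vector of F-statistics.
#' @examples
#' f_statistic(0.3, 0.03) # 100
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) param_error("`se` must be > 0")
  (beta / se)^2
}

#' Steiger directionality test for a candidate instrument
#'
#' Compares the variance in the exposure versus the outcome explained by a
#' variant: `r^2 = z^2 / (z^2 + n_eff - 2)` with `z = beta/se`, where
#' `n_eff` is the sample size for quantitative traits and
#' `4/(1/n_case + 1/n_control)` for case-control traits. The variant passes
#' (supports the exposure -> outcome direction) iff
#' `r2_exposure > r2_outcome`, strictly; ties fail.
#'
#' @param exposure,outcome `sumstats` tibbles (or row subsets) with aligned
#'   variants; vectorised over rows.
#' @return Tibble with `snp`, `r2_exposure`, `r2_outcome`, `steiger_pass`.
#' @export
steiger_test <- function(exposure, outcome) {
  stopifnot(nrow(exposure) == nrow(outcome))
  r2_of <- function(ss) {
    ne <- effective_n(ss)
    if (any(!is.finite(ne))) data_error("missing sample size for Steiger test")
    z2 <- (ss$beta / ss$se)^2
    z2 / (z2 + ne - 2)
  }
  tibble::tibble(snp = exposure$snp,
                 r2_exposure = r2_of(exposure),
                 r2_outcome = r2_of(outcome),
                 steiger_pass = r2_of(exposure) > r2_of(outcome))
}

#' Select the cis instrument for one gene x profile against one outcome
#'
#' Applies the full filter chain: harmonisation, cis-window restriction,
#' exposure p-value threshold, greedy LD clumping, F-statistic exclusion,
#' and Steiger direction filtering; the lowest-p survivor becomes the
#' gene's (single-SNP) instrument. Every exclusion is recorded with its
#' reason in the `exclusions` attribute of the result.
#'
#' @param exposure Exposure (eQTL) `sumstats` for one gene x profile.
#' @param outcome Outcome `sumstats`.
#' @param gene One-row gene annotation (`gene`, `chr`, `start`, `end`).
#' @param ld LD matrix covering the cis region.
#' @param config An [instrument_config()].
#' @return A one-row tibble (`gene`, `profile`, `snp`, exposure and outcome
#'   effect columns, `f_stat`, `r2_exposure`, `r2_outcome`,
#'   `steiger_pass`), or `NULL` when no variant survives. The `exclusions`
#'   attribute is a tibble of `snp`, `reason`.
#' @export
select_instrument <- function(exposure, outcome, gene, ld,
                              config = instrument_config()) {
  excl <- tibble::tibble(snp = character(), reason = character())
  note <- function(ids, reason) {
    if (length(ids) > 0) {
      excl <<- dplyr::bind_rows(excl,
                                tibble::tibble(snp = ids, reason = reason))
    }
  }
  done <- function(row) {
    if (!is.null(row)) attr(row, "exclusions") <- excl
    row
  }

  h <- tryCatch(harmonise(exposure, outcome, config$palindrome_window),
                mrcoco_empty_dataset = function(e) NULL)
  if (is.null(h)) {
    note(exposure$snp, "harmonisation_empty")
    return(done(NULL))
  }
  note(h$exclusions$snp, paste0("harmonise_", h$exclusions$reason))
  e <- cis_filter(h$exposure, gene, config$cis_window)
  note(setdiff(h$exposure$snp, e$snp), "outside_cis_window")
  sig <- e[e$p < config$p_threshold, , drop = FALSE]
  note(setdiff(e$snp, sig$snp), "above_p_threshold")
  if (nrow(sig) == 0) {
    return(done(NULL))
  }
  idx <- ld_clump(sig, ld, config$clump_r2, config$clump_window)
  note(setdiff(sig$snp, idx), "clumped")
  cand_e <- restat(sig[match(idx, sig$snp), , drop = FALSE], e)
  cand_o <- h$outcome[match(idx, h$outcome$snp), , drop = FALSE]

  f <- f_statistic(cand_e$beta, cand_e$se)
  weak <- f < config$f_min
  note(cand_e$snp[weak], "weak_instrument_f")
  st <- steiger_test(cand_e, cand_o)
  if (config$steiger) {
    note(cand_e$snp[!weak & !st$steiger_pass], "steiger_fail")
  }
  ok <- !weak & (if (config$steiger) st$steiger_pass else TRUE)
  if (!any(ok)) {
    return(done(NULL))
  }
  best <- which(ok)[which.min(cand_e$p[ok])]
  row <- tibble::tibble(
    gene = gene$gene, profile = attr(exposure, "trait_id") %||% "exposure",
    snp = cand_e$snp[best], chr = cand_e$chr[best], pos = cand_e$pos[best],
    ea = cand_e$ea[best], nea = cand_e$nea[best],
    eaf = cand_e$eaf[best],
    beta_exp = cand_e$beta[best], se_exp = cand_e$se[best],
    p_exp = cand_e$p[best], n_exp = cand_e$n[best],
    beta_out = cand_o$beta[best], se_out = cand_o$se[best],
    p_out = cand_o$p[best],
    f_stat = f[best], r2_exposure = st$r2_exposure[best],
    r2_outcome = st$r2_outcome[best], steiger_pass = st$steiger_pass[best])
  alternates <- cand_e$snp[ok][order(cand_e$p[ok])][-1]
  note(alternates, "alternate_index_snp")
  done(row)
}
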