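# Conditional and joint analysis of summary statistics against an LD
# reference (the COJO step of pairwise conditional colocalisation).
#
# All conditioning is exact summary-statistics joint least squares: the
# centred X'X is reconstructed as S[j,k] = (n-1) * r[j,k] * sd_j * sd_k
# (sd from reference allele frequencies under Hardy-Weinberg, or supplied
# genotype variances), X'y from the marginal betas via S[j,y] = S[j,j] *
# beta_j, and the phenotypic sum of squares from the median per-SNP implied
# value Syy_j = S[j,j] * (beta_j^2 + se_j^2 * (n - 2)). With in-sample LD
# and variances this reproduces genotype-level multiple regression
# coefficients and SEs exactly.

cojo_stats <- function(ss, ld, ref_eaf = NULL, var_x = NULL,
                       freq_mismatch = 0.2) {
  ids <- ss$snp
  missing_ld <- setdiff(ids, rownames(ld))
  if (length(missing_ld) > 0) {
    data_error(sprintf("variant(s) missing from LD matrix: %s",
                       paste(head(missing_ld, 5), collapse = ", ")))
  }
  masked <- tibble::tibble(snp = character(), reason = character())
  f <- ss$eaf
  if (!is.null(ref_eaf)) {
    fr <- unname(ref_eaf[ids])
    bad <- is.na(fr) | abs(fr - f) > freq_mismatch
    if (any(bad)) {
      warn(sprintf(
        "%d SNP(s) masked for reference/summary allele-frequency mismatch > %.2f",
        sum(bad), freq_mismatch))
      masked <- tibble::tibble(snp = ids[bad], reason = "freq_mismatch")
      ss <- ss[!bad, , drop = FALSE]
      ids <- ss$snp
      fr <- fr[!bad]
    }
    f <- fr
  }
  n <- median(ss$n)
  sd_x <- if (!is.null(var_x)) {
    sqrt(unname(var_x[ids]))
  } else {
    sqrt(2 * f * (1 - f))
  }
  sjj <- (n - 1) * sd_x^2
  syy <- median(sjj * (ss$beta^2 + ss$se^2 * (n - 2)))
  list(ss = ss, ids = ids, n = n, sd_x = sd_x, sjj = sjj,
       sjy = sjj * ss$beta, syy = syy,
       r = ld[ids, ids, drop = FALSE], masked = masked)
}

# Cross-products S[a, b] for id-index vectors a, b.
s_block <- function(st, a, b) {
  (st$n - 1) * st$r[a, b, drop = FALSE] *
    outer(st$sd_x[a], st$sd_x[b])
}

#' Conditional association estimates given a set of conditioning variants
#'
#' For every target variant `t` outside the conditioning set `C`, fits the
#' joint model `{t} + C` from summary statistics and the LD reference and
#' reports `t`'s coefficient, SE and p-value — the association of `t`
#' conditional on `C`. Conditioning variants themselves and variants in LD
#' `r^2 >` `collinearity_r2` with any conditioning variant are masked
#' (dropped, with reasons in the `masked` attribute). An empty `C` returns
#' the marginal dataset unchanged.
#'
#' @param ss A `sumstats` tibble for the region.
#' @param ld LD correlation matrix covering the region.
#' @param cond_snps Character vector of conditioning variant ids (subset of
#'   `ss$snp`).
#' @param ref_eaf Optional named vector of reference-panel allele
#'   frequencies; variants whose summary frequency differs by more than
#'   `freq_mismatch` are masked with a warning. `NULL` uses the summary
#'   frequencies.
#' @param var_x Optional named vector of genotype variances (overrides the
#'   Hardy-Weinberg `2f(1-f)`); pass in-sample variances to reproduce
#'   genotype-level regression exactly.
#' @param collinearity_r2 Mask threshold for LD with conditioning variants.
#' @param freq_mismatch Allele-frequency mismatch tolerance.
#' @return A `sumstats` tibble of the unmasked targets with `beta`, `se`,
#'   `p` replaced by conditional values; attributes `conditioned_on` and
#'   `masked`.
#' @export
cojo_conditional <- function(ss, ld, cond_snps, ref_eaf = NULL,
                             var_x = NULL, collinearity_r2 = 0.9,
                             freq_mismatch = 0.2) {
  if (length(cond_snps) == 0) {
    out <- restat(ss, ss)
    attr(out, "conditioned_on") <- character()
    attr(out, "masked") <- tibble::tibble(snp = character(),
                                          reason = character())
    return(out)
  }
  bad_c <- setdiff(cond_snps, ss$snp)
  if (length(bad_c) > 0) {
    data_error(sprintf("conditioning variant(s) not in dataset: %s",
                       paste(bad_c, collapse = ", ")))
  }
  st <- cojo_stats(ss, ld, ref_eaf, var_x, freq_mismatch)
  cond_snps <- intersect(cond_snps, st$ids)
  ci <- match(cond_snps, st$ids)
  k <- length(ci)

  s_cc <- s_block(st, ci, ci)
  M <- tryCatch(solve(s_cc), error = function(e) {
    abort(paste0("conditioning set is singular (collinear variants); ",
                 "lower `collinearity_r2` or drop one of: ",
                 paste(cond_snps, collapse = ", ")),
          class = "mrcoco_conditioning_error")
  })
  alpha_c <- drop(M %*% st$sjy[ci])
  base_rss <- st$syy - sum(st$sjy[ci] * alpha_c)

  ti <- setdiff(seq_along(st$ids), ci)
  r2_to_c <- apply(st$r[ti, ci, drop = FALSE]^2, 1, max)
  collinear <- r2_to_c > collinearity_r2
  masked <- dplyr::bind_rows(
    st$masked,
    tibble::tibble(snp = st$ids[ci], reason = "conditioning_variant"),
    tibble::tibble(snp = st$ids[ti][collinear],
                   reason = "collinear_with_conditioning"))
  ti <- ti[!collinear]
  s_tc <- s_block(st, ti, ci)
  u <- s_tc %*% M
  num <- st$sjy[ti] - drop(u %*% st$sjy[ci])
  den <- st$sjj[ti] - rowSums(u * s_tc)
  ok <- den > .Machine$double.eps * st$syy
  rss <- pmax(base_rss - num^2 / den, 0)
  df <- st$n - (k + 1) - 1
  se2 <- (rss / df) / den
  beta_c <- num / den
  if (any(!ok)) {
    masked <- dplyr::bind_rows(
      masked, tibble::tibble(snp = st$ids[ti][!ok],
                             reason = "degenerate_partial_variance"))
    ti <- ti[ok]
    beta_c <- beta_c[ok]
    se2 <- se2[ok]
  }
  out <- st$ss[ti, , drop = FALSE]
  out$beta <- unname(beta_c)
  out$se <- unname(sqrt(se2))
  out$p <- unname(z_to_p(beta_c / sqrt(se2)))
  out <- restat(out, ss)
  attr(out, "conditioned_on") <- cond_snps
  attr(out, "masked") <- masked
  out
}

#' Stepwise selection of conditionally independent signals
#'
#' Greedy forward model selection against the LD reference: start from the
#' sentinel (lowest marginal p) variant if it passes `p_entry`, then
#' repeatedly add the variant with the smallest conditional p-value below
#' `p_entry` that is not collinear with the selected set; stop when none
#' qualifies. Returns the selected variants with their joint-model
#' estimates.
#'
#' @inheritParams cojo_conditional
#' @param p_entry Entry threshold on the conditional p-value (default
#'   5e-8).
#' @param max_signals Safety cap on the number of selected signals.
#' @return Tibble with `snp`, `beta_joint`, `se_joint`, `p_joint` in
#'   selection order (zero rows for a null region).
#' @export
cojo_stepwise <- function(ss, ld, p_entry = 5e-8, collinearity_r2 = 0.9,
                          ref_eaf = NULL, var_x = NULL, max_signals = 10,
                          freq_mismatch = 0.2) {
  empty <- tibble::tibble(snp = character(), beta_joint = numeric(),
                          se_joint = numeric(), p_joint = numeric())
  if (nrow(ss) == 0) {
    return(empty)
  }
  sentinel <- ss$snp[order(ss$p, ss$pos, ss$snp)][1]
  if (min(ss$p) >= p_entry) {
    return(empty)
  }
  selected <- sentinel
  repeat {
    if (length(selected) >= max_signals) break
    cond <- cojo_conditional(ss, ld, selected, ref_eaf = ref_eaf,
                             var_x = var_x,
                             collinearity_r2 = collinearity_r2,
                             freq_mismatch = freq_mismatch)
    if (nrow(cond) == 0 || min(cond$p) >= p_entry) break
    selected <- c(selected,
                  cond$snp[order(cond$p, cond$pos, cond$snp)][1])
  }

  # Joint estimates for the final model.
  st <- cojo_stats(ss, ld, ref_eaf, var_x, freq_mismatch)
  ji <- match(selected, st$ids)
  s_jj <- s_block(st, ji, ji)
  M <- solve(s_jj)
  b <- drop(M %*% st$sjy[ji])
  rss <- max(st$syy - sum(st$sjy[ji] * b), 0)
  sigma2 <- rss / (st$n - length(ji) - 1)
  se <- sqrt(pmax(diag(M) * sigma2, 0))
  tibble::tibble(snp = selected, beta_joint = unname(b),
                 se_joint = unname(se), p_joint = unname(z_to_p(b / se)))
}
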