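#' Harmonise exposure and outcome summary statistics to a common scale
#'
#' Restricts both datasets to their shared variants and expresses the
#' outcome effects relative to the exposure's effect allele. Where the
#' outcome's alleles are recorded in the opposite orientation, the outcome
#' beta is negated and its allele frequency reflected; variant pairs whose
#' alleles cannot be reconciled are dropped. Palindromic variants (A/T, C/G)
#' carry no strand information in their labels, so they are retained only
#' when both allele frequencies fall outside the ambiguity band
#' `[0.5 - palindrome_window, 0.5 + palindrome_window]` and on the same side
#' of 0.5; otherwise they are dropped. The operation is idempotent, and the
#' same variants are excluded regardless of argument order.
#'
#' @param exposure,outcome `sumstats` tibbles sharing a variant-id
#'   namespace.
#' @param palindrome_window Half-width of the allele-frequency ambiguity
#'   band around 0.5 (default 0.08).
#' @return A list with elements `exposure`, `outcome` (aligned `sumstats`
#'   tibbles with identical variant order) and `exclusions` (tibble of
#'   `snp`, `reason`).
#' @examples
#' panel <- simulate_haplotype_panel(100, 20, seed = 1)
#' exp <- simulate_quant_sumstats(panel, c(rs00005 = 0.3), n = 500, seed = 2)
#' out <- simulate_quant_sumstats(panel, c(rs00005 = 0.1), n = 500, seed = 3)
#' h <- harmonise(exp, out)
#' nrow(h$exposure)
#' @export
harmonise <- function(exposure, outcome, palindrome_window = 0.08) {
  assert_scalar_prob(palindrome_window, "palindrome_window",
                     open_left = FALSE)
  common <- intersect(exposure$snp, outcome$snp)
  if (length(common) == 0) {
    abort("no shared variants between exposure and outcome",
          class = "mrcoco_empty_dataset")
  }
  e <- exposure[match(common, exposure$snp), , drop = FALSE]
  o <- outcome[match(common, outcome$snp), , drop = FALSE]
  dropped_ids <- setdiff(union(exposure$snp, outcome$snp), common)
  excl <- tibble::tibble(snp = dropped_ids,
                         reason = rep("not_in_both", length(dropped_ids)))

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  same <- e$ea == o$ea & e$nea == o$nea
  swapped <- e$ea == o$nea & e$nea == o$ea
  palindromic <- e$nea == comp[e$ea]

  # Flip outcome rows recorded against the opposite allele.
  flip <- swapped & !same
  o$beta[flip] <- -o$beta[flip]
  o$eaf[flip] <- 1 - o$eaf[flip]
  tmp <- o$ea[flip]
  o$ea[flip] <- o$nea[flip]
  o$nea[flip] <- tmp

  keep <- same | flip
  mismatch <- !keep
  w <- palindrome_window
  amb <- palindromic & keep &
    !(abs(e$eaf - 0.5) > w & abs(o$eaf - 0.5) > w &
        sign(e$eaf - 0.5) == sign(o$eaf - 0.5))
  keep <- keep & !amb

  excl <- dplyr::bind_rows(
    excl,
    tibble::tibble(snp = common[mismatch],
                   reason = rep("allele_mismatch", sum(mismatch))),
    tibble::tibble(snp = common[amb],
                   reason = rep("palindromic_ambiguous", sum(amb)))
  )
  if (!any(keep)) {
    abort("harmonisation removed all shared variants",
          class = "mrcoco_empty_dataset")
  }
  list(exposure = restat(e[keep, , drop = FALSE], exposure),
       outcome = restat(o[keep, , drop = FALSE], outcome),
       exclusions = excl)
}
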