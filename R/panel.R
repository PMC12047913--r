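#' Simulate a reference haplotype panel with Markov linkage disequilibrium
#'
#' Generates `2 * n_ref` binary haplotypes over `n_snp` variants using a
#' first-order Markov chain along the chromosome: the allele at each variant
#' is drawn conditionally on the previous variant so that the pair attains a
#' target Pearson correlation of `ld_decay` (capped at the maximum
#' correlation attainable for the two allele frequencies). Because the
#' variants are binary, correlation is exactly multiplicative along the
#' chain, so the population LD between variants `j` and `k` is the product
#' of the achieved adjacent correlations between them — a closed form that
#' [ld_from_panel()] can return directly.
#'
#' Allele labels are drawn from the strand-unambiguous pairs (A/G, A/C, T/G,
#' T/C and their reverses) so that synthetic studies exercise allele flips
#' rather than strand inference; palindromic handling is a concern of
#' [harmonise()] and is tested with explicit fixtures.
#'
#' @param n_ref Number of diploid reference individuals (the panel holds
#'   `2 * n_ref` haplotypes).
#' @param n_snp Number of variants.
#' @param maf_range Length-2 interval inside (0, 0.5] from which per-variant
#'   minor-allele frequencies are drawn uniformly.
#' @param ld_decay Target correlation between adjacent variants, in `[0, 1)`.
#' @param region_span Width of the region in base pairs; positions are drawn
#'   uniformly (without replacement where possible) and sorted.
#' @param chr Chromosome label.
#' @param start 1-based base-pair coordinate of the region start.
#' @param id_prefix Prefix for the generated variant ids (ids are
#'   `sprintf("%s%05d", id_prefix, 1:n_snp)`); give each simulated region a
#'   distinct prefix to keep ids globally unique in multi-region studies.
#' @param seed Integer seed; identical seeds give bit-identical panels.
#'
#' @return An object of class `haplotype_panel`: a list with
#'   * `haplotypes`: integer matrix (`2 * n_ref` rows, `n_snp` columns,
#'     entries 0/1 counting the effect allele), column names = variant ids;
#'   * `snps`: a tibble with `snp`, `chr`, `pos`, `ea`, `nea`, `maf_target`,
#'     `eaf` (empirical effect-allele frequency), `maf` (empirical minor
#'     allele frequency), and `adj_r` (achieved target correlation with the
#'     previous variant; `NA` for the first).
#' @examples
#' panel <- simulate_haplotype_panel(100, 50, seed = 1)
#' dim(panel$haplotypes)
#' @export
simulate_haplotype_panel <- function(n_ref, n_snp,
                                     maf_range = c(0.05, 0.5),
                                     ld_decay = 0.9,
                                     region_span = 1e6,
                                     chr = "1", start = 1L,
                                     id_prefix = "rs",
                                     seed = NULL) {
  if (!is.numeric(n_snp) || n_snp < 1) param_error("`n_snp` must be >= 1.")
  if (!is.numeric(n_ref) || n_ref < 2) param_error("`n_ref` must be >= 2.")
  if (length(maf_range) != 2 || any(!is.finite(maf_range)) ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    param_error("`maf_range` must be an interval inside (0, 0.5].")
  }
  if (!is.numeric(ld_decay) || length(ld_decay) != 1 ||
      ld_decay < 0 || ld_decay >= 1) {
    param_error("`ld_decay` must lie in [0, 1).")
  }
  n_snp <- as.integer(n_snp)
  n_hap <- 2L * as.integer(n_ref)

  with_seed(seed, {
    maf <- runif(n_snp, maf_range[1], maf_range[2])
    pos <- if (region_span >= n_snp) {
      sort(sample.int(as.integer(region_span), n_snp)) + as.integer(start) - 1L
    } else {
      sort(sample.int(as.integer(region_span), n_snp, replace = TRUE)) +
        as.integer(start) - 1L
    }
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                      "G", "A", "C", "A", "G", "T", "C", "T"),
                    ncol = 2, byrow = TRUE)
    alle <- pairs[sample.int(nrow(pairs), n_snp, replace = TRUE), , drop = FALSE]

    hap <- matrix(0L, nrow = n_hap, ncol = n_snp)
    adj_r <- rep(NA_real_, n_snp)
    hap[, 1] <- rbinom(n_hap, 1L, maf[1])
    if (n_snp > 1) {
      for (j in 2:n_snp) {
        f1 <- maf[j - 1]
        f2 <- maf[j]
        r_max <- min(sqrt(f1 * (1 - f2) / (f2 * (1 - f1))),
                     sqrt(f2 * (1 - f1) / (f1 * (1 - f2))))
        r <- min(ld_decay, r_max)
        adj_r[j] <- r
        sd12 <- sqrt(f2 * (1 - f2))
        p_given1 <- f2 + r * sd12 * sqrt((1 - f1) / f1)
        p_given0 <- f2 - r * sd12 * sqrt(f1 / (1 - f1))
        p_cond <- ifelse(hap[, j - 1] == 1L, p_given1, p_given0)
        hap[, j] <- rbinom(n_hap, 1L, pmin(pmax(p_cond, 0), 1))
      }
    }

    ids <- sprintf("%s%05d", id_prefix, seq_len(n_snp))
    colnames(hap) <- ids
    eaf <- colMeans(hap)
    snps <- tibble::tibble(
      snp = ids, chr = as.character(chr), pos = as.integer(pos),
      ea = alle[, 1], nea = alle[, 2],
      maf_target = maf, eaf = eaf, maf = pmin(eaf, 1 - eaf),
      adj_r = adj_r
    )
    structure(list(haplotypes = hap, snps = snps),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d SNPs, chr %s:%d-%d\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              x$snps$chr[1], min(x$snps$pos), max(x$snps$pos)))
  invisible(x)
}

#' Linkage-disequilibrium matrix of a haplotype panel
#'
#' `method = "empirical"` returns the Pearson correlation of allele counts
#' across the panel's haplotypes. `method = "markov"` returns the exact
#' population correlation implied by the panel's Markov construction
#' (products of achieved adjacent correlations), which is free of
#' finite-panel noise and full rank — the reference used by the analytic
#' summary-statistics simulator.
#'
#' Monomorphic variants have no defined correlation; their rows/columns are
#' set to 0 off-diagonal (diagonal 1) with a warning.
#'
#' @param panel A [haplotype_panel][simulate_haplotype_panel()].
#' @param method `"empirical"` or `"markov"`.
#' @return A symmetric numeric matrix with unit diagonal and variant ids as
#'   dimnames.
#' @examples
#' panel <- simulate_haplotype_panel(200, 10, seed = 1)
#' ld <- ld_from_panel(panel)
#' ld[1:3, 1:3]
#' @export
ld_from_panel <- function(panel, method = c("empirical", "markov")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "haplotype_panel"))
  ids <- panel$snps$snp
  if (method == "markov") {
    # R[j, k] = prod of adjacent correlations between j and k; in log space
    # this is exp(-(a_k - a_j)) with a = cumsum(-log adj_r).
    r <- panel$snps$adj_r
    a <- c(0, cumsum(-log(pmax(r[-1], 0))))
    R <- exp(-abs(outer(a, a, "-")))
    R[is.nan(R)] <- 0 # blocks separated by adj_r = 0
    diag(R) <- 1
    dimnames(R) <- list(ids, ids)
    return(R)
  }
  H <- panel$haplotypes
  sds <- apply(H, 2, stats::sd)
  mono <- sds == 0
  if (any(mono)) {
    warn(sprintf("%d monomorphic SNP(s) in panel; LD set to 0: %s",
                 sum(mono), paste(head(ids[mono], 5), collapse = ", ")))
    H <- H[, !mono, drop = FALSE]
  }
  R <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (ncol(H) > 0) {
    R[!mono, !mono] <- stats::cor(H)
  }
  diag(R) <- 1
  R
}
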