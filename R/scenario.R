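# Ground-truth scenario generator: paired eQTL/GWAS regions under known
# causal configurations, the generative counterparts of the colocalisation
# hypotheses.

pick_near <- function(snps, eligible, target_pos) {
  cand <- which(eligible)
  if (length(cand) == 0) {
    abort("no eligible causal SNP in panel (need maf >= 0.1)",
          class = "mrcoco_generation_error")
  }
  cand[which.min(abs(snps$pos[cand] - target_pos))]
}

#' Simulate a complete colocalisation/MR scenario with known truth
#'
#' Builds one cis region: an LD reference, one exposure (gene expression)
#' summary dataset per cell-state profile, and one case-control outcome
#' dataset, under a named causal configuration:
#'
#' * `"shared"` — one causal variant drives both traits; the outcome log
#'   odds equal `wald_true` times the exposure effect (unless `outcome_hsq`
#'   overrides the outcome effect size), so the Wald ratio is recoverable.
#' * `"distinct"` — the exposure and outcome have different causal variants
#'   with pairwise LD below `distinct_r2_cap`.
#' * `"null"` — the exposure has a causal variant, the outcome has none.
#' * `"secondary_shared"` — the exposure carries two independent signals
#'   (primary stronger than secondary, LD below `secondary_r2_cap`); only
#'   the *secondary* is shared with the outcome. Marginal colocalisation is
#'   expected to fail here while the conditional decomposition succeeds —
#'   the stress case for pairwise conditional colocalisation.
#'
#' Effect sizes are parameterised by variance explained: the exposure causal
#' variant explains `exposure_hsq` of the (unit-variance) expression trait;
#' in `"secondary_shared"` the primary explains `exposure_hsq` and the
#' secondary `secondary_hsq`. When `outcome_hsq` is `NULL` the outcome
#' effect is coupled to the exposure through `wald_true`; otherwise the
#' outcome causal variant gets `beta = sqrt(outcome_hsq) / s` on the
#' log-odds score scale and the implied Wald ratio is recorded in the truth.
#'
#' Profiles share causal variants; their effect sizes are the base effect
#' times a profile-specific multiplier drawn from an equicorrelated Gaussian
#' (mean 1, SD 0.2, correlation `profile_correlation`, floored at 0.2).
#'
#' @param kind Scenario kind (see above).
#' @param n_snp,n_ref,maf_range,ld_decay,region_span,chr Panel parameters,
#'   passed to [simulate_haplotype_panel()]. Defaults give ~1,600 variants
#'   over 1 Mb.
#' @param n_exposure Exposure (eQTL) sample size.
#' @param n_case,n_control Outcome GWAS case/control counts.
#' @param exposure_hsq Variance explained by the (primary) exposure causal
#'   variant.
#' @param secondary_hsq Variance explained by the secondary exposure signal
#'   (`"secondary_shared"` only).
#' @param wald_true True causal effect of a 1 SD expression change on the
#'   outcome log odds, used when `outcome_hsq` is `NULL`.
#' @param outcome_hsq Optional score-scale variance explained by the outcome
#'   causal variant; decouples the outcome signal strength from
#'   `wald_true`.
#' @param distinct_r2_cap Maximum LD r^2 between the two causal variants in
#'   `"distinct"`; a generation error is raised if the panel cannot satisfy
#'   it.
#' @param secondary_r2_cap Maximum LD r^2 between the two exposure signals
#'   in `"secondary_shared"`.
#' @param n_profiles Number of exposure profiles.
#' @param profile_correlation Correlation of effect sizes across profiles.
#' @param mode Summary-statistics generation mode (see
#'   [simulate_quant_sumstats()]); `"analytic"` by default.
#' @param prevalence Outcome population prevalence (genotype-level mode).
#' @param gene_id Gene label; the gene body is a 20 kb interval at the
#'   region centre.
#' @param id_prefix Variant-id prefix passed to
#'   [simulate_haplotype_panel()].
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @return An object of class `mr_scenario`: a list with `exposures` (named
#'   list of `sumstats`), `outcome` (`sumstats`), `ld` (matrix), `panel`,
#'   `gene` (one-row annotation tibble: `gene, chr, start, end`) and
#'   `truth` (list: `kind`, `causal_exposure`, `causal_outcome`,
#'   `profile_multipliers`, `wald_true`, `seed`).
#' @examples
#' sc <- make_scenario("shared", n_snp = 200, n_ref = 100,
#'                     n_exposure = 1000, n_case = 500, n_control = 500,
#'                     seed = 1)
#' sc$truth$kind
#' names(sc$truth$causal_exposure)
#' @export
make_scenario <- function(kind = c("shared", "distinct", "null",
                                   "secondary_shared"),
                          n_snp = 1600, n_ref = 500,
                          maf_range = c(0.05, 0.5), ld_decay = 0.9,
                          region_span = 1e6, chr = "1",
                          n_exposure = 10000, n_case = 20000,
                          n_control = 20000,
                          exposure_hsq = 0.05,
                          secondary_hsq = exposure_hsq / 2,
                          wald_true = 0.2, outcome_hsq = NULL,
                          distinct_r2_cap = 0.01, secondary_r2_cap = 0.05,
                          n_profiles = 1, profile_correlation = 0.8,
                          mode = c("analytic", "genotype_level"),
                          prevalence = 0.1, gene_id = "gene_1",
                          id_prefix = "rs", seed = NULL) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  with_seed(seed, {
    panel <- simulate_haplotype_panel(n_ref, n_snp, maf_range, ld_decay,
                                      region_span, chr = chr,
                                      id_prefix = id_prefix, seed = NULL)
    ld <- ld_from_panel(panel,
                        method = if (mode == "analytic") "markov"
                                 else "empirical")
    sn <- panel$snps
    s <- panel_geno_sd(panel)
    eligible <- sn$maf >= 0.1
    centre <- (min(sn$pos) + max(sn$pos)) / 2

    causal_exp <- numeric()
    causal_out <- numeric()
    implied_wald <- NA_real_

    beta_from_hsq <- function(i, hsq) sqrt(hsq) / s[i]
    out_beta <- function(i, b_exp) {
      if (is.null(outcome_hsq)) {
        wald_true * b_exp
      } else {
        sqrt(outcome_hsq) / s[i]
      }
    }

    if (kind %in% c("shared", "null", "distinct")) {
      iA <- pick_near(sn, eligible, centre)
      bA <- beta_from_hsq(iA, exposure_hsq)
      causal_exp <- stats::setNames(bA, sn$snp[iA])
      if (kind == "shared") {
        bo <- out_beta(iA, bA)
        causal_out <- stats::setNames(bo, sn$snp[iA])
        implied_wald <- unname(bo / bA)
      } else if (kind == "distinct") {
        far <- eligible & (ld[iA, ]^2 < distinct_r2_cap)
        far[iA] <- FALSE
        if (!any(far)) {
          abort(sprintf(
            "no SNP with r^2 < %g to the exposure causal SNP %s; increase the region or relax the cap",
            distinct_r2_cap, sn$snp[iA]), class = "mrcoco_generation_error")
        }
        iB <- pick_near(sn, far, min(sn$pos) + 0.75 * region_span)
        bo <- out_beta(iB, bA)
        causal_out <- stats::setNames(bo, sn$snp[iB])
      }
    } else { # secondary_shared
      i1 <- pick_near(sn, eligible, min(sn$pos) + region_span / 3)
      far <- eligible & (ld[i1, ]^2 < secondary_r2_cap)
      far[i1] <- FALSE
      if (!any(far)) {
        abort(sprintf(
          "no SNP with r^2 < %g to the primary signal %s for a secondary signal",
          secondary_r2_cap, sn$snp[i1]), class = "mrcoco_generation_error")
      }
      i2 <- pick_near(sn, far, min(sn$pos) + 2 * region_span / 3)
      b1 <- beta_from_hsq(i1, exposure_hsq)
      b2 <- beta_from_hsq(i2, secondary_hsq)
      causal_exp <- stats::setNames(c(b1, b2), sn$snp[c(i1, i2)])
      bo <- out_beta(i2, b2)
      causal_out <- stats::setNames(bo, sn$snp[i2])
      implied_wald <- unname(bo / b2)
    }

    # Profile multipliers: equicorrelated Gaussian around 1.
    rho <- profile_correlation
    z0 <- rnorm(1)
    mult <- pmax(1 + 0.2 * (sqrt(rho) * z0 +
                              sqrt(1 - rho) * rnorm(n_profiles)), 0.2)
    if (n_profiles == 1) mult <- 1

    exposures <- lapply(seq_len(n_profiles), function(pfx) {
      simulate_quant_sumstats(
        panel, causal_exp * mult[pfx], n = n_exposure, mode = mode,
        trait_id = sprintf("profile_%02d", pfx), seed = NULL)
    })
    names(exposures) <- sprintf("profile_%02d", seq_len(n_profiles))

    outcome <- simulate_cc_sumstats(panel, causal_out, n_case, n_control,
                                    prevalence = prevalence, mode = mode,
                                    trait_id = "outcome", seed = NULL)

    gene <- tibble::tibble(
      gene = gene_id, chr = as.character(chr),
      start = as.integer(round(centre - 1e4)),
      end = as.integer(round(centre + 1e4)))

    structure(list(exposures = exposures, outcome = outcome, ld = ld,
                   panel = panel, gene = gene,
                   truth = list(kind = kind,
                                causal_exposure = causal_exp,
                                causal_outcome = causal_out,
                                profile_multipliers = mult,
                                wald_true = if (is.na(implied_wald) &&
                                                kind == "shared")
                                  wald_true else implied_wald,
                                seed = seed)),
              class = "mr_scenario")
  })
}

#' @export
print.mr_scenario <- function(x, ...) {
  cat(sprintf(
    "<mr_scenario> kind '%s': %d profile(s) x %d SNPs; exposure causal: %s; outcome causal: %s\n",
    x$truth$kind, length(x$exposures), nrow(x$panel$snps),
    paste(names(x$truth$causal_exposure), collapse = ",") %||% "-",
    if (length(x$truth$causal_outcome)) {
      paste(names(x$truth$causal_outcome), collapse = ",")
    } else {
      "none"
    }))
  invisible(x)
}

#' Simulate a multi-tissue eQTL lookup table
#'
#' Emulates a tissue-panel eQTL resource for a set of prioritised variants:
#' each variant is absent from the whole table with probability
#' `absent_probability` (exercising LD-proxy lookup), otherwise present in
#' each tissue with probability `presence_probability`, and each present
#' tissue x variant cell is genome-wide significant with probability
#' `share_probability`. The first two tissues are named as colon tissues so
#' reports can mark them distinctly.
#'
#' @param snp_ids Character vector of variant ids.
#' @param n_tissues Number of tissues (>= 1).
#' @param share_probability Probability that a present cell is significant
#'   (default 0.64, a realistic mean cross-tissue sharing rate).
#' @param absent_probability Probability a variant is missing from the
#'   table entirely.
#' @param presence_probability Per-tissue presence probability for
#'   non-absent variants.
#' @param p_threshold Significance threshold the generated p-values respect.
#' @param seed Integer seed.
#' @return Tibble with columns `tissue`, `snp`, `beta`, `se`, `p`.
#' @examples
#' tab <- make_multitissue_fixture(c("rs1", "rs2"), n_tissues = 5, seed = 1)
#' table(tab$tissue)
#' @export
make_multitissue_fixture <- function(snp_ids, n_tissues = 50,
                                     share_probability = 0.64,
                                     absent_probability = 0.1,
                                     presence_probability = 0.95,
                                     p_threshold = 5e-8, seed = NULL) {
  if (!is.numeric(n_tissues) || n_tissues < 1) {
    param_error("`n_tissues` must be >= 1")
  }
  assert_scalar_prob(share_probability, "share_probability",
                     open_left = FALSE, open_right = FALSE)
  tissues <- c("Colon_Sigmoid", "Colon_Transverse",
               sprintf("Tissue_%02d", seq_len(max(n_tissues - 2, 0)) + 2))
  tissues <- tissues[seq_len(n_tissues)]
  with_seed(seed, {
    keep_snp <- runif(length(snp_ids)) >= absent_probability
    grid <- tidyr::expand_grid(tissue = tissues,
                               snp = snp_ids[keep_snp])
    if (nrow(grid) == 0) {
      return(tibble::tibble(tissue = character(), snp = character(),
                            beta = numeric(), se = numeric(),
                            p = numeric()))
    }
    grid <- grid[runif(nrow(grid)) < presence_probability, , drop = FALSE]
    sig <- runif(nrow(grid)) < share_probability
    p <- ifelse(sig,
                10^(-runif(nrow(grid), -log10(p_threshold) + 0.5, 30)),
                runif(nrow(grid), 1e-4, 0.99))
    z <- p_to_z(p)
    se <- 0.05
    grid$beta <- sample(c(-1, 1), nrow(grid), replace = TRUE) * z * se
    grid$se <- se
    grid$p <- p
    grid
  })
}
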