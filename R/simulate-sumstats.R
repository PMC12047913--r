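# Synthetic GWAS/eQTL summary statistics with known ground truth.

# Columns of the markov LD matrix for a subset of SNPs, computed in O(p * k)
# from the panel's achieved adjacent correlations.
markov_ld_cols <- function(panel, ids) {
  r <- panel$snps$adj_r
  a <- c(0, cumsum(-log(pmax(r[-1], 0))))
  j <- match(ids, panel$snps$snp)
  out <- vapply(a[j], function(ac) exp(-abs(a - ac)), numeric(length(a)))
  out[is.nan(out)] <- 0
  dimnames(out) <- list(panel$snps$snp, ids)
  out
}

# Per-SNP genotype SD under Hardy-Weinberg at the panel's empirical eaf.
panel_geno_sd <- function(panel) {
  f <- panel$snps$eaf
  sqrt(2 * f * (1 - f))
}

# Correlated z-noise with the exact AR(1)-by-blocks structure of the Markov
# panel: cor(z_j, z_k) = prod of adjacent correlations between j and k.
markov_noise <- function(panel) {
  r <- panel$snps$adj_r
  p <- length(r)
  e <- rnorm(p)
  z <- e
  if (p > 1) {
    for (j in 2:p) {
      z[j] <- r[j] * z[j - 1] + sqrt(1 - r[j]^2) * e[j]
    }
  }
  z
}

check_causal_ids <- function(causal, panel) {
  if (length(causal) == 0) {
    return(invisible(NULL))
  }
  if (is.null(names(causal)) || any(!nzchar(names(causal)))) {
    param_error("causal effects must be a named vector of variant ids")
  }
  bad <- setdiff(names(causal), panel$snps$snp)
  if (length(bad) > 0) {
    param_error(sprintf("causal variant(s) not in panel: %s",
                        paste(bad, collapse = ", ")))
  }
  invisible(NULL)
}

# Expected marginal per-allele effects given causal per-allele effects:
# m_j = sum_c R[j, c] * (s_c / s_j) * b_c.
marginal_means <- function(panel, causal, s) {
  p <- nrow(panel$snps)
  if (length(causal) == 0) {
    return(numeric(p))
  }
  Rc <- markov_ld_cols(panel, names(causal))
  ci <- match(names(causal), panel$snps$snp)
  drop(Rc %*% (s[ci] * unname(causal))) / s
}

#' Simulate quantitative-trait (eQTL-style) summary statistics
#'
#' Produces per-variant marginal association statistics for a standardised
#' quantitative trait (variance 1, so effects are per SD) driven by the
#' given causal variants.
#'
#' * `mode = "genotype_level"`: draws `n` diploid genotypes from the panel's
#'   haplotypes, builds the phenotype as the causal genetic score plus
#'   Gaussian noise scaled so the trait variance is 1, and runs a simple
#'   per-variant regression for each SNP.
#' * `mode = "analytic"`: draws the marginal effect vector directly from its
#'   sampling distribution under the panel's exact Markov LD — mean = the
#'   LD-weighted causal effects, SE = `1 / (s_j * sqrt(n))` with
#'   `s_j = sqrt(2 f_j (1 - f_j))`, and noise correlated across variants
#'   with the LD structure. This is the standard generative model for
#'   summary-statistics methods and is orders of magnitude faster.
#'
#' Both modes are deterministic given `seed`.
#'
#' @param panel A [haplotype_panel][simulate_haplotype_panel()].
#' @param causal_effects Named numeric vector: per-effect-allele effects (SD
#'   units) keyed by variant id. Empty vector = null trait.
#' @param n Sample size (>= 50).
#' @param mode `"genotype_level"` or `"analytic"`.
#' @param trait_id Trait label.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `sumstats` tibble (quantitative).
#' @examples
#' panel <- simulate_haplotype_panel(200, 20, seed = 1)
#' ss <- simulate_quant_sumstats(panel, c(rs00010 = 0.3), n = 1000, seed = 2)
#' ss[which.min(ss$p), ]
#' @export
simulate_quant_sumstats <- function(panel, causal_effects = numeric(),
                                    n,
                                    mode = c("genotype_level", "analytic"),
                                    trait_id = "expression", seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.numeric(n) || length(n) != 1 || n < 50) {
    param_error("`n` must be a single sample size >= 50")
  }
  check_causal_ids(causal_effects, panel)
  s <- panel_geno_sd(panel)
  b <- unname(causal_effects)
  ci <- match(names(causal_effects), panel$snps$snp)
  v_explained <- if (length(b) > 0) {
    Rcc <- markov_ld_cols(panel, names(causal_effects))[ci, , drop = FALSE]
    drop(t(b * s[ci]) %*% Rcc %*% (b * s[ci]))
  } else {
    0
  }
  if (v_explained >= 1) {
    param_error(sprintf(
      "causal effects explain %.3f of trait variance (must be < 1)",
      v_explained))
  }

  with_seed(seed, {
    if (mode == "analytic") {
      se <- 1 / (s * sqrt(n))
      beta <- marginal_means(panel, causal_effects, s) + se * markov_noise(panel)
    } else {
      n_hap <- nrow(panel$haplotypes)
      g <- panel$haplotypes[sample.int(n_hap, n, replace = TRUE), ,
                            drop = FALSE] +
        panel$haplotypes[sample.int(n_hap, n, replace = TRUE), ,
                         drop = FALSE]
      score <- if (length(b) > 0) {
        drop(g[, ci, drop = FALSE] %*% b)
      } else {
        numeric(n)
      }
      y <- score + rnorm(n, 0, sqrt(1 - v_explained))
      fit <- marginal_ols(g, y)
      beta <- fit$beta
      se <- fit$se
    }
    p <- z_to_p(beta / se)
    build_sim_sumstats(panel, beta, se, p, n = n, trait_id = trait_id,
                       trait_type = "quantitative")
  })
}

# Vectorised per-SNP simple linear regression of y on each column of g.
marginal_ols <- function(g, y) {
  n <- length(y)
  mg <- colMeans(g)
  sxx <- colSums(g^2) - n * mg^2
  my <- mean(y)
  sxy <- drop(crossprod(g, y)) - n * mg * my
  syy <- sum(y^2) - n * my^2
  poly <- sxx > 0
  beta <- ifelse(poly, sxy / sxx, 0)
  sigma2 <- pmax((syy - beta * sxy) / (n - 2), 0)
  se <- ifelse(poly, sqrt(sigma2 / pmax(sxx, 1e-300)), 1e6)
  list(beta = beta, se = se)
}

build_sim_sumstats <- function(panel, beta, se, p, n, trait_id, trait_type,
                               n_case = NULL, n_control = NULL) {
  sn <- panel$snps
  df <- tibble::tibble(
    snp = sn$snp, chr = sn$chr, pos = sn$pos, ea = sn$ea, nea = sn$nea,
    eaf = unname(sn$eaf), beta = unname(beta), se = unname(se),
    p = unname(pmax(p, 1e-320)),
    n = rep(as.numeric(n), nrow(sn))
  )
  if (!is.null(n_case)) {
    df$n_case <- as.numeric(n_case)
    df$n_control <- as.numeric(n_control)
  }
  region <- list(chr = sn$chr[1], start = min(sn$pos), end = max(sn$pos))
  as_sumstats(df, trait_id = trait_id, trait_type = trait_type,
              region = region, validate = FALSE)
}

#' Simulate case-control GWAS summary statistics
#'
#' Generates marginal log-odds-ratio statistics for a binary outcome under a
#' logistic disease model with the given causal per-allele log odds ratios.
#'
#' * `mode = "genotype_level"`: simulates a population pool of genotypes
#'   drawn from the panel, sets the logistic intercept so the population
#'   prevalence matches `prevalence`, and resamples the pool with
#'   case/control posterior weights to hit `n_case` / `n_control` exactly.
#'   Marginal effects come from a per-SNP logistic fit when the total sample
#'   is at most `exact_n_max`, and from the score-test (Wald) approximation
#'   `beta = U/V`, `se = 1/sqrt(V)` above it, keeping large designs
#'   desk-scale.
#' * `mode = "analytic"`: draws marginal log ORs from their approximate
#'   sampling distribution: mean = LD-weighted causal log odds, SE
#'   `2 / (s_j * sqrt(n_eff))` with `n_eff = 4 / (1/n_case + 1/n_control)`,
#'   LD-correlated noise.
#'
#' @param panel A [haplotype_panel][simulate_haplotype_panel()].
#' @param causal_log_odds Named numeric vector of per-allele log odds ratios
#'   keyed by variant id. Empty vector = null trait.
#' @param n_case,n_control Case and control counts (each >= 50).
#' @param prevalence Baseline population prevalence in (0, 1).
#' @param mode `"genotype_level"` or `"analytic"`.
#' @param pool_mult Pool size multiplier for case/control resampling.
#' @param exact_n_max Largest total sample for which the exact per-SNP
#'   logistic fit is used in genotype-level mode.
#' @param trait_id Trait label.
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `sumstats` tibble (case-control; carries `n_case`,
#'   `n_control`).
#' @examples
#' panel <- simulate_haplotype_panel(200, 10, seed = 1)
#' ss <- simulate_cc_sumstats(panel, c(rs00005 = 0.2),
#'                            n_case = 500, n_control = 500, seed = 2)
#' ss[which.min(ss$p), c("snp", "beta", "se", "p")]
#' @export
simulate_cc_sumstats <- function(panel, causal_log_odds = numeric(),
                                 n_case, n_control, prevalence = 0.1,
                                 mode = c("genotype_level", "analytic"),
                                 pool_mult = 2, exact_n_max = 2000,
                                 trait_id = "outcome", seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!is.numeric(n_case) || n_case < 50 || !is.numeric(n_control) ||
      n_control < 50) {
    param_error("`n_case` and `n_control` must each be >= 50")
  }
  assert_scalar_prob(prevalence, "prevalence")
  check_causal_ids(causal_log_odds, panel)
  s <- panel_geno_sd(panel)
  n_total <- n_case + n_control
  n_eff <- 4 / (1 / n_case + 1 / n_control)

  with_seed(seed, {
    if (mode == "analytic") {
      se <- 2 / (s * sqrt(n_eff))
      beta <- marginal_means(panel, causal_log_odds, s) +
        se * markov_noise(panel)
    } else {
      n_hap <- nrow(panel$haplotypes)
      n_pool <- ceiling(pool_mult * n_total)
      i1 <- sample.int(n_hap, n_pool, replace = TRUE)
      i2 <- sample.int(n_hap, n_pool, replace = TRUE)
      ci <- match(names(causal_log_odds), panel$snps$snp)
      score <- if (length(causal_log_odds) > 0) {
        drop((panel$haplotypes[i1, ci, drop = FALSE] +
                panel$haplotypes[i2, ci, drop = FALSE]) %*%
               unname(causal_log_odds))
      } else {
        numeric(n_pool)
      }
      alpha <- if (length(causal_log_odds) > 0) {
        uniroot(function(a) mean(plogis(a + score)) - prevalence,
                lower = qlogis(prevalence) - 20,
                upper = qlogis(prevalence) + 20)$root
      } else {
        qlogis(prevalence)
      }
      p_case <- plogis(alpha + score)
      rows <- c(sample.int(n_pool, n_case, replace = TRUE, prob = p_case),
                sample.int(n_pool, n_control, replace = TRUE,
                           prob = 1 - p_case))
      g <- panel$haplotypes[i1[rows], , drop = FALSE] +
        panel$haplotypes[i2[rows], , drop = FALSE]
      y <- rep(c(1, 0), c(n_case, n_control))
      if (n_total <= exact_n_max) {
        fit <- apply(g, 2, function(x) {
          if (stats::var(x) == 0) {
            return(c(0, 1e6))
          }
          m <- stats::glm.fit(cbind(1, x), y,
                              family = stats::binomial())
          cf <- m$coefficients[2]
          # Wald SE from the inverse information of the fitted model.
          w <- m$weights
          X <- cbind(1, x)
          v <- tryCatch(solve(crossprod(X * sqrt(w)))[2, 2],
                        error = function(e) NA_real_)
          c(cf, sqrt(v))
        })
        beta <- fit[1, ]
        se <- fit[2, ]
      } else {
        ybar <- mean(y)
        mg <- colMeans(g)
        sxx <- colSums(g^2) - n_total * mg^2
        V <- ybar * (1 - ybar) * sxx
        U <- drop(crossprod(g, y - ybar))
        poly <- V > 0
        beta <- ifelse(poly, U / V, 0)
        se <- ifelse(poly, 1 / sqrt(pmax(V, 1e-300)), 1e6)
      }
    }
    p <- z_to_p(beta / se)
    build_sim_sumstats(panel, beta, se, p, n = n_total,
                       trait_id = trait_id, trait_type = "case_control",
                       n_case = n_case, n_control = n_control)
  })
}
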