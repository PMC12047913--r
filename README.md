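# mrcoco

Transcriptome-wide Mendelian randomisation with pairwise conditional
colocalisation, in R.

## The problem

Does changing the expression of a gene in a particular cell state change
disease risk? Given per-variant summary statistics for gene expression
(cis-eQTLs, e.g. across CD4+ T cell activation states) and for a
case-control outcome (e.g. colorectal cancer GWAS), `mrcoco` runs the full
causal-screening workflow on summary data alone:

1. **Instrument selection** — cis variants (gene body ± 500 kb) with
   association *P* < 5×10⁻⁸, greedily LD-clumped (r² < 0.001 within 10 kb),
   weak instruments removed at *F* = (β/se)² < 10, and Steiger-filtered so
   the variant explains more variance in expression than in the outcome.
2. **Wald-ratio MR** — for a single-SNP instrument the causal estimate is
   β_wald = β_outcome / β_exposure with delta-method standard error
   se_out/|β_exp| (second order optional), reported as an odds ratio per SD
   of expression with 95% CI, and Benjamini–Hochberg FDR across the screen.
3. **Colocalisation with conditional decomposition (PWCoCo)** — per-variant
   Wakefield log approximate Bayes factors
   `labf = ½[log(se²/(se²+W)) + z²·W/(se²+W)]` feed posteriors for the five
   hypotheses H0–H4 (no signal / one trait only / two distinct variants /
   one shared variant) with priors p1 = p2 = 1×10⁻⁵, p12 = 1×10⁻⁷. Regions
   with several independent signals are first decomposed by stepwise
   conditional analysis against an LD reference (summary-statistics joint
   least squares, the COJO model); every marginal/conditional dataset pair
   is colocalised and the evidence summarised by max H4 (> 0.8 declares a
   shared variant).
4. **Multi-tissue lookup** — for genes passing both gates, the lead eQTL
   (or its best LD proxy at r² ≥ 0.8) is checked for genome-wide-significant
   association with the gene's expression across a tissue panel.

Every stage is testable without external data: the package ships a
synthetic summary-statistics generator (Markov haplotype panels with exact
closed-form LD, quantitative and case-control GWAS under known causal
configurations, multi-gene studies, tissue lookup tables) whose ground
truth drives the whole test suite.

## Worked example

```r
library(mrcoco)

# one cis region where expression and outcome share a causal variant
sc <- make_scenario("shared", n_snp = 400, n_ref = 300,
                    outcome_hsq = 0.02, seed = 5)

inst <- select_instrument(sc$exposures[[1]], sc$outcome, sc$gene, sc$ld)
w <- wald_ratio(inst$beta_exp, inst$se_exp, inst$beta_out, inst$se_out)
dplyr::bind_cols(w, or_with_ci(w$wald_beta, w$wald_se))
#> # A tibble: 1 × 6
#>   wald_beta wald_se   pvalue or_point ci_low ci_high
#>       <dbl>   <dbl>    <dbl>    <dbl>  <dbl>   <dbl>
#> 1     0.673  0.0478 5.38e-45     1.96   1.79    2.15

res <- pwcoco(sc$exposures[[1]], sc$outcome, sc$ld)
glance(res)
#> # A tibble: 1 × 5
#>   n_pairs n_signals_exposure n_signals_outcome max_h4 colocalises
#>     <int>              <int>             <int>  <dbl> <lgl>
#> 1       1                  1                 1   1.00 TRUE
```

The Wald ratio says each SD of higher expression roughly doubles the odds
(OR 1.96, CI 1.79–2.15 — this synthetic gene is harmful by construction:
the simulated outcome effect divided by the exposure effect at the shared
variant). One signal per trait, so PWCoCo collapses to a single
marginal×marginal colocalisation; max H4 > 0.8 correctly recovers the
shared variant.
The stress case is a region where the exposure has two independent
signals and only the *secondary* one is shared — marginal colocalisation
fails while the conditional decomposition succeeds:

```r
sc2 <- make_scenario("secondary_shared", n_snp = 400, n_ref = 300,
                     outcome_hsq = 0.02, seed = 6)
pwcoco(sc2$exposures[[1]], sc2$outcome, sc2$ld)$pairs[, c(1, 2, 6, 7)]
#>   exposure_version outcome_version       h3       h4
#> 1         marginal        marginal 1.00e+00 7.29e-45
#> 2   signal_rs00132        marginal 1.00e+00 1.64e-32
#> 3   signal_rs00273        marginal 2.44e-09 1.00e+00
```

An end-to-end study (instruments → MR → FDR gate → PWCoCo gate → tissue
lookup) over genes × profiles × outcome strata:

```r
study <- simulate_study(n_genes = 12, n_profiles = 2, n_snp = 200,
                        n_ref = 200, seed = 11)
run <- run_pipeline(study, pipeline_config(seed = 3), out_dir = "out")
run$manifest
#>   stage             count
#> 1 tests_attempted      24
#> 2 instruments_found    24
#> 3 fdr_significant       6
#> 4 colocalised           2
#> 5 tissue_lookups        1
report <- make_report(run)   # volcano, contributions, coloc/tissue matrices
autoplot(run$mr)             # volcano plot
```

The funnel counts are monotone by construction: colocalised ≤
FDR-significant ≤ instruments ≤ tests.

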