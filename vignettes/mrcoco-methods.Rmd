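---
title: "Methods: cis-MR screening with pairwise conditional colocalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cis-MR screening with pairwise conditional colocalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcoco)
```

`mrcoco` screens gene-expression exposures against a disease outcome using
only per-variant summary statistics: single-SNP Wald-ratio Mendelian
randomisation gated by false-discovery control, followed by Bayesian
colocalisation with conditional decomposition of multi-signal regions, and
a cross-tissue eQTL lookup for the survivors. This vignette documents the
statistical model behind each stage, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
the numerical decisions that a maintainer would otherwise have to
reverse-engineer.

## 1. Data model

A summary dataset (`as_sumstats()`) is a tibble of per-variant records:
id, chromosome, 1-based position (closed intervals throughout), effect and
other allele, effect-allele frequency, effect estimate, standard error,
p-value, and sample size (case/control counts for binary traits).
Quantitative traits are assumed standardised — expression effects are per
SD of expression — which also fixes the colocalisation prior scale
(section 4). Validation drops rows with non-positive SEs, out-of-range
frequencies or p-values, indels/multi-allelic records, duplicate ids, and
records whose p-value implies a z-score more than 10% away from
`beta/se`; every drop is counted by reason. For case-control traits the
effective sample size `4/(1/n_case + 1/n_control)` — the equivalent
balanced design — is used wherever a single n enters a variance formula
(Steiger test, conditional analysis).

Two-sample harmonisation (`harmonise()`) aligns the outcome to the
exposure's effect allele: swapped alleles negate the outcome beta and
reflect its frequency; irreconcilable allele pairs are dropped.
Palindromic variants (A/T, C/G) carry no strand information in their
labels, so they are kept only when both allele frequencies are outside
0.5 ± w and on the same side; the half-width w defaults to 0.08, the
conventional ambiguity band in two-sample MR. Harmonisation is idempotent
and symmetric in what it excludes.

## 2. Instrument selection

For each gene × cell-state profile the candidate instruments are variants
in the cis window (gene body ± 500 kb, closed) with exposure
*P* < 5×10⁻⁸ (strict). Greedy LD clumping then keeps, at each step, the
lowest-p unassigned variant and prunes variants that are simultaneously
within 10 kb *and* at r² ≥ 0.001 with it — both conditions must hold,
the standard clumping semantics; ties on p break by position, then id.
Weak instruments are removed by the single-SNP F-statistic
`F = (beta/se)²` at F < 10, and the Steiger direction filter removes
variants whose explained variance in the outcome,
`r² = z²/(z² + n_eff − 2)`, is at least their explained variance in the
exposure (ties fail — reverse causation is not given the benefit of the
doubt). The lowest-p survivor is *the* instrument: the package estimates
single-SNP Wald ratios only, so one variant per gene × profile is selected
and alternates are logged with reason `alternate_index_snp`.

## 3. Wald-ratio MR and FDR

The causal effect of a 1 SD expression change on outcome log odds is
`wald_beta = beta_out/beta_exp`. The default SE is the first-order delta
method, `se_out/|beta_exp|` — the dominant convention for single-SNP
ratios, accurate when the instrument is strong (F well above 10); the
second-order form `sqrt(se_out²/beta_exp² + beta_out²·se_exp²/beta_exp⁴)`
is available by configuration. P-values are two-sided normal; with
summary-level GWAS sample sizes a small-sample t correction would be
immaterial. Effects are reported as OR = exp(wald_beta) with
`exp(wald_beta ± z_{1−α/2}·wald_se)` intervals.

Benjamini–Hochberg q-values are computed within one outcome dataset by
default (each outcome stratum is its own screen, mirroring per-outcome
reporting); a global family across outcomes is available. Whether
correction should span outcomes jointly is a genuinely open choice — the
per-outcome default keeps strata with very different power from
contaminating each other's ranking.

## 4. Colocalisation with conditional decomposition

Per variant, evidence of association is the Wakefield log approximate
Bayes factor: with `z = beta/se` and prior effect variance `W`,
`labf = ½[log(se²/(se²+W)) + z²·W/(se²+W)]`. The prior SD is 0.2 × trait
SD for quantitative traits (0.2 with standardised expression) and 0.15 on
the log-odds scale for binary traits — the established defaults of the
ABF colocalisation framework. Region posteriors for the five hypotheses
use per-variant priors p1 = p2 = 1×10⁻⁵ and p12 = 1×10⁻⁷, calibrated for
windows of ~1,600 variants: `expected_signal_counts()` shows they imply
~0.016 expected causal variants per trait per window and ~1.6×10⁻⁴ shared
ones. All sums of exponentiated labfs are accumulated in log space with
max-subtraction, so |labf| in the hundreds is exact; `L1·L2 − L12` (the
H3 weight) is computed via `log1p(−exp(·))` and a single-variant region
forces H3 = 0 identically.

A region with several independent signals violates the single-causal
assumption of plain colocalisation, so each trait is first decomposed by
stepwise conditional analysis against the LD reference. The conditional
model is exact summary-statistics joint least squares: the centred X'X is
rebuilt as `S[j,k] = (n−1)·r[j,k]·sd_j·sd_k` with `sd` from reference
allele frequencies under Hardy–Weinberg (or supplied genotype variances),
X'y from the marginal betas, and the phenotypic sum of squares from the
median per-variant implied value `S[j,j]·(beta_j² + se_j²·(n−2))` — the
same trick the COJO literature uses, which also handles log-odds traits
without a separate variance parameter. Conditional estimates are the
target variant's coefficient and SE from the joint fit of target +
conditioning set; with in-sample LD and variances this reproduces
genotype-level multiple regression to numerical precision (an approximate
form that divides by the marginal rather than the partialled diagonal
exists in the literature; the exact fit was chosen because it is the
quantity the approximation estimates, and it is what genotype-level
regression verifies). Stepwise selection starts at the sentinel, adds the
best conditional p < 5×10⁻⁸, masks variants at r² > 0.9 with the selected
set (both thresholds configurable — no canonical values exist), and stops
when nothing qualifies. Reference allele frequencies come from the LD
panel; variants whose summary frequency differs by more than 0.2 are
masked with a warning.

Pairwise conditional colocalisation then colocalises every cross-trait
pair of datasets — the marginal one plus, for a trait with k > 1 signals,
the k conditionals (each signal's association conditioned on all other
selected signals). Evidence for a shared variant is `max H4` over pairs,
declared at H4 > 0.8. With one signal per side this is exactly plain
colocalisation.

## 5. The synthetic-data generator

The generator exists so that every stage has a ground truth. Its parts:

* **Haplotype panel** (`simulate_haplotype_panel()`): binary first-order
  Markov chain along the chromosome. Adjacent variants attain a *target*
  Pearson correlation (default 0.9, capped at the bound implied by their
  frequencies) via the conditional Bernoulli that preserves margins.
  Because conditional expectations of binary variables are linear,
  correlation is exactly multiplicative along the chain, so the population
  LD matrix has the closed form `R[j,k] = prod of adjacent r` — full rank,
  noise-free, O(n) to sample from. `ld_from_panel()` returns either this
  closed form (`"markov"`) or the empirical haplotype correlation
  (`"empirical"`).
* **Quantitative traits** (`simulate_quant_sumstats()`): either
  genotype-level (diploid genotypes drawn from the panel, phenotype =
  causal score + Gaussian noise scaled to unit trait variance, per-variant
  simple regression) or analytic — marginal betas drawn from their
  sampling distribution under the Markov LD: mean = LD-weighted causal
  effects, SE = `1/(s_j√n)` with `s_j = sqrt(2f_j(1−f_j))`, and noise
  correlated across variants with the LD structure (sampled exactly by
  the AR(1) recursion). The analytic route is the standard generative
  model for summary-statistics methods and is what makes 100-seed
  full-design simulations affordable.
* **Case-control traits** (`simulate_cc_sumstats()`): logistic disease
  model. Genotype-level mode simulates a population pool, solves the
  intercept for the target prevalence (default 0.1), resamples cases and
  controls by their posterior weights to hit the exact counts, and
  estimates marginal log ORs by per-variant logistic fits up to a
  configurable total n (default 2,000) and by the score-test
  approximation above it. Analytic mode mirrors the quantitative case
  with SE `2/(s_j√n_eff)`.
* **Scenarios** (`make_scenario()`): the generative counterparts of the
  colocalisation hypotheses — `shared`, `distinct` (causal pair at
  r² < 0.01), `null` (exposure signal, no outcome signal), and
  `secondary_shared` (two exposure signals, only the weaker shared: the
  case marginal colocalisation gets wrong and conditional decomposition
  rescues). Defaults are the study design used throughout the tests:
  1,600 variants over 1 Mb (mirroring ~1,600-variant cis windows),
  n_exposure = 10,000, 20,000 cases / 20,000 controls, exposure causal
  variance 5% (a strong lead cis-eQTL; the secondary-shared primary gets
  8% and the secondary 4% so the sentinel is unambiguous), and a true
  Wald effect of 0.2 coupling the outcome to the exposure. For
  colocalisation-focused runs the outcome signal can instead be given its
  own variance (`outcome_hsq`, typically 0.02 so each trait's causal
  variant explains at least 1% of its score-scale variance and reaches
  genome-wide significance); the implied Wald ratio is then recorded in
  the truth. Profile effects share causal variants with multipliers from
  an equicorrelated Gaussian (mean 1, SD 0.2, correlation 0.8).
* **Tissue tables** (`make_multitissue_fixture()`): per tissue × variant
  records where a present cell is genome-wide significant with the share
  probability (default 0.64, a realistic mean cross-tissue sharing rate);
  some variants are absent entirely to exercise LD-proxy lookup.

What the generator deliberately does **not** emulate: real human LD block
structure, recombination hotspots, population stratification, imputation
quality, sample overlap between exposure and outcome, sex-specific
genetic effects on expression, and the extreme LD of the MHC region.
Passing tests therefore demonstrate the *methods* are implemented and
calibrated correctly under a clean generative model — not that any
particular real-data finding would replicate. Variant alleles are drawn
from strand-unambiguous pairs so that synthetic pipelines exercise allele
flips; palindromic handling is covered by explicit fixtures instead.

## 6. Numerical and design decisions

* All randomness flows through one explicit seed per generator call; the
  caller's RNG state is restored afterwards, and composite generators
  (`make_scenario()`, `simulate_study()`) fan a single outer seed into
  their sub-calls. Identical seeds give bit-identical outputs, including
  written TSVs.
* Clumping and stepwise ties break deterministically (p, then position,
  then id). Greedy clumping is verified against a literal brute-force
  re-implementation on random instances.
* Degenerate inputs: monomorphic panel variants get LD 0 with a warning;
  a singular conditioning set raises a conditioning error naming the
  collinear variants; conditioning targets with near-zero partial
  variance are masked rather than returned with exploding SEs.
* p-values are floored at 1e-320 to stay in (0, 1] through I/O
  round-trips.
* `bh_fdr()` validates its domain and delegates to the stock step-up
  implementation (`p.adjust`), cross-checked against a literal
  re-implementation in the tests — the procedure is standard, so the
  standard tool is used.
* The pipeline gates exactly as the screening design dictates:
  colocalisation runs only for FDR-significant gene × profile × outcome
  triples, the tissue lookup only for colocalised genes, so the manifest
  funnel (colocalised ≤ significant ≤ instrumented ≤ tested) is monotone
  by construction. Outputs contain no timestamps, making reruns
  byte-identical; existing outputs are not overwritten unless forced.
* The package is function-first: `run_pipeline()` / `make_report()` and
  `scripts/acceptance.R` are the orchestration surface, and every result
  object has broom-style `tidy()`/`glance()` and `autoplot()` methods.

## 7. Problem sizes used in the checks

The test suite exercises the full study design where it matters:
scenario discrimination runs 100 seeds per family at 1,600 variants with
n_exposure = 10,000 and 20,000/20,000 cases/controls; Wald calibration
uses 200 replicates of the same design; error control uses a 1,000-gene
null screen plus twenty 200-gene end-to-end null studies; conditional
analysis is checked against genotype-level regression on fifty 20-variant
two-signal regions; clumping and FDR against brute-force oracles on 500
random instances each. `scripts/acceptance.R` recomputes the same
quantities at 50 seeds per scenario family and 100 Wald replicates, sizes
chosen so a complete from-scratch run stays within a few minutes on one
CPU while leaving Monte-Carlo error well inside the decision margins.

## 8. Known limitations

Single-SNP instruments only (no IVW/Egger/median estimators, no
multivariable MR); no heterogeneity statistics; conditional decomposition
assumes the LD reference matches the GWAS population (a mismatched panel
degrades both clumping and conditioning); colocalisation beyond
conditional decomposition (e.g. fine-mapping-based variants) is out of
scope; and the tissue lookup flags shared eQTL activity but does not
attribute causal tissues — a significant lookup in another tissue is a
pleiotropy warning, not a verdict.
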