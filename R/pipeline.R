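# End-to-end orchestration: instruments -> MR screen -> FDR gate -> pairwise
# conditional colocalisation gate -> multi-tissue lookup.

#' Pipeline configuration
#'
#' Gathers every tunable of the screen with defaults matching standard
#' practice for this design: FDR 0.05, colocalisation declared at H4 > 0.8,
#' stepwise entry at genome-wide significance.
#'
#' @param instruments An [instrument_config()].
#' @param priors A [coloc_priors()].
#' @param fdr_level FDR significance level.
#' @param fdr_family `"per_outcome"` or `"global"` (see [mr_screen()]).
#' @param h4_threshold Colocalisation threshold on max H4.
#' @param p_entry,collinearity_r2 COJO stepwise parameters.
#' @param se_order Delta-method order for Wald SEs.
#' @param tissue_p_threshold,proxy_r2_min Tissue-lookup thresholds.
#' @param n_tissues,share_probability Parameters of the simulated tissue
#'   table used when the study does not carry one.
#' @param seed Seed for any randomness the pipeline itself introduces
#'   (tissue-table simulation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(instruments = instrument_config(),
                            priors = coloc_priors(),
                            fdr_level = 0.05,
                            fdr_family = c("per_outcome", "global"),
                            h4_threshold = 0.8,
                            p_entry = 5e-8, collinearity_r2 = 0.9,
                            se_order = c("first", "second"),
                            tissue_p_threshold = 5e-8, proxy_r2_min = 0.8,
                            n_tissues = 50, share_probability = 0.64,
                            seed = 1) {
  assert_scalar_prob(fdr_level, "fdr_level")
  assert_scalar_prob(h4_threshold, "h4_threshold")
  structure(list(instruments = instruments, priors = priors,
                 fdr_level = fdr_level,
                 fdr_family = match.arg(fdr_family),
                 h4_threshold = h4_threshold, p_entry = p_entry,
                 collinearity_r2 = collinearity_r2,
                 se_order = match.arg(se_order),
                 tissue_p_threshold = tissue_p_threshold,
                 proxy_r2_min = proxy_r2_min, n_tissues = n_tissues,
                 share_probability = share_probability, seed = seed),
            class = "pipeline_config")
}

#' Simulate a multi-gene synthetic study
#'
#' Builds a complete study for the end-to-end pipeline: one cis region per
#' gene (each on its own chromosome label, with globally unique variant
#' ids), several exposure profiles per gene named
#' `"<subtype>@<timepoint>"`, and one case-control outcome per stratum
#' assembled from the per-gene regional statistics. Scenario kinds are
#' recycled across genes so a study can mix shared, distinct and null
#' configurations.
#'
#' @param n_genes Number of genes.
#' @param kinds Character vector of scenario kinds recycled over genes.
#' @param n_profiles Exposure profiles per gene.
#' @param n_snp Variants per cis region (a study-scale default; single-region
#'   analyses use larger regions).
#' @param strata Names of outcome strata; the first uses the full
#'   case/control counts, later ones `stratum_fraction` of them with
#'   independently re-simulated statistics under the same truth.
#' @param stratum_fraction Case/control scaling for non-first strata.
#' @param seed Integer seed for the whole study.
#' @param ... Further arguments to [make_scenario()] (sample sizes, effect
#'   sizes, LD parameters, `mode`, ...).
#' @return An object of class `mr_study`: list with `exposures` (named
#'   `"gene::profile"`), `gene_map`, `genes`, `outcomes`, `ld`,
#'   `ref_eaf`, `positions`, `truth` (per gene), `seed`.
#' @export
simulate_study <- function(n_genes = 30,
                           kinds = c("shared", "distinct", "null"),
                           n_profiles = 3, n_snp = 400,
                           strata = "overall", stratum_fraction = 0.5,
                           seed = NULL, ...) {
  subtypes <- c("CD4_naive", "CD4_memory", "nTreg", "TCM", "TEM")
  timepoints <- c("0h", "LA", "16h", "40h", "5d")
  profile_names <- paste(
    subtypes[(seq_len(n_profiles) - 1) %% length(subtypes) + 1],
    timepoints[((seq_len(n_profiles) - 1) %/% length(subtypes)) %%
                 length(timepoints) + 1],
    sep = "@")
  kinds <- rep_len(kinds, n_genes)
  dots <- list(...)

  with_seed(seed, {
    per_gene <- lapply(seq_len(n_genes), function(g) {
      args <- c(list(kind = kinds[g], n_snp = n_snp,
                     n_profiles = n_profiles, chr = as.character(g),
                     gene_id = sprintf("gene_%03d", g),
                     id_prefix = sprintf("rs%03d_", g), seed = NULL),
                dots)
      sc <- do.call(make_scenario, args)
      names(sc$exposures) <- profile_names
      for (pn in profile_names) {
        attr(sc$exposures[[pn]], "trait_id") <- pn
      }
      sc
    })
    names(per_gene) <- sprintf("gene_%03d", seq_len(n_genes))

    exposures <- list()
    gene_map <- character()
    for (g_id in names(per_gene)) {
      for (pn in profile_names) {
        key <- paste(g_id, pn, sep = "::")
        exposures[[key]] <- per_gene[[g_id]]$exposures[[pn]]
        gene_map[key] <- g_id
      }
    }

    outcomes <- lapply(seq_along(strata), function(si) {
      parts <- lapply(per_gene, function(sc) {
        if (si == 1) {
          sc$outcome
        } else {
          nc <- max(ceiling(sc$outcome$n_case[1] * stratum_fraction), 50)
          nu <- max(ceiling(sc$outcome$n_control[1] * stratum_fraction), 50)
          simulate_cc_sumstats(sc$panel, sc$truth$causal_outcome,
                               n_case = nc, n_control = nu,
                               mode = dots$mode %||% "analytic",
                               trait_id = strata[si], seed = NULL)
        }
      })
      out <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
      as_sumstats(out, trait_id = strata[si], trait_type = "case_control",
                  validate = FALSE)
    })
    names(outcomes) <- strata

    structure(list(
      exposures = exposures, gene_map = gene_map,
      genes = dplyr::bind_rows(lapply(per_gene, `[[`, "gene")),
      outcomes = outcomes,
      ld = lapply(per_gene, `[[`, "ld"),
      ref_eaf = lapply(per_gene, function(sc) {
        stats::setNames(sc$panel$snps$eaf, sc$panel$snps$snp)
      }),
      positions = lapply(per_gene, function(sc) {
        stats::setNames(sc$panel$snps$pos, sc$panel$snps$snp)
      }),
      truth = lapply(per_gene, `[[`, "truth"),
      seed = seed), class = "mr_study")
  })
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf(
    "<mr_study> %d gene(s) x %d profile(s), %d outcome stratum/strata\n",
    nrow(x$genes), length(x$exposures) / max(nrow(x$genes), 1),
    length(x$outcomes)))
  invisible(x)
}

#' Run the full screen: instruments, MR, FDR gate, colocalisation gate,
#' tissue lookup
#'
#' Executes the study workflow: instrument selection and Wald-ratio MR for
#' every gene x profile x outcome, Benjamini-Hochberg correction, pairwise
#' conditional colocalisation for the FDR-significant results only, and the
#' multi-tissue lookup for genes passing both gates. All stages are
#' deterministic given the study and `config$seed`; when `out_dir` is given
#' the result tables and the run manifest are written as TSV (and an
#' existing manifest makes the write a no-op unless `force = TRUE`).
#'
#' @param study An `mr_study` (see [simulate_study()]), or any list with
#'   the same fields built from real data.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @param force Overwrite existing outputs in `out_dir`?
#' @return An object of class `mr_pipeline`: list with `mr` (the
#'   [mr_screen()] tibble), `coloc` (per significant triple: posteriors of
#'   every dataset pair plus `max_h4`, `colocalises`), `tissues` (one row
#'   per colocalised gene), `manifest` (stage counts) and `config`.
#' @export
run_pipeline <- function(study, config = pipeline_config(),
                         out_dir = NULL, force = FALSE) {
  mr <- mr_screen(study$exposures, study$outcomes, study$genes,
                  study$gene_map, study$ld,
                  config = config$instruments,
                  fdr_level = config$fdr_level,
                  fdr_family = config$fdr_family,
                  se_order = config$se_order)

  sig <- mr[mr$significant %in% TRUE, , drop = FALSE]
  coloc_rows <- purrr::pmap(
    list(sig$gene, sig$profile, sig$outcome),
    function(g_id, pf, out_name) {
      key <- paste(g_id, pf, sep = "::")
      res <- pwcoco(study$exposures[[key]], study$outcomes[[out_name]],
                    ld = study$ld[[g_id]], priors = config$priors,
                    p_entry = config$p_entry,
                    collinearity_r2 = config$collinearity_r2,
                    ref_eaf = study$ref_eaf[[g_id]],
                    h4_threshold = config$h4_threshold)
      dplyr::bind_cols(
        tibble::tibble(gene = g_id, profile = pf, outcome = out_name),
        res$pairs,
        tibble::tibble(max_h4 = res$max_h4,
                       colocalises = res$colocalises))
    })
  coloc <- if (length(coloc_rows) > 0) {
    dplyr::bind_rows(coloc_rows)
  } else {
    tibble::tibble(gene = character(), profile = character(),
                   outcome = character(), exposure_version = character(),
                   outcome_version = character(), h0 = numeric(),
                   h1 = numeric(), h2 = numeric(), h3 = numeric(),
                   h4 = numeric(), n_snps = integer(),
                   max_h4 = numeric(), colocalises = logical())
  }

  coloc_hits <- unique(coloc[coloc$colocalises,
                             c("gene", "profile", "outcome")])
  hit_leads <- unique(dplyr::inner_join(
    sig, coloc_hits, by = c("gene", "profile", "outcome"))[
      c("gene", "snp")])
  tissues <- if (nrow(hit_leads) > 0) {
    tissue_table <- study$tissue_table %||%
      make_multitissue_fixture(
        unique(hit_leads$snp), n_tissues = config$n_tissues,
        share_probability = config$share_probability,
        seed = config$seed)
    purrr::pmap_dfr(hit_leads, function(gene, snp) {
      tissue_share(gene, snp, tissue_table, ld = study$ld[[gene]],
                   p_threshold = config$tissue_p_threshold,
                   r2_min = config$proxy_r2_min,
                   positions = study$positions[[gene]])
    })
  } else {
    tibble::tibble(gene = character(), lead_id = character(),
                   used_id = character(), proxy_r2 = numeric(),
                   availability = character(), n_present = integer(),
                   n_significant = integer(),
                   proportion_significant = numeric(), tissues = list())
  }

  n_coloc_triples <- nrow(coloc_hits)
  manifest <- tibble::tibble(
    stage = c("tests_attempted", "instruments_found", "fdr_significant",
              "colocalised", "tissue_lookups"),
    count = c(length(study$exposures) * length(study$outcomes),
              nrow(mr), nrow(sig), n_coloc_triples, nrow(tissues)))
  stopifnot(manifest$count[4] <= manifest$count[3],
            manifest$count[3] <= manifest$count[2],
            manifest$count[2] <= manifest$count[1])

  result <- structure(list(mr = mr, coloc = coloc, tissues = tissues,
                           manifest = manifest, config = config),
                      class = "mr_pipeline")
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, force = force)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir, force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (file.exists(manifest_path) && !force) {
    inform("outputs already present; skipping write (use force = TRUE)")
    return(invisible(result))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$mr, file.path(out_dir, "mr_results.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$coloc, file.path(out_dir, "coloc_results.tsv"),
                   progress = FALSE)
  readr::write_tsv(dplyr::select(result$tissues, -dplyr::any_of("tissues")),
                   file.path(out_dir, "tissue_results.tsv"),
                   progress = FALSE)
  readr::write_tsv(result$manifest, manifest_path, progress = FALSE)
  invisible(result)
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat("<mr_pipeline>\n")
  print(x$manifest)
  invisible(x)
}

#' Report tables for a pipeline run
#'
#' Derives presentation tables from the persisted result tables: a volcano
#' table (effect vs -log10 p with subtype/timepoint parsed from the profile
#' label), the contribution of activation timepoints and cell subtypes
#' among FDR-significant results (proportions summing to 1), a gene x
#' outcome colocalisation matrix, and a tissue-sharing matrix with the
#' colon tissues broken out.
#'
#' @param result An `mr_pipeline` from [run_pipeline()].
#' @return A named list of tibbles: `volcano`, `timepoint_contribution`,
#'   `subtype_contribution`, `coloc_matrix`, `tissue_matrix`.
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "mr_pipeline"))
  mr <- result$mr
  if (nrow(mr) == 0) {
    warn("empty result bundle; report tables are empty")
  }
  split_profile <- function(x, i) {
    vapply(strsplit(x, "@", fixed = TRUE),
           function(p) if (length(p) >= i) p[i] else NA_character_, "")
  }
  volcano <- mr |>
    dplyr::transmute(
      gene = .data$gene, profile = .data$profile, outcome = .data$outcome,
      subtype = split_profile(.data$profile, 1),
      timepoint = split_profile(.data$profile, 2),
      effect = .data$wald_beta, neglog10_p = -log10(.data$pvalue),
      significant = .data$significant)

  sig <- volcano[volcano$significant %in% TRUE, , drop = FALSE]
  contribution <- function(var) {
    if (nrow(sig) == 0) {
      out <- tibble::tibble(category = character(), n = integer(),
                            proportion = numeric())
      names(out)[1] <- var
      return(out)
    }
    sig |>
      dplyr::count(dplyr::across(dplyr::all_of(var)), name = "n") |>
      dplyr::mutate(proportion = .data$n / sum(.data$n))
  }

  hits <- result$coloc[result$coloc$colocalises, , drop = FALSE]
  coloc_matrix <- if (nrow(hits) == 0) {
    tibble::tibble(gene = character(), outcome = character(),
                   profiles = character(), max_h4 = numeric())
  } else {
    hits |>
      dplyr::distinct(.data$gene, .data$profile, .data$outcome,
                      .data$max_h4) |>
      dplyr::group_by(.data$gene, .data$outcome) |>
      dplyr::summarise(profiles = paste(sort(unique(.data$profile)),
                                        collapse = "; "),
                       max_h4 = max(.data$max_h4), .groups = "drop")
  }

  tissue_matrix <- if (nrow(result$tissues) == 0) {
    tibble::tibble(gene = character(), lead = character(),
                   proxy = character(), proxy_r2 = numeric(),
                   sigmoid_colon = character(),
                   transverse_colon = character(),
                   pct_all_tissues = numeric())
  } else {
    colon_flag <- function(flags, tis) {
      row <- flags[flags$tissue == tis, , drop = FALSE]
      if (nrow(row) == 0 || !row$present) {
        "absent"
      } else if (isTRUE(row$significant)) "Y" else "N"
    }
    result$tissues |>
      dplyr::mutate(
        lead = .data$lead_id,
        proxy = dplyr::if_else(.data$availability == "proxy",
                               .data$used_id, NA_character_),
        sigmoid_colon = purrr::map_chr(.data$tissues, colon_flag,
                                       "Colon_Sigmoid"),
        transverse_colon = purrr::map_chr(.data$tissues, colon_flag,
                                          "Colon_Transverse"),
        pct_all_tissues = 100 * .data$proportion_significant) |>
      dplyr::select("gene", "lead", "proxy", "proxy_r2", "sigmoid_colon",
                    "transverse_colon", "pct_all_tissues")
  }

  list(volcano = volcano,
       timepoint_contribution = contribution("timepoint"),
       subtype_contribution = contribution("subtype"),
       coloc_matrix = coloc_matrix,
       tissue_matrix = tissue_matrix)
}
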