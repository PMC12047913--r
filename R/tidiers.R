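# broom-style tidiers for the package's result objects.

#' Tidy a pairwise-conditional-colocalisation result
#'
#' @param x A `pwcoco_result` from [pwcoco()].
#' @param ... Unused.
#' @return The per-pair posterior tibble (`exposure_version`,
#'   `outcome_version`, `h0`..`h4`, `n_snps`).
#' @method tidy pwcoco_result
#' @export
tidy.pwcoco_result <- function(x, ...) {
  x$pairs
}

#' @rdname tidy.pwcoco_result
#' @return `glance()`: a one-row tibble with `n_pairs`,
#'   `n_signals_exposure`, `n_signals_outcome`, `max_h4`, `colocalises`.
#' @method glance pwcoco_result
#' @export
glance.pwcoco_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 n_signals_exposure = nrow(x$signals_exposure),
                 n_signals_outcome = nrow(x$signals_outcome),
                 max_h4 = x$max_h4, colocalises = x$colocalises)
}

#' Tidy a colocalisation posterior
#'
#' @param x A `coloc_result` from [coloc_posteriors()] / [coloc_abf()].
#' @param ... Unused.
#' @return A long tibble with `hypothesis` (`"h0"`..`"h4"`) and
#'   `posterior`.
#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = paste0("h", 0:4),
                 posterior = c(x$h0, x$h1, x$h2, x$h3, x$h4))
}

#' Tidy and summarise a pipeline run
#'
#' @param x An `mr_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: the per-test MR result tibble. `glance()`: the stage
#'   counts of the run manifest as a one-row tibble.
#' @method tidy mr_pipeline
#' @export
tidy.mr_pipeline <- function(x, ...) {
  tibble::as_tibble(x$mr)
}

#' @rdname tidy.mr_pipeline
#' @method glance mr_pipeline
#' @export
glance.mr_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$manifest, names_from = "stage",
                     values_from = "count")
}

#' Summarise an MR screen
#'
#' @param x An `mr_screen` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of tests, outcomes, significant results,
#'   and the smallest q-value.
#' @method glance mr_screen
#' @export
glance.mr_screen <- function(x, ...) {
  tibble::tibble(n_tests = nrow(x),
                 n_outcomes = dplyr::n_distinct(x$outcome),
                 n_significant = sum(x$significant, na.rm = TRUE),
                 min_fdr_q = if (nrow(x) > 0) min(x$fdr_q) else NA_real_)
}
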