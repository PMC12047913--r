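# ggplot2 visualisations for the result objects.

#' Volcano plot of an MR screen
#'
#' Wald-ratio effect (log OR per SD expression) against -log10 p, coloured
#' by FDR significance and faceted by outcome when several strata are
#' present.
#'
#' @param object An `mr_screen` tibble from [mr_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_screen
#' @export
autoplot.mr_screen <- function(object, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$wald_beta, y = -log10(.data$pvalue),
                 colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "log OR of outcome per SD expression",
                  y = expression(-log[10](italic(p))),
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$outcome) > 1) {
    p <- p + ggplot2::facet_wrap(~outcome)
  }
  p
}

#' Posterior bar chart of a pairwise conditional colocalisation
#'
#' One panel per dataset pair (marginal and conditional versions), bars for
#' the five hypothesis posteriors, with the H4 decision threshold marked.
#'
#' @param object A `pwcoco_result` from [pwcoco()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pwcoco_result
#' @export
autoplot.pwcoco_result <- function(object, ...) {
  long <- object$pairs |>
    dplyr::mutate(pair = paste(.data$exposure_version,
                               .data$outcome_version, sep = " x ")) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("h", 0:4)),
                        names_to = "hypothesis", values_to = "posterior")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$hypothesis,
                                     y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$h4_threshold,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Regional association plot of a simulated scenario
#'
#' -log10 p against position for the first exposure profile and the
#' outcome, with the true causal variants marked — a quick visual check of
#' what a scenario generated.
#'
#' @param object An `mr_scenario` from [make_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_scenario
#' @export
autoplot.mr_scenario <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$exposures[[1]]),
                  trait = "exposure"),
    dplyr::mutate(tibble::as_tibble(object$outcome), trait = "outcome"))
  causal <- tibble::tibble(
    trait = c(rep("exposure", length(object$truth$causal_exposure)),
              rep("outcome", length(object$truth$causal_outcome))),
    snp = c(names(object$truth$causal_exposure),
            names(object$truth$causal_outcome)))
  causal <- dplyr::inner_join(causal, df[c("trait", "snp", "pos", "p")],
                              by = c("trait", "snp"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = causal, colour = "red", shape = 17,
                        size = 2) +
    ggplot2::facet_wrap(~trait, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](italic(p))),
                  title = sprintf("scenario: %s", object$truth$kind)) +
    ggplot2::theme_minimal()
}

#' Tissue-sharing tile plot
#'
#' Present/absent/significant status of each gene's lookup variant across
#' the tissue panel.
#'
#' @param tissues The `tissues` tibble of an `mr_pipeline`, or the output
#'   of [tissue_share()] rows bound together.
#' @return A ggplot object.
#' @export
plot_tissue_share <- function(tissues) {
  long <- tissues |>
    dplyr::select("gene", "tissues") |>
    tidyr::unnest("tissues") |>
    dplyr::mutate(status = dplyr::case_when(
      !.data$present ~ "absent",
      .data$significant ~ "significant",
      TRUE ~ "not significant"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$gene,
                                     fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
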