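# Multi-tissue eQTL lookup: is a gene's lead eQTL (or an LD proxy) also a
# tissue eQTL elsewhere?

#' Find the variant to use in a tissue lookup: the lead or its best proxy
#'
#' Returns the lead variant itself when it is present in the lookup table;
#' otherwise the available variant in highest LD with the lead, provided
#' `r^2 >= r2_min`. Ties on r^2 are broken by smaller base-pair distance to
#' the lead (when `positions` are supplied), then by id.
#'
#' @param lead_id Lead variant id.
#' @param available_ids Variant ids present in the tissue table.
#' @param ld LD correlation matrix covering the lead (lookup error if
#'   absent) and any candidates.
#' @param r2_min Minimum proxy r^2 (default 0.8).
#' @param positions Optional named vector of base-pair positions for
#'   distance tie-breaks.
#' @return One-row tibble `used_id`, `proxy_r2`, or `NULL` when neither the
#'   lead nor an adequate proxy is available.
#' @export
proxy_lookup <- function(lead_id, available_ids, ld, r2_min = 0.8,
                         positions = NULL) {
  if (!lead_id %in% rownames(ld)) {
    data_error(sprintf("lead variant %s missing from LD matrix", lead_id))
  }
  if (lead_id %in% available_ids) {
    return(tibble::tibble(used_id = lead_id, proxy_r2 = 1))
  }
  cand <- intersect(available_ids, rownames(ld))
  if (length(cand) == 0) {
    return(NULL)
  }
  r2 <- ld[lead_id, cand]^2
  dist <- if (!is.null(positions)) {
    abs(positions[cand] - positions[lead_id])
  } else {
    rep(0, length(cand))
  }
  ord <- order(-r2, dist, cand)
  best <- ord[1]
  if (r2[best] < r2_min) {
    return(NULL)
  }
  tibble::tibble(used_id = cand[best], proxy_r2 = unname(r2[best]))
}

#' Cross-tissue sharing of a gene's lead eQTL
#'
#' Looks the gene's lead variant (or its best LD proxy, see
#' [proxy_lookup()]) up in a per-tissue eQTL table and flags each tissue
#' where the variant is present and genome-wide significant
#' (`p < p_threshold`). The sharing proportion is the significant count
#' over the tissues where the variant is *present* (tissues where it is
#' absent do not enter the denominator). When neither the lead nor a proxy
#' is available the result is an NA row with `availability = "none"`.
#'
#' @param gene Gene id (label only).
#' @param lead_id Lead variant id.
#' @param tissue_table Tibble with columns `tissue`, `snp`, `p` (one row
#'   per tissue x variant present in the resource).
#' @param ld LD matrix covering the lead variant.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_min Minimum proxy r^2 (default 0.8).
#' @param positions Optional positions for proxy tie-breaks.
#' @return One-row tibble: `gene`, `lead_id`, `used_id`, `proxy_r2`,
#'   `availability` (`"lead"`, `"proxy"` or `"none"`), `n_present`,
#'   `n_significant`, `proportion_significant`, and a list-column
#'   `tissues` holding the per-tissue flags (`tissue`, `present`,
#'   `significant`, `is_colon`).
#' @export
tissue_share <- function(gene, lead_id, tissue_table, ld,
                         p_threshold = 5e-8, r2_min = 0.8,
                         positions = NULL) {
  all_tissues <- sort(unique(tissue_table$tissue))
  px <- proxy_lookup(lead_id, unique(tissue_table$snp), ld,
                     r2_min = r2_min, positions = positions)
  if (is.null(px)) {
    return(tibble::tibble(
      gene = gene, lead_id = lead_id, used_id = NA_character_,
      proxy_r2 = NA_real_, availability = "none",
      n_present = NA_integer_, n_significant = NA_integer_,
      proportion_significant = NA_real_,
      tissues = list(tibble::tibble(
        tissue = all_tissues, present = FALSE, significant = NA,
        is_colon = grepl("colon", all_tissues, ignore.case = TRUE)))))
  }
  hits <- tissue_table[tissue_table$snp == px$used_id, , drop = FALSE]
  flags <- tibble::tibble(tissue = all_tissues) |>
    dplyr::left_join(hits[c("tissue", "p")], by = "tissue") |>
    dplyr::mutate(present = !is.na(.data$p),
                  significant = dplyr::if_else(.data$present,
                                               .data$p < p_threshold, NA),
                  is_colon = grepl("colon", .data$tissue,
                                   ignore.case = TRUE)) |>
    dplyr::select(-"p")
  n_present <- sum(flags$present)
  n_sig <- sum(flags$significant, na.rm = TRUE)
  tibble::tibble(
    gene = gene, lead_id = lead_id, used_id = px$used_id,
    proxy_r2 = px$proxy_r2,
    availability = if (px$used_id == lead_id) "lead" else "proxy",
    n_present = n_present, n_significant = n_sig,
    proportion_significant = if (n_present > 0) n_sig / n_present
                             else NA_real_,
    tissues = list(flags))
}
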