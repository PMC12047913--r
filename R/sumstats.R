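#' Build a validated summary-statistics dataset
#'
#' Coerces a data frame of per-variant association statistics into a
#' `sumstats` tibble — the container used by every stage of the package.
#' Rows violating the record invariants are dropped, with counts recorded in
#' the `drop_log` attribute and reported via a message:
#'
#' * missing values in a mandatory field;
#' * `se <= 0`, `eaf` outside (0, 1), `p` outside (0, 1];
#' * non-SNP alleles (indels, multi-allelic, `ea == nea`);
#' * duplicated variant id (first kept);
#' * `|z|` implied by `p` inconsistent with `beta/se` by more than 10%
#'   (checked where `|z| > 1`, where the relative comparison is meaningful);
#' * position outside `region`, when a region is declared.
#'
#' @param x Data frame with columns `snp`, `chr`, `pos`, `ea`, `nea`, `eaf`,
#'   `beta`, `se`, `p`, `n` (and `n_case`, `n_control` for case-control
#'   traits). `beta` is per effect allele: SD units of a standardised trait
#'   for quantitative traits, log-odds for case-control traits.
#' @param trait_id Label for the trait (e.g. a gene x cell-state profile or
#'   an outcome stratum).
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param region Optional list `list(chr =, start =, end =)` (1-based,
#'   closed) that all records must fall inside.
#' @param trait_sd SD of a quantitative trait (default 1: expression traits
#'   are standardised so effects are per SD).
#' @param validate Set `FALSE` to skip row filtering (internal generators
#'   produce already-valid rows).
#' @return A tibble of class `sumstats` with attributes `trait_id`,
#'   `trait_type`, `trait_sd`, `region`, `drop_log`.
#' @export
as_sumstats <- function(x, trait_id = "trait",
                        trait_type = c("quantitative", "case_control"),
                        region = NULL, trait_sd = 1, validate = TRUE) {
  trait_type <- match.arg(trait_type)
  need <- c("snp", "chr", "pos", "ea", "nea", "eaf", "beta", "se", "p", "n")
  if (trait_type == "case_control") need <- c(need, "n_case", "n_control")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    data_error(sprintf("missing mandatory column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)[union(need, names(x))]
  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  drop_log <- tibble::tibble(reason = character(), n = integer())

  if (validate) {
    drop <- function(keep, reason) {
      n_bad <- sum(!keep)
      if (n_bad > 0) {
        drop_log <<- dplyr::bind_rows(drop_log,
                                      tibble::tibble(reason = reason,
                                                     n = n_bad))
        x <<- x[keep, , drop = FALSE]
      }
    }
    num <- c("pos", "eaf", "beta", "se", "p", "n")
    drop(stats::complete.cases(x[c("snp", "chr", "ea", "nea", num)]) &
           apply(is.finite(as.matrix(x[num])), 1, all), "missing_value")
    drop(x$se > 0, "nonpositive_se")
    drop(x$eaf > 0 & x$eaf < 1, "eaf_out_of_range")
    drop(x$p > 0 & x$p <= 1, "pvalue_out_of_range")
    snp_allele <- function(a) a %in% c("A", "C", "G", "T")
    drop(snp_allele(x$ea) & snp_allele(x$nea) & x$ea != x$nea,
         "not_a_biallelic_snp")
    drop(!duplicated(x$snp), "duplicated_id")
    z_bs <- abs(x$beta / x$se)
    z_p <- p_to_z(x$p)
    drop(!(z_bs > 1 & abs(z_p - z_bs) > 0.1 * z_bs), "z_p_inconsistent")
    if (!is.null(region)) {
      drop(x$chr == as.character(region$chr) &
             x$pos >= region$start & x$pos <= region$end, "outside_region")
    }
    if (sum(drop_log$n) > 0) {
      inform(sprintf("as_sumstats: dropped %d row(s) [%s]", sum(drop_log$n),
                     paste(sprintf("%s: %d", drop_log$reason, drop_log$n),
                           collapse = "; ")))
    }
    if (nrow(x) == 0) {
      abort("no valid rows after filtering", class = "mrcoco_empty_dataset")
    }
  }

  structure(x,
            class = c("sumstats", class(tibble::tibble())),
            trait_id = trait_id, trait_type = trait_type,
            trait_sd = trait_sd, region = region, drop_log = drop_log)
}

# Rebuild attributes after dplyr verbs (which strip custom attrs).
restat <- function(x, template, ...) {
  dots <- list(...)
  structure(tibble::as_tibble(x),
            class = c("sumstats", class(tibble::tibble())),
            trait_id = dots$trait_id %||% attr(template, "trait_id"),
            trait_type = dots$trait_type %||% attr(template, "trait_type"),
            trait_sd = dots$trait_sd %||% attr(template, "trait_sd"),
            region = dots$region %||% attr(template, "region"),
            drop_log = attr(template, "drop_log"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  NextMethod()
}

#' Trait type and effective sample size helpers
#'
#' `trait_type()` returns the declared trait type of a `sumstats` object.
#' `effective_n()` returns the per-variant effective sample size: `n` for
#' quantitative traits and `4 / (1/n_case + 1/n_control)` for case-control
#' traits (the balanced-design equivalent).
#'
#' @param x A `sumstats` tibble.
#' @return `trait_type()`: a string; `effective_n()`: a numeric vector.
#' @export
trait_type <- function(x) {
  attr(x, "trait_type") %||%
    (if ("n_case" %in% names(x)) "case_control" else "quantitative")
}

#' @rdname trait_type
#' @export
effective_n <- function(x) {
  if (trait_type(x) == "case_control") {
    if (!all(c("n_case", "n_control") %in% names(x))) {
      data_error("case-control dataset lacks n_case/n_control")
    }
    4 / (1 / x$n_case + 1 / x$n_control)
  } else {
    if (!"n" %in% names(x)) data_error("dataset lacks sample size column n")
    x$n
  }
}

# ---------------------------------------------------------------------------
# File I/O: tab-separated, one header row, gzip-transparent.

#' Column dialect for summary-statistics files
#'
#' Maps the internal column names to the headers used on disk. The default
#' matches a common GWAS export layout (`SNP CHR POS EA NEA EAF BETA SE P N
#' [N_CASE N_CONTROL]`). There is no auto-sniffing: the dialect is declared.
#'
#' @param ... Overrides, e.g. `snp = "rsid"`.
#' @return Named character vector (internal name -> file header).
#' @export
sumstats_dialect <- function(...) {
  d <- c(snp = "SNP", chr = "CHR", pos = "POS", ea = "EA", nea = "NEA",
         eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N",
         n_case = "N_CASE", n_control = "N_CONTROL")
  over <- c(...)
  d[names(over)] <- over
  d
}

#' Read and write summary-statistics files
#'
#' Tab-separated with one header row; `.gz` paths are handled transparently
#' by readr. Rows violating the record invariants are dropped at read time
#' with logged counts (see [as_sumstats()]). A missing mandatory column is a
#' format error naming the column; a file with zero valid rows is an
#' empty-dataset error.
#'
#' @param path File path.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait_id,trait_type,region,trait_sd Passed to [as_sumstats()];
#'   `trait_type = NULL` infers `"case_control"` when the case/control count
#'   columns are present.
#' @return `read_sumstats()`: a `sumstats` tibble. `write_sumstats()`: the
#'   input, invisibly.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_id = basename(path), trait_type = NULL,
                          region = NULL, trait_sd = 1) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  have_cc <- all(dialect[c("n_case", "n_control")] %in% names(raw))
  if (is.null(trait_type)) {
    trait_type <- if (have_cc) "case_control" else "quantitative"
  }
  need <- c("snp", "chr", "pos", "ea", "nea", "eaf", "beta", "se", "p", "n")
  if (trait_type == "case_control") need <- c(need, "n_case", "n_control")
  missing_cols <- setdiff(dialect[need], names(raw))
  if (length(missing_cols) > 0) {
    data_error(sprintf("file %s lacks mandatory column(s): %s", path,
                       paste(missing_cols, collapse = ", ")))
  }
  keep <- intersect(dialect, names(raw))
  out <- raw[keep]
  names(out) <- names(dialect)[match(keep, dialect)]
  as_sumstats(out, trait_id = trait_id, trait_type = trait_type,
              region = region, trait_sd = trait_sd)
}

#' @rdname read_sumstats
#' @param x A `sumstats` tibble.
#' @export
write_sumstats <- function(x, path, dialect = sumstats_dialect()) {
  cols <- intersect(names(dialect), names(x))
  out <- x[cols]
  names(out) <- dialect[cols]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Read and write a dense LD matrix
#'
#' Tab-separated: a leading `SNP` id column plus one column per variant id.
#'
#' @param x Square correlation matrix with variant-id dimnames.
#' @param path File path.
#' @return `read_ld_matrix()`: a numeric matrix; `write_ld_matrix()`: the
#'   input, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  df <- tibble::as_tibble(x, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(SNP = rownames(x)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(x)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}
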