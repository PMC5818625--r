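# Reading differential-expression tables, classifying genes by direction
# of regulation, and joining with seed-match annotations.

#' Read a differential-expression table
#'
#' TSV with mandatory columns `gene_id` and `log2FC` (treated vs control)
#' and optional `pvalue` / `padj`. Missing numeric cells (empty or "NA")
#' become `NA`, never 0.
#'
#' @param path Path to a TSV file.
#' @return Tibble `gene_id`, `log2FC`, `pvalue`, `padj`.
#' @export
read_de_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA", "NaN"))
  miss <- setdiff(c("gene_id", "log2FC"), names(tab))
  if (length(miss))
    abort(paste0("DE table is missing mandatory column(s): ",
                 paste(miss, collapse = ", ")))
  parse_num <- function(x, col) {
    y <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(y))
    if (length(bad))
      abort(sprintf("non-numeric value '%s' in column %s at row %d",
                    x[bad[1L]], col, bad[1L]))
    y
  }
  tibble(
    gene_id = tab$gene_id,
    log2FC = parse_num(tab$log2FC, "log2FC"),
    pvalue = if ("pvalue" %in% names(tab)) parse_num(tab$pvalue, "pvalue") else NA_real_,
    padj = if ("padj" %in% names(tab)) parse_num(tab$padj, "padj") else NA_real_)
}

#' Classify genes by direction of regulation
#'
#' A gene is `down` when `padj <= alpha` and `log2FC < -min_abs_lfc`, `up`
#' when `padj <= alpha` and `log2FC > min_abs_lfc`, `excluded` when `padj`
#' is missing (genes the upstream tool never tested, e.g. independent
#' filtering casualties), and `unchanged` otherwise. The labels partition
#' the input. The default threshold (adjusted p <= 0.05, no fold-change
#' cutoff) matches the convention of volcano-plot significance colouring.
#'
#' @param de Tibble with `gene_id`, `log2FC`, `padj` (e.g. from
#'   [read_de_table()] or [call_de()]).
#' @param alpha Adjusted-p significance threshold, in (0, 1).
#' @param min_abs_lfc Minimum |log2FC| beyond which direction is assigned
#'   (default 0).
#' @return The input with a `label` factor column added.
#' @export
classify_de <- function(de, alpha = 0.05, min_abs_lfc = 0) {
  stopifnot(is.data.frame(de), all(c("gene_id", "log2FC", "padj") %in% names(de)))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    abort("alpha must lie in (0, 1)")
  if (min_abs_lfc < 0) abort("min_abs_lfc must be non-negative")
  de %>%
    mutate(label = case_when(
      is.na(.data$padj) ~ "excluded",
      .data$padj <= alpha & .data$log2FC < -min_abs_lfc ~ "down",
      .data$padj <= alpha & .data$log2FC > min_abs_lfc ~ "up",
      TRUE ~ "unchanged"))
}

#' Join regulation labels with seed-match annotations
#'
#' Genes with a DE label but no UTR record are dropped and tallied in the
#' `n_no_utr` attribute (they cannot be scored for seed matches); genes
#' with a UTR but no DE record are ignored. `has_match` is presence/absence
#' (`count >= 1`): the downstream Fisher test dichotomizes at the gene
#' level.
#'
#' @param classes Output of [classify_de()].
#' @param matches Output of [scan_set()].
#' @return Long tibble `gene_id`, `label`, `spec_label`, `site`, `count`,
#'   `has_match`, with attribute `n_no_utr`.
#' @export
join_matches <- function(classes, matches) {
  stopifnot(is.data.frame(classes), is.data.frame(matches),
            all(c("gene_id", "label") %in% names(classes)),
            all(c("gene_id", "spec_label", "count") %in% names(matches)))
  common <- intersect(classes$gene_id, matches$gene_id)
  if (length(common) == 0L)
    abort("no genes shared between the DE table and the UTR scan")
  n_no_utr <- length(setdiff(classes$gene_id, matches$gene_id))
  out <- classes %>%
    select("gene_id", "label") %>%
    inner_join(select(matches, "gene_id", "spec_label", "site", "count"),
               by = "gene_id") %>%
    mutate(has_match = .data$count >= 1L)
  attr(out, "n_no_utr") <- n_no_utr
  out
}
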