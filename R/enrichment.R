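# Seed-match enrichment: 2x2 contingency tables (seed match x regulation
# direction) and Fisher's exact test, computed in log space so that
# transcriptome-scale margins (~2e4 genes and beyond) stay overflow-safe.
#
# The primary statistic is the one-sided tail P(X >= a) of the central
# hypergeometric law with the observed margins — enrichment of seed matches
# among the chosen direction class. The two-sided minimum-likelihood p is
# reported alongside.

.logsumexp <- function(lp) {
  if (!length(lp)) return(-Inf)
  m <- max(lp)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lp - m)))
}

# log point probabilities of the hypergeometric family sharing the table's
# margins, over the full support, plus the index of the observed table
.hyper_family <- function(a, b, c, d) {
  r <- a + b            # size of the direction class
  k <- a + c            # genes with a seed match
  n <- a + b + c + d
  lo <- max(0L, r + k - n)
  hi <- min(r, k)
  x <- lo:hi
  lp <- lchoose(k, x) + lchoose(n - k, r - x) - lchoose(n, r)
  list(x = x, lp = lp, obs = match(a, x))
}

.check_table <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
    abort("contingency counts must be non-negative integers")
  if (sum(v) < 1) abort("contingency table is empty")
  invisible(NULL)
}

.fisher1 <- function(a, b, c, d) {
  f <- .hyper_family(a, b, c, d)
  min(exp(.logsumexp(f$lp[f$x >= a])), 1)
}

.fisher2 <- function(a, b, c, d) {
  f <- .hyper_family(a, b, c, d)
  # minimum-likelihood two-sided rule with a small relative tolerance so
  # ties in point probability are kept on both sides
  keep <- f$lp <= f$lp[f$obs] + 1e-7
  min(exp(.logsumexp(f$lp[keep])), 1)
}

#' One-sided Fisher's exact test for seed-match enrichment
#'
#' For a table `(a, b, c, d)` = (down & match, down & no match, other &
#' match, other & no match), returns `P(X >= a)` under the central
#' hypergeometric distribution with the table's margins: the probability of
#' an enrichment of matches in the direction class at least as strong as
#' observed.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @return p-value(s) in (0, 1].
#' @examples
#' fisher_one_sided(3, 0, 0, 3)  # 1/20
#' @export
fisher_one_sided <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    .check_table(a, b, c, d)
    .fisher1(a, b, c, d)
  }, a, b, c, d)
}

#' Two-sided Fisher's exact test (minimum-likelihood rule)
#'
#' Sums the probabilities of all margin-compatible tables whose point
#' probability does not exceed that of the observed table.
#'
#' @inheritParams fisher_one_sided
#' @return p-value(s) in (0, 1].
#' @export
fisher_two_sided <- function(a, b, c, d) {
  mapply(function(a, b, c, d) {
    .check_table(a, b, c, d)
    .fisher2(a, b, c, d)
  }, a, b, c, d)
}

#' Build a seed-match x direction contingency table
#'
#' Rows labelled `excluded` (untested genes) are removed first; the
#' complement class pools every remaining non-excluded gene, so the table
#' total equals the number of tested genes with a UTR.
#'
#' @param analysis Long analysis table from [join_matches()].
#' @param spec_label Which seed window to tabulate (e.g. `"antisense_2_8"`).
#' @param direction `"down"` or `"up"`.
#' @return One-row tibble `spec_label`, `direction`, `a`, `b`, `c`, `d`.
#' @export
build_table <- function(analysis, spec_label, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(analysis),
            all(c("gene_id", "label", "spec_label", "has_match") %in% names(analysis)))
  sub <- analysis %>%
    filter(.data$spec_label == .env$spec_label, .data$label != "excluded")
  if (nrow(sub) == 0L)
    abort(sprintf("no tested genes for spec '%s'", spec_label))
  in_dir <- sub$label == direction
  tibble(spec_label = spec_label,
         direction = direction,
         a = sum(in_dir & sub$has_match),
         b = sum(in_dir & !sub$has_match),
         c = sum(!in_dir & sub$has_match),
         d = sum(!in_dir & !sub$has_match))
}

.odds_ratio <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  or <- ifelse(zero,
               (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)),
               a * d / (b * c))
  list(odds_ratio = or, haldane = zero)
}

#' Run the seed-enrichment analysis over windows and directions
#'
#' Computes one [build_table()] + Fisher result per (seed window,
#' direction) pair. The scientific signal is antisense-down; sense-down and
#' antisense-up act as strand and direction controls, expected to be null
#' when off-target repression is seed mediated.
#'
#' Odds ratios use the Haldane 0.5 continuity correction only when a zero
#' cell is present, flagged in the `haldane` column.
#'
#' @param analysis Long analysis table from [join_matches()].
#' @param spec_labels Seed windows to test (default: all present).
#' @param directions Direction classes to test (default `c("down", "up")`).
#' @param bonferroni Add a `p_adj` column with Bonferroni correction across
#'   the tested (window, direction) pairs (default `FALSE`: per-panel
#'   p-values are reported as-is).
#' @return A `seed_enrichment` tibble: `spec_label`, `direction`, `a`-`d`,
#'   `odds_ratio`, `haldane`, `p_one_sided`, `p_two_sided`.
#' @export
run_enrichment <- function(analysis, spec_labels = NULL,
                           directions = c("down", "up"),
                           bonferroni = FALSE) {
  stopifnot(is.data.frame(analysis))
  spec_labels <- spec_labels %||% unique(analysis$spec_label)
  if (!length(spec_labels) || !length(directions))
    abort("at least one seed window and one direction are required")
  grid <- tidyr::expand_grid(spec_label = spec_labels, direction = directions)
  out <- purrr::pmap_dfr(grid, function(spec_label, direction) {
    build_table(analysis, spec_label, direction)
  })
  or <- .odds_ratio(out$a, out$b, out$c, out$d)
  out <- out %>%
    mutate(odds_ratio = or$odds_ratio,
           haldane = or$haldane,
           p_one_sided = fisher_one_sided(.data$a, .data$b, .data$c, .data$d),
           p_two_sided = fisher_two_sided(.data$a, .data$b, .data$c, .data$d))
  if (bonferroni)
    out <- mutate(out, p_adj = pmin(.data$p_one_sided * nrow(out), 1))
  class(out) <- c("seed_enrichment", class(out))
  out
}

#' Export a volcano-plot table annotated by seed-match status
#'
#' One row per gene shared between the DE table and the scan: log2 fold
#' change, -log10 adjusted p (zeros clamped to the smallest positive
#' double before the log), seed-match status for the chosen window, and
#' the regulation class.
#'
#' @param de DE tibble (`gene_id`, `log2FC`, `padj`).
#' @param matches Output of [scan_set()].
#' @param spec_label Seed window to annotate by.
#' @param alpha,min_abs_lfc Classification thresholds, as in
#'   [classify_de()].
#' @return Tibble `gene_id`, `log2FC`, `neg_log10_padj`, `has_match`,
#'   `class`, of class `seed_volcano`.
#' @export
volcano_export <- function(de, matches, spec_label = "antisense_2_8",
                           alpha = 0.05, min_abs_lfc = 0) {
  joined <- join_matches(classify_de(de, alpha, min_abs_lfc), matches) %>%
    filter(.data$spec_label == .env$spec_label)
  if (nrow(joined) == 0L) abort(sprintf("no genes for spec '%s'", spec_label))
  out <- de %>%
    select("gene_id", "log2FC", "padj") %>%
    inner_join(select(joined, "gene_id", "has_match", class = "label"),
               by = "gene_id") %>%
    mutate(neg_log10_padj = -log10(pmax(.data$padj, .Machine$double.xmin)),
           .after = "log2FC") %>%
    select(-"padj")
  class(out) <- c("seed_volcano", class(out))
  out
}
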