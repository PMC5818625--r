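# Scanning 3'UTR sets for perfect seed-complementary sites.
#
# Matching is exact substring matching on the forward strand of the UTR;
# occurrences may overlap, coordinates are 1-based fully closed, and any
# window containing N never matches.

#' Load 3'UTR sequences from FASTA
#'
#' Gene identifiers are the first whitespace-delimited token of each
#' header. Sequences are upper-cased and U is converted to T, so RNA-style
#' UTR files are accepted. When a gene has several isoform UTRs the
#' `selection` rule reduces them to one record: `"longest"` (default, ties
#' broken by file order), `"first"`, or `"concatenate"` (file order).
#'
#' @param fasta Path to a FASTA file.
#' @param selection Per-gene isoform rule.
#' @return Tibble with columns `gene_id`, `sequence`, `length`.
#' @export
load_utrs <- function(fasta, selection = c("longest", "first", "concatenate")) {
  selection <- match.arg(selection)
  set <- Biostrings::readBStringSet(fasta)
  if (length(set) == 0L) abort("FASTA file contains no records")
  seqs <- chartr("U", "T", toupper(as.character(set)))
  if (any(!nzchar(seqs))) abort("FASTA contains a zero-length record")
  bad <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(bad))
    abort(sprintf("record '%s' contains non-ACGTN characters", names(seqs)[bad][1L]))
  utrs <- tibble(
    gene_id = stringr::str_split_i(names(seqs), "\\s+", 1L),
    sequence = unname(seqs))
  gene_order <- unique(utrs$gene_id)
  utrs <- switch(
    selection,
    longest = utrs %>%
      group_by(.data$gene_id) %>%
      slice(which.max(nchar(.data$sequence))) %>%
      ungroup(),
    first = utrs %>% distinct(.data$gene_id, .keep_all = TRUE),
    concatenate = utrs %>%
      group_by(.data$gene_id) %>%
      summarise(sequence = paste(.data$sequence, collapse = ""),
                .groups = "drop"))
  utrs %>%
    mutate(length = nchar(.data$sequence)) %>%
    arrange(match(.data$gene_id, gene_order))
}

.check_site <- function(site) {
  if (!is.character(site) || length(site) != 1L || is.na(site) || !nzchar(site))
    abort("site must be a non-empty DNA string")
  if (stringr::str_detect(site, "[^ACGT]"))
    abort("site must contain only A/C/G/T (no N or ambiguity codes)")
  invisible(site)
}

# overlap-counting exact matcher without position bookkeeping
.count_sites <- function(sequences, site) {
  Biostrings::vcountPattern(site, Biostrings::DNAStringSet(sequences),
                            fixed = TRUE)
}

#' Scan UTRs for exact occurrences of a site
#'
#' Counts all (possibly overlapping) exact occurrences of `site` in each
#' UTR sequence; windows containing N never match.
#'
#' @param utrs Tibble as returned by [load_utrs()] (columns `gene_id`,
#'   `sequence`).
#' @param site DNA string (typically the 7mer from [seed_site()]).
#' @return Tibble with columns `gene_id`, `site`, `count` and a `positions`
#'   list-column of 1-based match start coordinates.
#' @export
scan_utrs <- function(utrs, site) {
  stopifnot(is.data.frame(utrs), all(c("gene_id", "sequence") %in% names(utrs)))
  .check_site(site)
  subject <- Biostrings::DNAStringSet(utrs$sequence)
  hits <- Biostrings::vmatchPattern(site, subject, fixed = TRUE)
  starts <- Biostrings::startIndex(hits)
  starts <- lapply(starts, function(x) as.integer(x %||% integer()))
  tibble(gene_id = utrs$gene_id,
         site = site,
         count = lengths(starts),
         positions = starts)
}

#' Tabulate seed matches for a duplex over a UTR set
#'
#' For each seed window in `specs`, derives the complementary mRNA site via
#' [seed_site()] and scans every UTR. The result is complete: every
#' (gene, spec) combination appears, with zero counts rather than missing
#' rows.
#'
#' @param utrs Tibble from [load_utrs()].
#' @param duplex A `sirna_duplex`.
#' @param specs List of [seed_spec()] objects (default: antisense and sense
#'   nucleotides 2-8).
#' @return Long tibble `gene_id`, `spec_label`, `site`, `count`,
#'   `positions`.
#' @export
scan_set <- function(utrs, duplex,
                     specs = list(seed_spec("antisense"), seed_spec("sense"))) {
  stopifnot(inherits(duplex, "sirna_duplex"), is.list(specs))
  if (length(specs) == 0L)
    return(tibble(gene_id = character(), spec_label = character(),
                  site = character(), count = integer(),
                  positions = list()))
  purrr::map_dfr(specs, function(sp) {
    stopifnot(inherits(sp, "seed_spec"))
    scan_utrs(utrs, seed_site(duplex, sp)) %>%
      mutate(spec_label = sp$label, .after = "gene_id")
  })
}

#' Write a seed-match table to TSV
#'
#' Positions are comma-joined into a single column.
#'
#' @param matches Tibble from [scan_utrs()] or [scan_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(matches, path) {
  out <- matches %>%
    mutate(positions = purrr::map_chr(.data$positions, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}
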