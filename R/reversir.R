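# Complementarity screening of short REVERSIR-style oligonucleotides
# against miRNA sequence lists.
#
# A REVERSIR oligo silences loaded RISC by pairing with the siRNA antisense
# strand; before use it must be confirmed to have no full complementarity
# to any relevant (e.g. liver-expressed) miRNA it might block instead. The
# screen reports every miRNA window that is the exact reverse complement of
# the whole oligo; an empty result is the "clean" verdict. Which miRNAs
# count as expressed in the target tissue is the caller's choice — the
# screen takes whatever list it is given.

#' Read miRNA sequences from FASTA
#'
#' miRBase-style headers are accepted; the identifier is the first
#' whitespace-delimited token. Sequences are upper-cased and canonicalized
#' to the U alphabet.
#'
#' @param fasta Path to a FASTA file.
#' @return Tibble `mir_id`, `sequence`.
#' @export
read_mirna_fasta <- function(fasta) {
  set <- Biostrings::readBStringSet(fasta)
  if (length(set) == 0L) abort("FASTA file contains no records")
  seqs <- chartr("T", "U", toupper(as.character(set)))
  if (any(!nzchar(seqs))) abort("FASTA contains a zero-length record")
  tibble(mir_id = stringr::str_split_i(names(seqs), "\\s+", 1L),
         sequence = unname(seqs))
}

# does oligo base b1 pair with target base b2? (both RNA letters)
.pairs_with <- function(b1, b2, wobble = FALSE) {
  wc <- .complement_pairs(b1, b2)
  if (!wobble) return(wc)
  wc | (b1 == "G" & b2 == "U") | (b1 == "U" & b2 == "G")
}

#' Screen an oligonucleotide for full complementarity to miRNAs
#'
#' Reports a hit for every position at which the *entire* oligo is
#' Watson-Crick paired with a contiguous miRNA window (antiparallel, i.e.
#' the window equals the oligo's reverse complement). G·U wobble pairs are
#' not counted as complementary unless `wobble = TRUE`.
#'
#' @param oligo Base string (RNA or DNA letters), 6-30 nt.
#' @param mirnas Tibble `mir_id`, `sequence` (e.g. [read_mirna_fasta()]).
#' @param oligo_id Identifier recorded in the output.
#' @param wobble Also accept G·U pairs (default `FALSE`: strict).
#' @return Tibble `oligo_id`, `mir_id`, `start` (1-based offset of the
#'   complementary window within the miRNA), `window_length`, `window`.
#'   Zero rows mean the oligo is clean.
#' @export
screen_reversir <- function(oligo, mirnas, oligo_id = "oligo", wobble = FALSE) {
  stopifnot(is.data.frame(mirnas),
            all(c("mir_id", "sequence") %in% names(mirnas)))
  if (!is.character(oligo) || length(oligo) != 1L || is.na(oligo))
    abort("oligo must be a single base string")
  oligo <- chartr("T", "U", toupper(oligo))
  w <- nchar(oligo)
  if (w < 6L || w > 30L) abort("oligo length must be between 6 and 30 nt")
  ob <- strsplit(oligo, "", fixed = TRUE)[[1L]]
  if (!all(ob %in% c("A", "C", "G", "U"))) abort("oligo contains invalid characters")
  empty <- tibble(oligo_id = character(), mir_id = character(),
                  start = integer(), window_length = integer(),
                  window = character())
  if (nrow(mirnas) == 0L) return(empty)
  if (all(nchar(mirnas$sequence) < w)) {
    warn("oligo is longer than every miRNA in the list; nothing can be screened")
    return(empty)
  }
  hits <- purrr::pmap_dfr(mirnas, function(mir_id, sequence, ...) {
    seq <- chartr("T", "U", toupper(sequence))
    mb <- strsplit(seq, "", fixed = TRUE)[[1L]]
    L <- length(mb)
    if (L < w) return(NULL)
    out <- NULL
    for (s in seq_len(L - w + 1L)) {
      # oligo position j pairs the window position w - j + 1 (antiparallel)
      win <- mb[s:(s + w - 1L)]
      if (all(.pairs_with(ob, rev(win), wobble = wobble)))
        out <- bind_rows(out, tibble(mir_id = mir_id, start = s,
                                     window_length = w,
                                     window = paste(win, collapse = "")))
    }
    out
  })
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  mutate(hits, oligo_id = oligo_id, .before = 1L)
}
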