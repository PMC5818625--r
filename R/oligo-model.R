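# Data model and design operations for chemically modified siRNA duplexes.
#
# A strand is an ordered 5'->3' list of residues, each carrying a base
# (A/C/G/U/T, or X for abasic), a sugar chemistry (ribo, 2'-O-methyl,
# 2'-fluoro, GNA, LNA, 2'-deoxy) and the backbone linkage to the following
# residue (phosphodiester PO or phosphorothioate PS). 5'-caps (inverted
# abasic, morpholino, 5'-deoxy) and the 3' GalNAc conjugate are strand-level
# annotations, so residue numbering ("position 7", "nucleotides 2-8") never
# includes them.

.SUGARS   <- c("ribo", "2OMe", "2F", "GNA", "LNA", "2deoxy")
.LINKAGES <- c("PO", "PS")
.CAPS     <- c("none", "iB", "morpholino", "5deoxy")
.CONJ     <- c("none", "GalNAc")
.BASES    <- c("A", "C", "G", "U", "T", "X")

.SUGAR_TOKEN <- c(ribo = "", `2OMe` = "m", `2F` = "f", `2deoxy` = "d",
                  LNA = "l", GNA = "(gna)")
.CAP_TOKEN   <- c(iB = "[iB]", morpholino = "[mor]", `5deoxy` = "[5d]")

new_oligo_strand <- function(base, sugar, linkage,
                             cap_5prime = "none", conjugate_3prime = "none") {
  structure(
    list(residues = tibble(base = base, sugar = sugar, linkage = linkage),
         cap_5prime = cap_5prime, conjugate_3prime = conjugate_3prime),
    class = "oligo_strand")
}

#' Number of residues in a strand
#'
#' Caps and conjugates are annotations, not residues, so they never count.
#'
#' @param strand An `oligo_strand`.
#' @return Integer residue count.
#' @export
strand_length <- function(strand) {
  stopifnot(inherits(strand, "oligo_strand"))
  nrow(strand$residues)
}

#' Bases of a strand, 5' to 3'
#'
#' @param strand An `oligo_strand`.
#' @return Character vector of base letters (annotations dropped).
#' @export
strand_bases <- function(strand) {
  stopifnot(inherits(strand, "oligo_strand"))
  strand$residues$base
}

validate_oligo_strand <- function(strand) {
  r <- strand$residues
  if (nrow(r) == 0L) abort("strand has no residues")
  if (!all(r$base %in% .BASES)) abort("invalid base symbol")
  if (!all(r$sugar %in% .SUGARS)) abort("invalid sugar symbol")
  if (!all(r$linkage %in% .LINKAGES)) abort("invalid linkage symbol")
  if (!strand$cap_5prime %in% .CAPS) abort("invalid 5'-cap symbol")
  if (!strand$conjugate_3prime %in% .CONJ) abort("invalid 3'-conjugate symbol")
  abasic <- which(r$base == "X")
  if (length(abasic) && !all(abasic %in% c(1L, nrow(r))))
    abort("abasic (X) residues are permitted only at a strand terminus")
  invisible(strand)
}

#' Parse an annotated modified-oligonucleotide string
#'
#' One-letter sugar prefixes annotate each base: `m` = 2'-O-methyl,
#' `f` = 2'-fluoro, `d` = 2'-deoxy, `l` = LNA, `(gna)` = glycol nucleic
#' acid; an unprefixed base is unmodified ribo. A `*` after a residue marks
#' a phosphorothioate linkage to the following residue. `[iB]`, `[mor]` and
#' `[5d]` are 5'-caps and may appear only at the 5' terminus; `[GalNAc]`
#' marks the 3' conjugate and may appear only at the 3' terminus. `X` is an
#' abasic residue, allowed only terminally.
#'
#' @param text Annotated sequence string, 5' to 3'.
#' @return An `oligo_strand`.
#' @examples
#' parse_strand("mU*fU*mAfCmGfCmAfUmA")
#' parse_strand("[iB]mUfUmAmCmGmCmAmU")
#' @export
parse_strand <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    abort("empty sequence")
  pos <- 1L
  n <- nchar(text)
  base <- character(); sugar <- character(); linkage <- character()
  cap <- "none"; conj <- "none"
  bad <- function(tok, at)
    abort(sprintf("parse error at position %d: unexpected token '%s'", at, tok))
  while (pos <= n) {
    rest <- substr(text, pos, n)
    cap_hit <- which(startsWith(rest, .CAP_TOKEN))
    if (length(cap_hit)) {
      tok <- .CAP_TOKEN[[cap_hit[1L]]]
      if (pos != 1L) bad(tok, pos)
      cap <- names(.CAP_TOKEN)[cap_hit[1L]]
      pos <- pos + nchar(tok)
      next
    }
    if (startsWith(rest, "[GalNAc]")) {
      if (pos + nchar("[GalNAc]") - 1L != n) bad("[GalNAc]", pos)
      conj <- "GalNAc"
      pos <- n + 1L
      next
    }
    if (startsWith(rest, "(gna)")) {
      sug <- "GNA"; pos <- pos + 5L
    } else {
      pre <- substr(text, pos, pos)
      hit <- match(pre, .SUGAR_TOKEN[.SUGAR_TOKEN != "" & nchar(.SUGAR_TOKEN) == 1L])
      if (!is.na(hit)) {
        sug <- names(.SUGAR_TOKEN[.SUGAR_TOKEN != "" & nchar(.SUGAR_TOKEN) == 1L])[hit]
        pos <- pos + 1L
      } else sug <- "ribo"
    }
    b <- substr(text, pos, pos)
    if (!b %in% .BASES) bad(if (nzchar(b)) b else "<end>", pos)
    if (sug %in% c("GNA", "LNA") && b == "X")
      abort(sprintf("parse error at position %d: GNA/LNA residues require a standard base", pos))
    pos <- pos + 1L
    lk <- "PO"
    if (substr(text, pos, pos) == "*") {
      lk <- "PS"
      pos <- pos + 1L
    }
    base <- c(base, b); sugar <- c(sugar, sug); linkage <- c(linkage, lk)
  }
  if (!length(base)) abort("empty sequence")
  linkage[length(linkage)] <- "PO"  # linkage after the last residue is meaningless
  validate_oligo_strand(new_oligo_strand(base, sugar, linkage, cap, conj))
}

#' Serialize a strand back to its annotated-string form
#'
#' Inverse of [parse_strand()]: `parse_strand(serialize_strand(x))` is
#' identical to `x`, and round-tripping a canonical string is the identity.
#'
#' @param strand An `oligo_strand`.
#' @return Annotated sequence string.
#' @export
serialize_strand <- function(strand) {
  stopifnot(inherits(strand, "oligo_strand"))
  r <- strand$residues
  k <- nrow(r)
  stars <- ifelse(r$linkage == "PS", "*", "")
  stars[k] <- ""
  body <- paste0(.SUGAR_TOKEN[r$sugar], r$base, stars, collapse = "")
  paste0(if (strand$cap_5prime != "none") .CAP_TOKEN[[strand$cap_5prime]] else "",
         body,
         if (strand$conjugate_3prime == "GalNAc") "[GalNAc]" else "")
}

#' @export
print.oligo_strand <- function(x, ...) {
  cat(sprintf("<oligo_strand> %d nt  5'-cap: %s  3'-conjugate: %s\n",
              strand_length(x), x$cap_5prime, x$conjugate_3prime))
  cat(" ", serialize_strand(x), "\n")
  invisible(x)
}

#' @export
as_tibble.oligo_strand <- function(x, ...) {
  mutate(x$residues, position = row_number(), .before = 1L)
}

# ---- complementarity -------------------------------------------------------

.complement_pairs <- function(b1, b2) {
  # U and T are equivalent; X never pairs
  a <- chartr("T", "U", b1)
  b <- chartr("T", "U", b2)
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Reverse complement of a nucleic-acid string
#'
#' Accepts both U and T on input; the output alphabet is chosen by
#' `alphabet` (`"RNA"` uses U, `"DNA"` uses T). `N` maps to `N`.
#'
#' @param seq Base string over A/C/G/U/T/N.
#' @param alphabet `"RNA"` or `"DNA"`.
#' @return The reverse complement as a string.
#' @examples
#' reverse_complement("UACGCAU", "DNA")  # "ATGCGTA"
#' @export
reverse_complement <- function(seq, alphabet = c("RNA", "DNA")) {
  alphabet <- match.arg(alphabet)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    abort("sequence must be a non-empty string")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "U", "T", "N")))
    abort(sprintf("invalid character '%s' in sequence",
                  setdiff(chars, c("A", "C", "G", "U", "T", "N"))[1L]))
  u <- if (alphabet == "RNA") "U" else "T"
  comp <- c(A = u, C = "G", G = "C", U = "A", T = "A", N = "N")
  paste(rev(unname(comp[chars])), collapse = "")
}

# ---- duplex ----------------------------------------------------------------

#' Construct an siRNA duplex
#'
#' The two strands pair over their full lengths minus `overhang_length`
#' residues at each 3' end: antisense position `i` pairs sense position
#' `L_paired - i + 1`. Every paired position must be a Watson-Crick
#' complement (U and T equivalent); abasic residues never pair.
#' The derived property `risc_loading_competent` is `FALSE` exactly when the
#' antisense 5' end carries a cap, which blocks the 5'-phosphorylation
#' required for RISC loading; a sense-strand cap leaves it `TRUE`.
#'
#' @param antisense,sense `oligo_strand` objects or annotated strings
#'   understood by [parse_strand()].
#' @param overhang_length Residues at each strand's 3' end excluded from the
#'   complementarity check (default 2, the canonical siRNA architecture).
#' @return A `sirna_duplex`.
#' @export
sirna_duplex <- function(antisense, sense, overhang_length = 2L) {
  if (is.character(antisense)) antisense <- parse_strand(antisense)
  if (is.character(sense)) sense <- parse_strand(sense)
  stopifnot(inherits(antisense, "oligo_strand"), inherits(sense, "oligo_strand"))
  overhang_length <- as.integer(overhang_length)
  if (is.na(overhang_length) || overhang_length < 0L)
    abort("overhang_length must be a non-negative integer")
  dx <- structure(list(antisense = antisense, sense = sense,
                       overhang_length = overhang_length),
                  class = "sirna_duplex")
  validate_sirna_duplex(dx)
}

validate_sirna_duplex <- function(duplex) {
  la <- strand_length(duplex$antisense)
  ls <- strand_length(duplex$sense)
  o <- duplex$overhang_length
  if (la < 8L || ls < 8L) abort("each strand must have at least 8 residues")
  lp_a <- la - o
  lp_s <- ls - o
  if (lp_a < 1L || lp_s < 1L) abort("overhang leaves no paired region")
  if (lp_a != lp_s)
    abort("paired regions differ in length; strands are incompatible")
  a <- strand_bases(duplex$antisense)[seq_len(lp_a)]
  s <- strand_bases(duplex$sense)[lp_s - seq_len(lp_a) + 1L]
  ok <- a != "X" & s != "X" & .complement_pairs(a, s)
  if (!all(ok))
    abort(sprintf("duplex is not complementary at antisense position %d",
                  which(!ok)[1L]))
  duplex
}

paired_length <- function(duplex) {
  strand_length(duplex$antisense) - duplex$overhang_length
}

#' @export
print.sirna_duplex <- function(x, ...) {
  cat(sprintf("<sirna_duplex> paired %d nt, 3'-overhang %d nt, RISC-loading %s\n",
              paired_length(x), x$overhang_length,
              if (risc_loading_competent(x)) "competent" else "blocked"))
  cat("  antisense:", serialize_strand(x$antisense), "\n")
  cat("  sense:    ", serialize_strand(x$sense), "\n")
  invisible(x)
}

#' Is the duplex competent for RISC loading?
#'
#' @param duplex A `sirna_duplex`.
#' @return `FALSE` iff the antisense 5' end carries a cap.
#' @export
risc_loading_competent <- function(duplex) {
  stopifnot(inherits(duplex, "sirna_duplex"))
  duplex$antisense$cap_5prime == "none"
}

# ---- seed window -----------------------------------------------------------

#' Define a seed window on one strand of a duplex
#'
#' The default is the canonical antisense seed, nucleotides 2-8 (7 nt),
#' numbered 1-based from the strand's 5' end (caps excluded from numbering).
#'
#' @param strand `"antisense"` or `"sense"`.
#' @param start,end 1-based inclusive window bounds.
#' @return A `seed_spec` with a `label` of the form `"antisense_2_8"`.
#' @export
seed_spec <- function(strand = c("antisense", "sense"), start = 2L, end = 8L) {
  strand <- match.arg(strand)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start >= end)
    abort("seed window requires 1 <= start < end")
  structure(list(strand = strand, start = start, end = end,
                 label = paste(strand, start, end, sep = "_")),
            class = "seed_spec")
}

#' @export
print.seed_spec <- function(x, ...) {
  cat(sprintf("<seed_spec> %s nucleotides %d-%d\n", x$strand, x$start, x$end))
  invisible(x)
}

#' Extract the seed bases from a duplex
#'
#' @param duplex A `sirna_duplex`.
#' @param spec A [seed_spec()].
#' @return Base string of the window, 5' to 3' (annotations dropped).
#' @export
extract_seed <- function(duplex, spec = seed_spec()) {
  stopifnot(inherits(duplex, "sirna_duplex"), inherits(spec, "seed_spec"))
  strand <- duplex[[spec$strand]]
  if (spec$end > strand_length(strand))
    abort(sprintf("seed window %d-%d exceeds %s strand length %d",
                  spec$start, spec$end, spec$strand, strand_length(strand)))
  b <- strand_bases(strand)[spec$start:spec$end]
  if (any(b == "X")) abort("seed window covers an abasic residue")
  paste(b, collapse = "")
}

#' mRNA site complementary to a seed
#'
#' The DNA 7mer (for the default window) that a 3'UTR must contain for a
#' perfect seed match: the reverse complement of [extract_seed()].
#'
#' @inheritParams extract_seed
#' @return DNA string of the same length as the window.
#' @export
seed_site <- function(duplex, spec = seed_spec()) {
  reverse_complement(extract_seed(duplex, spec), "DNA")
}

# ---- design operations -----------------------------------------------------

.set_base <- function(strand, pos, new_base) {
  strand$residues$base[pos] <- new_base
  strand
}

#' Swap the seed region between two duplexes
#'
#' Replaces the recipient's antisense bases over the window with the
#' donor's, updates the paired sense bases so the duplex stays
#' complementary, and leaves every chemical annotation (sugar, linkage,
#' caps, conjugates) of the recipient untouched — the in-silico counterpart
#' of exchanging seeds between two compounds without changing the chemical
#' modification pattern.
#'
#' @param recipient,donor `sirna_duplex` objects.
#' @param spec A [seed_spec()]; must address the antisense strand.
#' @return The modified recipient duplex.
#' @export
swap_seed <- function(recipient, donor, spec = seed_spec()) {
  stopifnot(inherits(recipient, "sirna_duplex"), inherits(donor, "sirna_duplex"))
  if (spec$strand != "antisense") abort("seeds are swapped on the antisense strand")
  donor_bases <- strsplit(extract_seed(donor, spec), "", fixed = TRUE)[[1L]]
  idx <- spec$start:spec$end
  if (spec$end > strand_length(recipient$antisense))
    abort("recipient antisense strand shorter than the seed window")
  out <- recipient
  out$antisense <- .set_base(out$antisense, idx, donor_bases)
  lp <- paired_length(out)
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (i > lp) next  # window residue falls in the 3' overhang: unpaired
    j <- lp - i + 1L
    old <- strand_bases(out$sense)[j]
    comp <- reverse_complement(donor_bases[k], "RNA")
    if (old == "T" && comp == "U") comp <- "T"  # keep the stored letter style
    out$sense <- .set_base(out$sense, j, comp)
  }
  validate_sirna_duplex(out)
}

#' Place a glycol nucleic acid (GNA) residue on the antisense strand
#'
#' A thermally destabilizing GNA residue in the seed (canonically antisense
#' position 7) lowers seed-pairing affinity and thereby seed-mediated
#' off-target repression. Only the sugar chemistry changes; the base is
#' preserved, so seed extraction (which reads bases only) is unchanged.
#'
#' @param duplex A `sirna_duplex`.
#' @param position 1-based antisense position (default 7).
#' @return The modified duplex.
#' @export
place_gna <- function(duplex, position = 7L) {
  stopifnot(inherits(duplex, "sirna_duplex"))
  position <- as.integer(position)
  if (is.na(position) || position < 1L ||
      position > strand_length(duplex$antisense))
    abort("GNA position out of range")
  if (strand_bases(duplex$antisense)[position] == "X")
    abort("cannot place GNA on an abasic residue")
  duplex$antisense$residues$sugar[position] <- "GNA"
  validate_sirna_duplex(duplex)
}

#' Set or remove a 5'-cap on one strand
#'
#' Caps (`iB` inverted abasic, `morpholino`, `5deoxy`) block
#' 5'-phosphorylation. Capping the antisense strand abolishes RISC-loading
#' competence; capping the sense strand alone does not.
#'
#' @param duplex A `sirna_duplex`.
#' @param strand `"antisense"` or `"sense"`.
#' @param cap One of `"none"`, `"iB"`, `"morpholino"`, `"5deoxy"`.
#' @return The modified duplex.
#' @export
set_cap <- function(duplex, strand = c("antisense", "sense"), cap) {
  stopifnot(inherits(duplex, "sirna_duplex"))
  strand <- match.arg(strand)
  if (!is.character(cap) || length(cap) != 1L || !cap %in% .CAPS)
    abort(sprintf("unknown cap symbol '%s'", as.character(cap)[1L]))
  duplex[[strand]]$cap_5prime <- cap
  validate_sirna_duplex(duplex)
}

#' Sugar-chemistry composition of a strand
#'
#' Percentages are taken over non-abasic residues and sum to 100; the
#' phosphorothioate linkage count is reported separately as the
#' `ps_count` attribute (the linkage following the last residue is
#' ignored). This is the accounting used to compare, e.g., a high-2'F
#' (48% 2'F / 52% 2'OMe) design with a low-2'F one.
#'
#' @param strand An `oligo_strand` (or a `sirna_duplex`, in which case the
#'   antisense strand is used).
#' @return Tibble with columns `sugar`, `n`, `percent` and attribute
#'   `ps_count`.
#' @export
mod_composition <- function(strand) {
  if (inherits(strand, "sirna_duplex")) strand <- strand$antisense
  stopifnot(inherits(strand, "oligo_strand"))
  r <- filter(strand$residues, .data$base != "X")
  if (nrow(r) == 0L) abort("strand has no scoreable residues")
  out <- r %>%
    group_by(sugar = .data$sugar) %>%
    summarise(n = n(), .groups = "drop") %>%
    mutate(percent = 100 * .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n))
  k <- nrow(strand$residues)
  attr(out, "ps_count") <- sum(strand$residues$linkage[seq_len(max(k - 1L, 0L))] == "PS")
  out
}

# ---- duplex table I/O ------------------------------------------------------

#' Read a duplex table
#'
#' TSV with columns `duplex_id`, `antisense`, `sense`, `overhang_length`
#' (annotated-sequence notation, antisense first).
#'
#' @param path Path to a TSV file.
#' @return Tibble with the input columns plus a `duplex` list-column of
#'   parsed `sirna_duplex` objects.
#' @export
read_duplex_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("duplex_id", "antisense", "sense", "overhang_length")
  miss <- setdiff(need, names(tab))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  tab %>%
    mutate(overhang_length = as.integer(.data$overhang_length),
           duplex = purrr::pmap(list(.data$antisense, .data$sense,
                                     .data$overhang_length),
                                sirna_duplex))
}
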