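# Shared helpers: independent brute-force oracles and small fixture builders.

# naive window-enumeration site counter: tests every window of the sequence
naive_scan <- function(sequence, site) {
  w <- nchar(site)
  L <- nchar(sequence)
  if (L < w) return(integer())
  starts <- seq_len(L - w + 1L)
  windows <- substring(sequence, starts, starts + w - 1L)
  starts[windows == site]
}

# exact Fisher p-values by enumerating every table with the observed margins
# and summing dhyper point probabilities (independent of the package's
# log-space implementation)
enum_fisher <- function(a, b, c, d) {
  r <- a + b
  k <- a + c
  n <- a + b + c + d
  x <- max(0L, r + k - n):min(r, k)
  probs <- stats::dhyper(x, k, n - k, r)
  obs <- probs[x == a]
  list(one = sum(probs[x >= a]),
       two = sum(probs[probs <= obs * (1 + 1e-7)]))
}

# random sequence of given length
random_dna <- function(n, n_frac = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, n, replace = TRUE)
  if (n_frac > 0) {
    k <- rbinom(1, n, n_frac)
    if (k > 0) s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

random_rna_bases <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

# build a valid duplex from antisense bases alone (plain ribo sense strand)
make_test_duplex <- function(antisense, overhang = 2L) {
  complementary_duplex(paste(antisense, collapse = ""), overhang)
}

# write a FASTA file into tempdir and return its path
write_fasta <- function(records, path = withr::local_tempfile(fileext = ".fa",
                                                              .local_envir = parent.frame())) {
  writeLines(paste0(">", names(records), "\n", unname(records)), path)
  path
}

write_de_tsv <- function(de, path = withr::local_tempfile(fileext = ".tsv",
                                                          .local_envir = parent.frame())) {
  readr::write_tsv(de, path)
  path
}

# tiny configuration for fast smoke-level simulations
small_config <- function(...) {
  synthetic_config(n_genes = 150L, utr_length_range = c(100L, 400L),
                   n_on_target = 1L, ...)
}
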