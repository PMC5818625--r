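test_that("parse_strand reads sugar prefixes, PS marks, caps and conjugates", {
  s <- parse_strand("mU*fU*mAfCmGfCmAfUmA")
  expect_equal(strand_length(s), 9L)
  expect_equal(strand_bases(s), c("U", "U", "A", "C", "G", "C", "A", "U", "A"))
  expect_equal(s$residues$sugar, rep(c("2OMe", "2F"), length.out = 9L))
  expect_equal(s$residues$linkage[1:3], c("PS", "PS", "PO"))

  capped <- parse_strand("[iB]mUfUmA")
  expect_equal(capped$cap_5prime, "iB")
  expect_equal(strand_length(capped), 3L)

  gna <- parse_strand("mUfU(gna)AmC")
  expect_equal(gna$residues$sugar[3], "GNA")
  expect_equal(gna$residues$base[3], "A")

  conj <- parse_strand("mUfUmAmC[GalNAc]")
  expect_equal(conj$conjugate_3prime, "GalNAc")
  expect_equal(strand_length(conj), 4L)
})

test_that("parse_strand rejects malformed input, naming token and position", {
  expect_error(parse_strand("mUfQ"), "position 4.*'Q'")
  expect_error(parse_strand("mU[iB]fU"), "position 3")
  expect_error(parse_strand("mU[GalNAc]fU"), "GalNAc")
  expect_error(parse_strand(""), "empty")
  expect_error(parse_strand("(gna)X"), "standard base")
  expect_error(parse_strand("mUXfUmAfU"), "abasic")  # X must be terminal
})

test_that("parse/serialize round-trip is the identity on canonical strings", {
  set.seed(421)
  sugars <- c("", "m", "f", "d", "l", "(gna)")
  for (i in 1:200) {
    k <- sample(8:25, 1)
    sug <- sample(sugars, k, replace = TRUE)
    base <- sample(c("A", "C", "G", "U", "T"), k, replace = TRUE)
    star <- c(ifelse(runif(k - 1) < 0.3, "*", ""), "")
    txt <- paste0(
      if (runif(1) < 0.3) sample(c("[iB]", "[mor]", "[5d]"), 1) else "",
      paste0(sug, base, star, collapse = ""),
      if (runif(1) < 0.3) "[GalNAc]" else "")
    expect_identical(serialize_strand(parse_strand(txt)), txt)
  }
})

test_that("serialization canonicalizes a meaningless trailing PS mark", {
  expect_identical(serialize_strand(parse_strand("mUfUmAfC*")), "mUfUmAfC")
})

test_that("reverse_complement honours alphabet, maps N, and is an involution", {
  expect_identical(reverse_complement("UACGCAU", "DNA"), "ATGCGTA")
  expect_identical(reverse_complement("A", "RNA"), "U")
  expect_identical(reverse_complement("ACGN", "DNA"), "NCGT")
  expect_error(reverse_complement("ACGB", "DNA"), "invalid character 'B'")
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(sample(1:60, 1))
    expect_identical(reverse_complement(reverse_complement(s, "DNA"), "DNA"), s)
  }
})

test_that("extract_seed and seed_site read the seed window off the duplex", {
  dx <- make_test_duplex(strsplit("UUACGCAUAAAGUCUUGGCUU", "")[[1]])
  expect_identical(extract_seed(dx, seed_spec("antisense", 2, 8)), "UACGCAU")
  expect_identical(seed_site(dx, seed_spec("antisense", 2, 8)), "ATGCGTA")
  sense_b <- strand_bases(dx$sense)
  expect_identical(extract_seed(dx, seed_spec("sense", 2, 8)),
                   paste(sense_b[2:8], collapse = ""))
  expect_error(extract_seed(dx, seed_spec("antisense", 2, 25)), "exceeds")
  expect_error(seed_spec("antisense", 8, 2), "start < end")
  # site length always equals the window length
  expect_equal(nchar(seed_site(dx, seed_spec("antisense", 3, 9))), 7L)
  expect_equal(nchar(seed_site(dx, seed_spec("antisense", 2, 5))), 4L)
})

test_that("swap_seed exchanges bases, repairs the sense strand, keeps chemistry", {
  set.seed(11)
  recipient <- random_sirna_duplex()
  donor_bases <- random_rna_bases(21)
  donor_bases[2:8] <- "G"
  donor <- make_test_duplex(donor_bases)
  out <- swap_seed(recipient, donor, seed_spec("antisense", 2, 8))
  expect_identical(extract_seed(out, seed_spec("antisense", 2, 8)), "GGGGGGG")
  lp <- strand_length(out$antisense) - out$overhang_length
  expect_identical(strand_bases(out$sense)[lp - (2:8) + 1], rep("C", 7))
  # chemistry untouched everywhere
  expect_identical(out$antisense$residues$sugar, recipient$antisense$residues$sugar)
  expect_identical(out$antisense$residues$linkage, recipient$antisense$residues$linkage)
  expect_identical(out$sense$residues$sugar, recipient$sense$residues$sugar)
  expect_identical(out$sense$conjugate_3prime, recipient$sense$conjugate_3prime)
  # base-level involution: swapping back the original seed restores the duplex
  back <- swap_seed(out, recipient, seed_spec("antisense", 2, 8))
  expect_identical(strand_bases(back$antisense), strand_bases(recipient$antisense))
  expect_identical(strand_bases(back$sense), strand_bases(recipient$sense))
})

test_that("place_gna changes sugar only and validates position", {
  set.seed(3)
  dx <- random_sirna_duplex()
  seed_before <- extract_seed(dx)
  out <- place_gna(dx, 7)
  expect_identical(out$antisense$residues$sugar[7], "GNA")
  expect_identical(strand_bases(out$antisense), strand_bases(dx$antisense))
  expect_identical(extract_seed(out), seed_before)
  expect_error(place_gna(dx, 0), "out of range")
  expect_error(place_gna(dx, 99), "out of range")
})

test_that("5'-caps control RISC-loading competence strand-specifically", {
  set.seed(5)
  dx <- random_sirna_duplex()
  expect_true(risc_loading_competent(dx))
  expect_false(risc_loading_competent(set_cap(dx, "antisense", "iB")))
  expect_false(risc_loading_competent(set_cap(dx, "antisense", "morpholino")))
  expect_true(risc_loading_competent(set_cap(dx, "sense", "iB")))
  restored <- set_cap(set_cap(dx, "antisense", "iB"), "antisense", "none")
  expect_true(risc_loading_competent(restored))
  expect_error(set_cap(dx, "antisense", "acetyl"), "unknown cap")
})

test_that("mod_composition reports percentages over residues and PS separately", {
  ten <- parse_strand("mUfUmAfCmGfCmAfUmAfC")
  comp <- mod_composition(ten)
  expect_equal(sort(comp$percent), c(50, 50))
  expect_equal(sum(comp$percent), 100, tolerance = 1e-9)

  allm <- parse_strand("mUmUmAmCmGmCmAmU")
  expect_equal(mod_composition(allm)$percent, 100)

  s21 <- parse_strand(paste0(strrep("mU", 17), strrep("fA", 4)))
  comp21 <- mod_composition(s21)
  expect_equal(comp21$percent[comp21$sugar == "2F"], 100 * 4 / 21,
               tolerance = 1e-9)

  ps <- parse_strand("mU*fU*mAfCmGfCmAfU")
  expect_equal(attr(mod_composition(ps), "ps_count"), 2L)
})

test_that("composition is invariant under capping", {
  set.seed(13)
  dx <- random_sirna_duplex()
  before <- mod_composition(dx$antisense)
  after <- mod_composition(set_cap(dx, "antisense", "iB")$antisense)
  expect_equal(before$percent, after$percent)
  expect_equal(sum(after$percent), 100, tolerance = 1e-9)
})

test_that("duplex validation enforces pairing geometry and complementarity", {
  expect_error(sirna_duplex("mUfUmA", "mUfUmA", 0), "at least 8")
  expect_error(sirna_duplex("AAAAAAAAAA", "UUUUUUUUUU", 10), "no paired region")
  # sense equal to antisense (not complementary) must fail
  expect_error(sirna_duplex("ACGUACGUACGU", "ACGUACGUACGU", 2),
               "not complementary")
  # mismatched paired-region lengths
  expect_error(sirna_duplex("ACGUACGUACGUACGU", "ACGUACGUACGU", 2),
               "incompatible|differ")
})

test_that("design operations preserve duplex complementarity on random duplexes", {
  set.seed(99)
  for (i in 1:50) {
    dx <- random_sirna_duplex()
    donor <- random_sirna_duplex()
    expect_s3_class(swap_seed(dx, donor), "sirna_duplex")
    expect_s3_class(place_gna(dx, sample(21, 1)), "sirna_duplex")
    expect_s3_class(set_cap(dx, sample(c("antisense", "sense"), 1), "iB"),
                    "sirna_duplex")
  }
})

test_that("duplex TSV round-trips through the parser", {
  set.seed(2)
  dx <- random_sirna_duplex()
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    duplex_id = "dx1",
    antisense = serialize_strand(dx$antisense),
    sense = serialize_strand(dx$sense),
    overhang_length = dx$overhang_length), path)
  tab <- read_duplex_tsv(path)
  expect_equal(nrow(tab), 1L)
  expect_identical(strand_bases(tab$duplex[[1]]$antisense),
                   strand_bases(dx$antisense))
  expect_error(read_duplex_tsv(write_de_tsv(tibble::tibble(duplex_id = "x"))),
               "missing column")
})
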