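test_that("configuration is validated and round-trips through YAML", {
  cfg <- synthetic_config()
  expect_s3_class(cfg, "synthetic_config")
  expect_error(synthetic_config(frac_seed_match = 1.2), "frac_seed_match")
  expect_error(synthetic_config(dispersion = 0), "dispersion")
  expect_error(synthetic_config(reps_per_group = 1), "replicates")
  expect_error(synthetic_config(offtarget_lfc_mean = 0.3), "<= 0")
  expect_warning(synthetic_config(n_genes = 5, frac_seed_match = 0.01),
                 "no sites")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_genes = 99, frac_seed_match = 0.2, rng_seed = 5),
                   path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$n_genes, 99L)
  expect_equal(cfg2$reps_per_group, cfg$reps_per_group)  # defaults retained
  yaml::write_yaml(list(n_genez = 3), path)
  expect_error(read_synthetic_config(path), "unknown config field")
})

test_that("generated universes are deterministic and fraction-faithful", {
  cfg <- synthetic_config(n_genes = 400, frac_seed_match = 0.2, rng_seed = 42)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1$utrs, u2$utrs)
  expect_identical(serialize_strand(u1$duplex$antisense),
                   serialize_strand(u2$duplex$antisense))
  expect_identical(u1$truth, u2$truth)
  # at least the planted fraction carries a verified site
  expect_gte(sum(u1$truth$is_seed_match), 0.2 * 400)
  expect_equal(sum(u1$truth$planted_antisense), 80L)
  expect_equal(sum(u1$truth$planted_sense), 80L)
  # disjoint planting
  expect_equal(sum(u1$truth$planted_antisense & u1$truth$planted_sense), 0L)
})

test_that("truth flags equal a post-hoc scan of the generated UTRs", {
  for (seed in c(7, 19)) {
    cfg <- small_config(rng_seed = seed)
    uni <- generate_universe(cfg)
    rescan_a <- scan_utrs(uni$utrs, uni$sites$antisense)
    rescan_s <- scan_utrs(uni$utrs, uni$sites$sense)
    expect_identical(uni$truth$is_seed_match, rescan_a$count >= 1L)
    expect_identical(uni$truth$is_sense_seed_match, rescan_s$count >= 1L)
    # on-target genes contain the full-length antisense complement
    full <- reverse_complement(paste(strand_bases(uni$duplex$antisense),
                                     collapse = ""), "DNA")
    ot <- uni$utrs$sequence[uni$truth$is_on_target]
    expect_true(all(vapply(ot, function(s) grepl(full, s, fixed = TRUE), TRUE)))
  }
})

test_that("zero planting still records chance matches in the truth", {
  cfg <- synthetic_config(n_genes = 300, frac_seed_match = 0,
                          n_on_target = 0, rng_seed = 8)
  uni <- generate_universe(cfg)
  expect_equal(sum(uni$truth$planted_antisense), 0L)
  expect_identical(uni$truth$is_seed_match,
                   scan_utrs(uni$utrs, uni$sites$antisense)$count >= 1L)
})

test_that("planted effects respect the twofold cap and on-target knockdown", {
  cfg <- small_config(rng_seed = 9)
  uni <- generate_universe(cfg)
  sim <- generate_counts(uni, cfg)
  tr <- sim$truth
  off <- tr$is_repressed & !tr$is_on_target
  expect_true(all(tr$true_log2FC[off] <= 0))
  expect_true(all(abs(tr$true_log2FC[off]) <= cfg$offtarget_lfc_cap))
  expect_equal(unique(tr$true_log2FC[tr$is_on_target]), cfg$ontarget_lfc)
  # sense-only matches carry no effect
  sense_only <- tr$is_sense_seed_match & !tr$is_seed_match & !tr$is_on_target
  expect_true(all(tr$true_log2FC[sense_only] == 0))
  expect_equal(dim(sim$counts), c(cfg$n_genes, 2L * cfg$reps_per_group))
  # determinism of the counts stage
  expect_identical(sim$counts, generate_counts(uni, cfg)$counts)
})

test_that("large size parameter approaches the Poisson limit", {
  set.seed(100)
  mu <- 50
  draws <- rnbinom(1e5, mu = mu, size = 1e6)
  expect_equal(var(draws) / mean(draws), 1, tolerance = 0.02)
})

test_that("the DE stand-in reproduces hand-computed fold changes", {
  # two samples per group engineered to library size 1e6 so CPM == counts
  counts <- rbind(
    g1 = c(100, 100, 100, 25, 25, 25),
    g2 = c(200, 200, 200, 200, 200, 200),
    filler = c(1e6 - 300, 1e6 - 300, 1e6 - 300, 1e6 - 225, 1e6 - 225, 1e6 - 225))
  groups <- rep(c("control", "treated"), each = 3)
  de <- call_de(counts, groups)
  expect_equal(de$log2FC[de$gene_id == "g1"], log2(25.5 / 100.5),
               tolerance = 1e-6)
  expect_equal(round(de$log2FC[de$gene_id == "g1"], 2), -1.98)
})

test_that("degenerate genes get the stated p-value rules", {
  varying <- c(10L, 20L, 30L, 40L, 50L, 60L)
  counts <- rbind(same = rep(50L, 6),
                  zero = rep(0L, 6),
                  varying = varying,
                  filler = 2000L - 50L - varying)  # equal library sizes
  groups <- rep(c("control", "treated"), each = 3)
  de <- call_de(counts, groups)
  expect_equal(de$pvalue[de$gene_id == "same"], 1)  # zero variance, equal means
  expect_true(is.na(de$padj[de$gene_id == "zero"]))  # untested all-zero row
  expect_false(is.na(de$padj[de$gene_id == "varying"]))
})

test_that("Benjamini-Hochberg matches the step-up closed form", {
  # the adjustment itself is delegated to p.adjust; this pins the contract
  # the classifier depends on
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("the end-to-end simulation is deterministic and truth-consistent", {
  cfg <- small_config(rng_seed = 77)
  s1 <- end_to_end_sim(cfg, n_sim = 2)
  s2 <- end_to_end_sim(cfg, n_sim = 2)
  expect_identical(s1$results, s2$results)
  expect_identical(s1$runs, s2$runs)
  expect_equal(nrow(s1$results), 2L * 4L)
  g <- glance(s1)
  expect_true(all(c("reject_rate_signal", "reject_rate_sense_down") %in% names(g)))
  expect_equal(nrow(tidy(s1)), 8L)
})

test_that("a literal all-null transcriptome yields a degenerate enrichment p", {
  # with every true log2FC = 0 the BH-controlled down class is (almost
  # always) empty and the one-sided enrichment p is identically 1 — the
  # reason type-I calibration uses the seed-independent repression null
  cfg <- synthetic_config(n_genes = 500, offtarget_lfc_mean = 0,
                          offtarget_lfc_sd = 0, n_on_target = 0,
                          rng_seed = 123)
  uni <- generate_universe(cfg)
  sim <- generate_counts(uni, cfg)
  expect_true(all(sim$truth$true_log2FC == 0))
  res <- run_enrichment(join_matches(classify_de(call_de(sim)),
                                     scan_set(uni$utrs, uni$duplex)))
  expect_equal(res$p_one_sided[res$spec_label == "antisense_2_8" &
                                 res$direction == "down"], 1)
})

test_that("seed-independent repression decouples matches from the down class", {
  cfg <- synthetic_config(n_genes = 800, seed_dependent = FALSE, rng_seed = 31)
  uni <- generate_universe(cfg)
  sim <- generate_counts(uni, cfg)
  tr <- sim$truth
  # repression hits matched and unmatched genes at comparable rates
  p_match <- mean(tr$is_repressed[tr$is_seed_match])
  p_nomatch <- mean(tr$is_repressed[!tr$is_seed_match])
  expect_lt(abs(p_match - p_nomatch), 0.15)
  expect_equal(sum(tr$is_repressed), round(0.15 * 800))
})

test_that("estimated fold changes recover the truncated-normal mean closely", {
  cfg <- synthetic_config(rng_seed = 88)
  uni <- generate_universe(cfg)
  sim <- generate_counts(uni, cfg)
  de <- call_de(sim)
  tr <- sim$truth
  off <- tr$is_repressed & !tr$is_on_target
  est <- mean(de$log2FC[match(tr$gene_id[off], de$gene_id)])
  # single-run sanity bound; the tighter multi-run recovery check lives in
  # the acceptance suite
  expect_lt(abs(est - truncated_normal_mean(-0.6, 0.2, -1, 0)), 0.15)
})

test_that("truncated normal mean matches Monte-Carlo integration", {
  set.seed(5)
  u <- qnorm(runif(2e5, pnorm(-1, -0.6, 0.2), pnorm(0, -0.6, 0.2)), -0.6, 0.2)
  expect_equal(truncated_normal_mean(-0.6, 0.2, -1, 0), mean(u),
               tolerance = 0.005)
  expect_equal(truncated_normal_mean(-0.6, 0, -1, 0), -0.6)
  expect_equal(truncated_normal_mean(-5, 0, -1, 0), -1)  # clamped point mass
})
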