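# Synthetic transcriptome-response generator.
#
# Emulates the statistical structure the enrichment analysis assumes: a
# random modified duplex; random UTRs with antisense-seed sites planted at a
# controlled frequency (and sense-seed sites planted into a disjoint
# control fraction); negative-binomial counts for treated/control replicate
# groups in which antisense-seed-match genes are mildly repressed (|log2FC|
# capped at the twofold ceiling), one on-target gene is strongly knocked
# down, and nothing is tied to the sense seed or to upregulation. A
# deliberately simple DE caller (Welch t-test on log2 CPM +
# Benjamini-Hochberg) stands in for a full count-model fit.

# deterministic per-stage seed derivation from one master seed; the
# multiplier is the classic Lehmer constant, modulus 2^31 - 1 keeps the
# result a valid 32-bit seed
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + stage) %% 2147483647)
}

#' Configuration for the synthetic transcriptome simulator
#'
#' Defaults describe the regime the analysis targets: ~2000 genes, 15% of
#' UTRs carrying a planted antisense-seed site, off-target repression drawn
#' from Normal(-0.6, 0.2) truncated to `[-1, 0]` log2 units (magnitudes
#' never exceeding twofold), one strongly knocked-down on-target gene
#' (log2FC -2.5), and 3 treated vs 3 control replicates with
#' technical-replicate-like negative-binomial noise.
#'
#' @param n_genes Number of genes.
#' @param utr_length_range Integer pair; UTR lengths are uniform on this
#'   range (nt).
#' @param base_composition Named probabilities for A/C/G/T.
#' @param frac_seed_match Target fraction of genes with a planted antisense
#'   seed site.
#' @param n_on_target Genes carrying a full-length antisense complement.
#' @param reps_per_group Replicates per group.
#' @param mean_log_expression Mean of the natural-log control means.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param offtarget_lfc_mean,offtarget_lfc_sd Normal parameters (log2
#'   units) of off-target repression before truncation; the mean should be
#'   negative or zero.
#' @param offtarget_lfc_cap Truncation bound: planted off-target effects
#'   satisfy |log2FC| <= cap (default 1, i.e. at most twofold).
#' @param ontarget_lfc log2FC of on-target genes (default -2.5).
#' @param seed_dependent If `TRUE` (default) off-target repression is
#'   applied to antisense-seed-match genes; if `FALSE` the same repression
#'   magnitudes are assigned to a random gene subset of the same size,
#'   independent of match status — the null used for type-I calibration of
#'   the enrichment test.
#' @param rng_seed Master RNG seed; every stage derives its own substream
#'   seed from it, so identical configs give byte-identical outputs.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             utr_length_range = c(200L, 2000L),
                             base_composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                             frac_seed_match = 0.15,
                             n_on_target = 1L,
                             reps_per_group = 3L,
                             mean_log_expression = log(500),
                             dispersion = 1000,
                             offtarget_lfc_mean = -0.6,
                             offtarget_lfc_sd = 0.2,
                             offtarget_lfc_cap = 1,
                             ontarget_lfc = -2.5,
                             seed_dependent = TRUE,
                             rng_seed = 1L) {
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    utr_length_range = as.integer(utr_length_range),
    base_composition = base_composition,
    frac_seed_match = frac_seed_match,
    n_on_target = as.integer(n_on_target),
    reps_per_group = as.integer(reps_per_group),
    mean_log_expression = mean_log_expression,
    dispersion = dispersion,
    offtarget_lfc_mean = offtarget_lfc_mean,
    offtarget_lfc_sd = offtarget_lfc_sd,
    offtarget_lfc_cap = offtarget_lfc_cap,
    ontarget_lfc = ontarget_lfc,
    seed_dependent = isTRUE(seed_dependent),
    rng_seed = as.integer(rng_seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1L) abort("n_genes must be positive")
    if (length(utr_length_range) != 2L || utr_length_range[1L] < 30L ||
        utr_length_range[1L] > utr_length_range[2L])
      abort("utr_length_range must be an increasing pair with minimum >= 30")
    if (!setequal(names(base_composition), c("A", "C", "G", "T")) ||
        any(base_composition < 0) || abs(sum(base_composition) - 1) > 1e-8)
      abort("base_composition must be A/C/G/T probabilities summing to 1")
    if (frac_seed_match < 0 || frac_seed_match > 1)
      abort("frac_seed_match must lie in [0, 1]")
    if (reps_per_group < 2L) abort("at least 2 replicates per group")
    if (dispersion <= 0) abort("dispersion must be positive")
    if (offtarget_lfc_sd < 0) abort("offtarget_lfc_sd must be non-negative")
    if (offtarget_lfc_cap <= 0) abort("offtarget_lfc_cap must be positive")
    if (offtarget_lfc_mean > 0) abort("offtarget_lfc_mean must be <= 0")
  })
  if (cfg$frac_seed_match > 0 && cfg$frac_seed_match * cfg$n_genes < 1)
    warn("frac_seed_match * n_genes < 1: no sites will be planted")
  cfg
}

#' Read a simulator configuration from YAML or JSON
#'
#' Fields not present in the file keep their [synthetic_config()] defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(synthetic_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    abort(paste0("unknown config field(s): ", paste(extra, collapse = ", ")))
  if (!is.null(vals$base_composition))
    vals$base_composition <- unlist(vals$base_composition)
  do.call(synthetic_config, vals)
}

#' Generate a random chemically modified siRNA duplex
#'
#' A 21-mer antisense strand with the standard alternating 2'-O-methyl /
#' 2'-fluoro pattern, phosphorothioate linkages at the two terminal
#' dinucleotides of each strand, a 2-nt 3' overhang on both strands, and a
#' GalNAc conjugate at the sense 3' end. Uses the current RNG state.
#'
#' @param length Antisense length (default 21).
#' @param overhang 3'-overhang length (default 2).
#' @return A `sirna_duplex`.
#' @export
random_sirna_duplex <- function(length = 21L, overhang = 2L) {
  length <- as.integer(length); overhang <- as.integer(overhang)
  anti <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
  lp <- length - overhang
  sense_paired <- strsplit(reverse_complement(paste(anti[seq_len(lp)], collapse = ""),
                                              "RNA"), "", fixed = TRUE)[[1L]]
  sense <- c(sense_paired, sample(c("A", "C", "G", "U"), overhang, replace = TRUE))
  mk <- function(bases) {
    k <- base::length(bases)
    sugar <- rep(c("2OMe", "2F"), length.out = k)
    linkage <- rep("PO", k)
    linkage[c(1L, 2L, k - 2L, k - 1L)] <- "PS"
    new_oligo_strand(bases, sugar, linkage)
  }
  a <- mk(anti)
  s <- mk(sense)
  s$conjugate_3prime <- "GalNAc"
  sirna_duplex(a, s, overhang)
}

.random_utrs <- function(n, len_range, comp) {
  len <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
  comp <- comp[c("A", "C", "G", "T")]
  idx <- sample.int(4L, sum(len), replace = TRUE, prob = comp)
  big <- rawToChar(charToRaw("ACGT")[idx])
  ends <- cumsum(len)
  seqs <- substring(big, ends - len + 1L, ends)
  tibble(gene_id = sprintf("gene_%05d", seq_len(n)),
         sequence = seqs, length = len)
}

.plant_site <- function(sequence, site) {
  w <- nchar(site)
  pos <- sample.int(nchar(sequence) - w + 1L, 1L)
  paste0(substr(sequence, 1L, pos - 1L), site,
         substr(sequence, pos + w, nchar(sequence)))
}

#' Generate a synthetic UTR universe for one duplex
#'
#' Draws a random duplex, samples UTRs from the configured base
#' composition, plants the antisense seed site into a `frac_seed_match`
#' fraction of genes and the sense seed site into a disjoint fraction of
#' equal size, and inserts a full-length antisense complement into
#' `n_on_target` genes. The ground truth is then *recomputed by scanning*
#' the generated sequences, so chance seed matches are recorded and no
#' planted site is assumed without verification.
#'
#' @param config A [synthetic_config()].
#' @return A `sirna_universe` list: `utrs`, `duplex`, `truth` (per-gene
#'   `is_seed_match`, `is_sense_seed_match`, `is_on_target` and planted
#'   flags), `sites`.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.stage_seed(config$rng_seed, 1L))
  repeat {
    duplex <- random_sirna_duplex()
    site_a <- seed_site(duplex, seed_spec("antisense"))
    site_s <- seed_site(duplex, seed_spec("sense"))
    if (site_a != site_s) break  # the strand control must be distinguishable
  }
  utrs <- .random_utrs(config$n_genes, config$utr_length_range,
                       config$base_composition)
  n_plant <- round(config$frac_seed_match * config$n_genes)
  planted_a <- sort(sample.int(config$n_genes, n_plant))
  pool <- setdiff(seq_len(config$n_genes), planted_a)
  planted_s <- sort(sample(pool, min(n_plant, length(pool))))
  for (i in planted_a) utrs$sequence[i] <- .plant_site(utrs$sequence[i], site_a)
  for (i in planted_s) utrs$sequence[i] <- .plant_site(utrs$sequence[i], site_s)
  on_target <- integer()
  if (config$n_on_target > 0L) {
    full_site <- reverse_complement(paste(strand_bases(duplex$antisense),
                                          collapse = ""), "DNA")
    pool2 <- setdiff(seq_len(config$n_genes), planted_s)
    on_target <- sort(sample(pool2, min(config$n_on_target, length(pool2))))
    for (i in on_target)
      utrs$sequence[i] <- .plant_site(utrs$sequence[i], full_site)
  }
  utrs$length <- nchar(utrs$sequence)
  truth <- tibble(
    gene_id = utrs$gene_id,
    planted_antisense = seq_len(config$n_genes) %in% planted_a,
    planted_sense = seq_len(config$n_genes) %in% planted_s,
    is_on_target = seq_len(config$n_genes) %in% on_target,
    is_seed_match = .count_sites(utrs$sequence, site_a) >= 1L,
    is_sense_seed_match = .count_sites(utrs$sequence, site_s) >= 1L)
  structure(list(utrs = utrs, duplex = duplex, truth = truth,
                 sites = list(antisense = site_a, sense = site_s)),
            class = "sirna_universe")
}

#' Mean of a truncated normal distribution
#'
#' Expectation of `Normal(mean, sd)` truncated to `[lower, upper]` — the
#' population mean of the simulator's planted off-target log2 fold
#' changes, used as the reference in parameter-recovery checks.
#'
#' @param mean,sd Normal parameters (`sd = 0` gives the clamped point mass).
#' @param lower,upper Truncation bounds.
#' @return The truncated mean.
#' @export
truncated_normal_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate negative-binomial counts for a universe
#'
#' Control means are log-normal (`exp(Normal(mean_log_expression, 1))`);
#' treated means are the control means scaled by `2^true_log2FC`, where the
#' true log2FC is `ontarget_lfc` for on-target genes, a truncated-normal
#' draw in `[-cap, 0]` for repressed genes (antisense-seed-match genes when
#' `seed_dependent`, a random subset of equal size otherwise), and 0 for
#' everything else. Counts are negative binomial with the configured size
#' parameter; library sizes are equal by construction (no per-sample depth
#' factor is drawn).
#'
#' @param universe Output of [generate_universe()].
#' @param config The same [synthetic_config()].
#' @return A `sirna_counts` list: integer `counts` matrix (genes x 2*reps),
#'   `groups` factor, and the universe `truth` extended with `true_log2FC`.
#' @export
generate_counts <- function(universe, config) {
  stopifnot(inherits(universe, "sirna_universe"),
            inherits(config, "synthetic_config"))
  set.seed(.stage_seed(config$rng_seed, 2L))
  truth <- universe$truth
  n <- nrow(truth)
  lfc <- numeric(n)
  repressed <- if (config$seed_dependent) {
    truth$is_seed_match & !truth$is_on_target
  } else {
    idx <- sample.int(n, round(config$frac_seed_match * n))
    seq_len(n) %in% idx & !truth$is_on_target
  }
  lfc[repressed] <- .rtrunc_norm(sum(repressed),
                                 config$offtarget_lfc_mean,
                                 config$offtarget_lfc_sd,
                                 -config$offtarget_lfc_cap, 0)
  lfc[truth$is_on_target] <- config$ontarget_lfc
  truth$is_repressed <- repressed
  truth$true_log2FC <- lfc
  mu_ctrl <- exp(rnorm(n, config$mean_log_expression, 1))
  mu_trt <- mu_ctrl * 2^lfc
  reps <- config$reps_per_group
  counts <- cbind(
    matrix(rnbinom(n * reps, mu = rep(mu_ctrl, reps), size = config$dispersion),
           nrow = n),
    matrix(rnbinom(n * reps, mu = rep(mu_trt, reps), size = config$dispersion),
           nrow = n))
  dimnames(counts) <- list(truth$gene_id,
                           c(paste0("control_", seq_len(reps)),
                             paste0("treated_", seq_len(reps))))
  structure(list(counts = counts,
                 groups = factor(rep(c("control", "treated"), each = reps),
                                 levels = c("control", "treated")),
                 truth = truth),
            class = "sirna_counts")
}

#' Lightweight differential-expression caller
#'
#' A deliberately simple stand-in for a count-model DE fit (it is *not* a
#' DESeq2 re-implementation): per-gene log2 fold change is
#' `log2((mean treated CPM + 0.5) / (mean control CPM + 0.5))`; the p-value
#' comes from a Welch two-sample t-test on `log2(CPM + 0.5)`; adjusted
#' p-values are Benjamini-Hochberg over tested genes. Genes with zero
#' counts in every sample are not tested (`padj` missing); genes with zero
#' variance in both groups get p = 1 when the group means are equal.
#'
#' @param counts Integer matrix (genes x samples) with row names, or a
#'   `sirna_counts` object.
#' @param groups Factor with two levels, control first; ignored when
#'   `counts` is a `sirna_counts`.
#' @return Tibble `gene_id`, `log2FC`, `pvalue`, `padj`.
#' @export
call_de <- function(counts, groups = NULL) {
  if (inherits(counts, "sirna_counts")) {
    groups <- counts$groups
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts), !is.null(groups), nlevels(factor(groups)) == 2L)
  groups <- factor(groups)
  if (min(table(groups)) < 2L) abort("at least 2 replicates per group")
  libsize <- colSums(counts)
  if (any(libsize == 0)) abort("a sample has zero total counts")
  cpm <- sweep(counts, 2L, libsize, "/") * 1e6
  ctrl <- groups == levels(groups)[1L]
  m_ctrl <- rowMeans(cpm[, ctrl, drop = FALSE])
  m_trt <- rowMeans(cpm[, !ctrl, drop = FALSE])
  log2fc <- log2((m_trt + 0.5) / (m_ctrl + 0.5))
  y <- log2(cpm + 0.5)
  n1 <- sum(ctrl); n2 <- sum(!ctrl)
  y1 <- y[, ctrl, drop = FALSE]; y2 <- y[, !ctrl, drop = FALSE]
  mu1 <- rowMeans(y1); mu2 <- rowMeans(y2)
  v1 <- rowSums((y1 - mu1)^2) / (n1 - 1L)
  v2 <- rowSums((y2 - mu2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (mu2 - mu1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1L)) + v2^2 / (n2^2 * (n2 - 1L)))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & mu1 == mu2] <- 1
  p[degenerate & mu1 != mu2] <- .Machine$double.xmin
  tested <- rowSums(counts) > 0
  padj <- rep(NA_real_, nrow(counts))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  tibble(gene_id = rownames(counts) %||% sprintf("gene_%05d", seq_len(nrow(counts))),
         log2FC = unname(log2fc),
         pvalue = unname(p),
         padj = padj)
}

#' End-to-end simulation of the seed-enrichment analysis
#'
#' For each of `n_sim` repetitions: generate a universe and counts, call
#' DE, classify, scan for antisense- and sense-seed sites, and run the
#' enrichment with both direction classes. Per-repetition seeds are
#' derived deterministically from the master `rng_seed`.
#'
#' @param config A [synthetic_config()].
#' @param n_sim Number of independent repetitions.
#' @param alpha Classification threshold passed to [classify_de()].
#' @return A `sirna_sim` object: `$results` (per-run enrichment rows),
#'   `$runs` (per-run truth-conditioned summary: class sizes, mean
#'   estimated log2FC among truly repressed genes), `$config`, `$alpha`.
#'   See [glance.sirna_sim()] for power/type-I summaries.
#' @export
end_to_end_sim <- function(config, n_sim = 1L, alpha = 0.05) {
  stopifnot(inherits(config, "synthetic_config"))
  n_sim <- as.integer(n_sim)
  results <- vector("list", n_sim)
  runs <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    cfg <- config
    cfg$rng_seed <- .stage_seed(config$rng_seed, 1000L + i)
    uni <- generate_universe(cfg)
    sim <- generate_counts(uni, cfg)
    de <- call_de(sim)
    classes <- classify_de(de, alpha = alpha)
    matches <- scan_set(uni$utrs, uni$duplex)
    analysis <- join_matches(classes, matches)
    enr <- run_enrichment(analysis)
    results[[i]] <- mutate(as_tibble(enr), run = i, .before = 1L)
    truth <- sim$truth
    est <- de$log2FC[match(truth$gene_id, de$gene_id)]
    repressed <- truth$true_log2FC < 0          # all genes with a planted effect
    off_only <- truth$is_repressed & !truth$is_on_target
    m <- function(x, keep) if (any(keep)) mean(x[keep]) else NA_real_
    runs[[i]] <- tibble(
      run = i,
      n_down = sum(classes$label == "down"),
      n_up = sum(classes$label == "up"),
      n_repressed = sum(repressed),
      mean_true_lfc_repressed = m(truth$true_log2FC, repressed),
      mean_est_lfc_repressed = m(est, repressed),
      mean_est_lfc_offtarget = m(est, off_only))
  }
  structure(list(results = bind_rows(results), runs = bind_rows(runs),
                 config = config, n_sim = n_sim, alpha = alpha),
            class = "sirna_sim")
}

#' @export
print.sirna_sim <- function(x, ...) {
  cat(sprintf("<sirna_sim> %d repetition(s), %d genes, alpha = %g\n",
              x$n_sim, x$config$n_genes, x$alpha))
  print(glance(x))
  invisible(x)
}
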