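# Orchestration: one-call analysis driver plus a thin command-line layer
# (exec/seedtox) over the exported functions. Data go to files, logging to
# standard error, and every subcommand leaves a JSON run-manifest from
# which its outputs can be regenerated (`seedtox rerun --manifest ...`).

#' Build a duplex from an antisense strand alone
#'
#' Constructs the complementary sense strand (unmodified ribo backbone,
#' `UU` 3'-overhang) for situations where only the antisense sequence is
#' known. Seed analysis depends on bases only, so the placeholder
#' chemistry is irrelevant downstream.
#'
#' @param antisense An `oligo_strand` or annotated string.
#' @param overhang_length 3'-overhang length (default 2).
#' @return A `sirna_duplex`.
#' @export
complementary_duplex <- function(antisense, overhang_length = 2L) {
  if (is.character(antisense)) antisense <- parse_strand(antisense)
  overhang_length <- as.integer(overhang_length)
  lp <- strand_length(antisense) - overhang_length
  if (lp < 1L) abort("overhang leaves no paired region")
  paired <- reverse_complement(paste(strand_bases(antisense)[seq_len(lp)],
                                     collapse = ""), "RNA")
  sense <- parse_strand(paste0(paired, strrep("U", overhang_length)))
  sirna_duplex(antisense, sense, overhang_length)
}

#' Run the full seed-mediated off-target analysis
#'
#' Loads UTRs and a DE table, scans for antisense- and sense-seed sites,
#' classifies genes, and computes the enrichment panels with strand and
#' direction controls.
#'
#' @param utrs UTR tibble from [load_utrs()] or a FASTA path.
#' @param de DE tibble or a TSV path for [read_de_table()].
#' @param duplex A `sirna_duplex`, or an annotated antisense string (the
#'   sense strand is then inferred with [complementary_duplex()]).
#' @param specs Seed windows (default antisense and sense 2-8).
#' @param alpha,min_abs_lfc Classification thresholds.
#' @param selection Per-gene UTR isoform rule for FASTA input.
#' @return An `offtarget_run` list: `$enrichment` (a `seed_enrichment`),
#'   `$analysis` (joined gene-level table), `$volcano` (antisense-window
#'   volcano table), `$n_no_utr`.
#' @export
run_offtarget_analysis <- function(utrs, de, duplex,
                                   specs = list(seed_spec("antisense"),
                                                seed_spec("sense")),
                                   alpha = 0.05, min_abs_lfc = 0,
                                   selection = "longest") {
  if (is.character(utrs)) utrs <- load_utrs(utrs, selection = selection)
  if (is.character(de)) de <- read_de_table(de)
  if (is.character(duplex)) duplex <- complementary_duplex(duplex)
  stopifnot(inherits(duplex, "sirna_duplex"))
  matches <- scan_set(utrs, duplex, specs)
  classes <- classify_de(de, alpha = alpha, min_abs_lfc = min_abs_lfc)
  analysis <- join_matches(classes, matches)
  enrichment <- run_enrichment(analysis)
  first_label <- specs[[1L]]$label
  volcano <- volcano_export(de, matches, spec_label = first_label,
                            alpha = alpha, min_abs_lfc = min_abs_lfc)
  structure(list(enrichment = enrichment, analysis = analysis,
                 volcano = volcano, n_no_utr = attr(analysis, "n_no_utr")),
            class = "offtarget_run")
}

#' @export
print.offtarget_run <- function(x, ...) {
  cat(sprintf("<offtarget_run> %d genes tested, %d without UTR dropped\n",
              length(unique(x$analysis$gene_id)), x$n_no_utr))
  print(as_tibble(x$enrichment))
  invisible(x)
}

#' @method autoplot offtarget_run
#' @export
autoplot.offtarget_run <- function(object, ...) autoplot(object$volcano, ...)

# ---- command-line layer ----------------------------------------------------

.cli_log <- function(...) message("[seedtox] ", sprintf(...))

# "--key value" pairs (keys normalized to underscores); bare flags -> TRUE
.parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) abort(sprintf("unexpected argument '%s'", a))
    key <- gsub("-", "_", substring(a, 3L))
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}

.opt <- function(opts, key, default = NULL) {
  if (!is.null(opts[[key]])) opts[[key]] else default
}

.need <- function(opts, key) {
  if (is.null(opts[[key]])) abort(sprintf("missing required option --%s",
                                          gsub("_", "-", key)))
  opts[[key]]
}

.out_dir <- function(opts) {
  dir <- .need(opts, "out")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

.write_manifest <- function(dir, command, opts) {
  manifest <- list(tool = "seedtox",
                   version = as.character(utils::packageVersion("seedtox")),
                   command = command,
                   params = opts)
  path <- file.path(dir, paste0("manifest_", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.cli_duplex <- function(opts) {
  if (!is.null(opts$duplex_tsv)) {
    tab <- read_duplex_tsv(opts$duplex_tsv)
    return(tab$duplex[[1L]])
  }
  anti <- .need(opts, "antisense")
  if (!is.null(opts$sense))
    sirna_duplex(anti, opts$sense, as.integer(.opt(opts, "overhang", 2L)))
  else
    complementary_duplex(anti, as.integer(.opt(opts, "overhang", 2L)))
}

.cli_scan <- function(opts) {
  dir <- .out_dir(opts)
  utrs <- load_utrs(.need(opts, "utrs"), .opt(opts, "selection", "longest"))
  duplex <- .cli_duplex(opts)
  matches <- scan_set(utrs, duplex)
  write_scan_tsv(matches, file.path(dir, "scan.tsv"))
  .cli_log("scanned %d genes for %d seed window(s)",
           length(unique(matches$gene_id)), length(unique(matches$spec_label)))
  .write_manifest(dir, "scan", opts)
}

.cli_classify <- function(opts) {
  dir <- .out_dir(opts)
  classes <- classify_de(read_de_table(.need(opts, "de")),
                         alpha = as.numeric(.opt(opts, "alpha", 0.05)),
                         min_abs_lfc = as.numeric(.opt(opts, "min_lfc", 0)))
  readr::write_tsv(classes, file.path(dir, "classes.tsv"))
  .cli_log("classified %d genes (%d down, %d up)",
           nrow(classes), sum(classes$label == "down"), sum(classes$label == "up"))
  .write_manifest(dir, "classify", opts)
}

.cli_enrich <- function(opts) {
  dir <- .out_dir(opts)
  run <- run_offtarget_analysis(
    utrs = .need(opts, "utrs"), de = .need(opts, "de"),
    duplex = .cli_duplex(opts),
    alpha = as.numeric(.opt(opts, "alpha", 0.05)),
    min_abs_lfc = as.numeric(.opt(opts, "min_lfc", 0)),
    selection = .opt(opts, "selection", "longest"))
  readr::write_tsv(as_tibble(run$enrichment), file.path(dir, "enrichment.tsv"))
  readr::write_tsv(as_tibble(run$volcano), file.path(dir, "volcano.tsv"))
  readr::write_tsv(run$analysis, file.path(dir, "analysis.tsv"))
  .cli_log("enrichment written; antisense-down p = %.3g",
           run$enrichment$p_one_sided[run$enrichment$direction == "down" &
             grepl("^antisense", run$enrichment$spec_label)][1L])
  .write_manifest(dir, "enrich", opts)
}

.cli_simulate <- function(opts) {
  dir <- .out_dir(opts)
  cfg <- if (!is.null(opts$config)) read_synthetic_config(opts$config)
         else synthetic_config()
  if (!is.null(opts$seed)) cfg$rng_seed <- as.integer(opts$seed)
  uni <- generate_universe(cfg)
  sim <- generate_counts(uni, cfg)
  de <- call_de(sim)
  run <- run_offtarget_analysis(uni$utrs, de, uni$duplex,
                                alpha = as.numeric(.opt(opts, "alpha", 0.05)))
  readr::write_tsv(as_tibble(sim$counts, rownames = "gene_id"),
                   file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(de, file.path(dir, "de.tsv"))
  readr::write_tsv(as_tibble(run$enrichment), file.path(dir, "enrichment.tsv"))
  .cli_log("simulated %d genes (seed %d)", cfg$n_genes, cfg$rng_seed)
  .write_manifest(dir, "simulate", opts)
}

.cli_design <- function(opts) {
  dir <- .out_dir(opts)
  duplex <- .cli_duplex(opts)
  op <- .need(opts, "op")
  duplex <- switch(
    op,
    gna = place_gna(duplex, as.integer(.opt(opts, "position", 7L))),
    cap = set_cap(duplex, .opt(opts, "strand", "antisense"),
                  .opt(opts, "cap", "iB")),
    swap = {
      donor <- sirna_duplex(.need(opts, "donor_antisense"),
                            .need(opts, "donor_sense"),
                            as.integer(.opt(opts, "overhang", 2L)))
      swap_seed(duplex, donor)
    },
    abort(sprintf("unknown design op '%s' (use gna, cap or swap)", op)))
  readr::write_tsv(
    tibble(duplex_id = .opt(opts, "duplex_id", "designed"),
           antisense = serialize_strand(duplex$antisense),
           sense = serialize_strand(duplex$sense),
           overhang_length = duplex$overhang_length,
           risc_loading_competent = risc_loading_competent(duplex)),
    file.path(dir, "duplex.tsv"))
  readr::write_tsv(mod_composition(duplex$antisense),
                   file.path(dir, "composition.tsv"))
  .cli_log("design op '%s' applied", op)
  .write_manifest(dir, "design", opts)
}

.cli_reversir <- function(opts) {
  dir <- .out_dir(opts)
  hits <- screen_reversir(.need(opts, "oligo"),
                          read_mirna_fasta(.need(opts, "mirnas")),
                          oligo_id = .opt(opts, "oligo_id", "oligo"),
                          wobble = isTRUE(.opt(opts, "wobble", FALSE)))
  readr::write_tsv(hits, file.path(dir, "reversir_hits.tsv"))
  .cli_log("%d complementarity hit(s); verdict: %s", nrow(hits),
           if (nrow(hits) == 0L) "clean" else "NOT clean")
  .write_manifest(dir, "reversir", opts)
}

.cli_all <- function(opts) {
  .cli_enrich(opts)
  if (!is.null(opts$oligo) && !is.null(opts$mirnas)) .cli_reversir(opts)
  .write_manifest(.out_dir(opts), "all", opts)
}

.cli_rerun <- function(opts) {
  manifest <- jsonlite::read_json(.need(opts, "manifest"), simplifyVector = TRUE)
  if (!identical(manifest$tool, "seedtox")) abort("not a seedtox manifest")
  .cli_dispatch(manifest$command, as.list(manifest$params))
}

.cli_dispatch <- function(command, opts) {
  switch(command,
         scan = .cli_scan(opts),
         classify = .cli_classify(opts),
         enrich = .cli_enrich(opts),
         simulate = .cli_simulate(opts),
         design = .cli_design(opts),
         reversir = .cli_reversir(opts),
         all = .cli_all(opts),
         rerun = .cli_rerun(opts),
         abort(sprintf("unknown subcommand '%s'", command)))
  invisible(NULL)
}

#' Command-line entry point
#'
#' Dispatches the `seedtox` subcommands (`scan`, `classify`, `enrich`,
#' `simulate`, `design`, `reversir`, `all`, `rerun`). Used by the
#' `exec/seedtox` script; calling it directly is convenient in tests.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: seedtox",
                 "<scan|classify|enrich|simulate|design|reversir|all|rerun>",
                 "[--option value ...]")
  if (length(args) == 0L) {
    message(usage)
    return(invisible(2L))
  }
  status <- tryCatch({
    .cli_dispatch(args[[1L]], .parse_cli_args(args[-1L]))
    0L
  }, error = function(e) {
    message("[seedtox] error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
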