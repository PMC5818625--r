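# broom-style tidiers for result objects.

#' Tidy a seed-enrichment result
#'
#' @param x A `seed_enrichment` tibble from [run_enrichment()].
#' @param ... Unused.
#' @return A plain tibble (one row per seed window x direction).
#' @method tidy seed_enrichment
#' @export
tidy.seed_enrichment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "seed_enrichment")
  as_tibble(out)
}

#' One-row summary of a seed-enrichment result
#'
#' @param x A `seed_enrichment` tibble from [run_enrichment()].
#' @param ... Unused.
#' @return Tibble with the number of tested panels, the antisense-down
#'   p-value (the signal panel, when present) and the smallest control
#'   p-value.
#' @method glance seed_enrichment
#' @export
glance.seed_enrichment <- function(x, ...) {
  signal <- x$p_one_sided[grepl("^antisense", x$spec_label) & x$direction == "down"]
  ctrl <- x$p_one_sided[!(grepl("^antisense", x$spec_label) & x$direction == "down")]
  tibble(n_panels = nrow(x),
         n_genes = sum(x$a[1L], x$b[1L], x$c[1L], x$d[1L]),
         p_signal = if (length(signal)) min(signal) else NA_real_,
         min_p_control = if (length(ctrl)) min(ctrl) else NA_real_)
}

#' Tidy an end-to-end simulation
#'
#' @param x A `sirna_sim` from [end_to_end_sim()].
#' @param ... Unused.
#' @return Per-run enrichment rows joined with the per-run truth summary.
#' @method tidy sirna_sim
#' @export
tidy.sirna_sim <- function(x, ...) {
  left_join(x$results, x$runs, by = "run")
}

#' Power / calibration summary of an end-to-end simulation
#'
#' Rates are computed at the simulation's classification `alpha` (0.05 by
#' default) and, for the signal panel, also at the stricter 1e-3 level
#' used for power statements.
#'
#' @param x A `sirna_sim` from [end_to_end_sim()].
#' @param ... Unused.
#' @return One-row tibble: rejection rates for the antisense-down signal
#'   panel and the sense-strand / up-direction controls, plus the mean
#'   estimated and true log2FC among repressed genes.
#' @method glance sirna_sim
#' @export
glance.sirna_sim <- function(x, ...) {
  r <- x$results
  pick <- function(spec, dir) r$p_one_sided[grepl(spec, r$spec_label) & r$direction == dir]
  sig <- pick("^antisense", "down")
  sense_down <- pick("^sense", "down")
  anti_up <- pick("^antisense", "up")
  tibble(
    n_sim = x$n_sim,
    reject_rate_signal = mean(sig < x$alpha),
    power_signal_1e3 = mean(sig < 1e-3),
    median_p_signal = stats::median(sig),
    reject_rate_sense_down = mean(sense_down < x$alpha),
    reject_rate_antisense_up = mean(anti_up < x$alpha),
    mean_est_lfc_repressed = mean(x$runs$mean_est_lfc_repressed, na.rm = TRUE),
    mean_true_lfc_repressed = mean(x$runs$mean_true_lfc_repressed, na.rm = TRUE))
}
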