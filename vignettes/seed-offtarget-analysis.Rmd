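---
title: "Seed-mediated off-target analysis of modified siRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-mediated off-target analysis of modified siRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedtox)
```

## The scientific question

Hepatocyte-targeted (GalNAc-conjugated) siRNAs can repress unintended
transcripts through the same mechanism endogenous miRNAs use: the guide
(antisense) strand's *seed region*, nucleotides 2–8 counted from its
5′ end, pairs with perfectly complementary 7-mer sites in 3′UTRs. This
miRNA-like activity produces many mild repressions — typically well under
twofold — and is a leading driver of sequence-dependent hepatotoxicity.
The signature that distinguishes seed-mediated off-targeting from
chemistry- or delivery-related effects is an *asymmetric enrichment*:

* transcripts downregulated after treatment are enriched for 3′UTR sites
  complementary to the **antisense** seed;
* upregulated transcripts show no such enrichment;
* sites complementary to the **sense**-strand seed show no enrichment in
  either direction.

`seedtox` implements that analysis as a reusable, tested pipeline, together
with the in-silico counterparts of the design interventions used to probe
the mechanism (5′-caps that block RISC loading, seed swapping, a
destabilizing GNA residue at antisense position 7, and a REVERSIR–miRNA
complementarity screen), and a synthetic-data generator that reproduces the
statistical structure the analysis assumes.

## The statistic

For one seed window and one regulation direction the pipeline builds a
2×2 contingency table over all tested genes with a UTR:

|            | seed match | no match |
|------------|-----------:|---------:|
| down       | a          | b        |
| not down   | c          | d        |

and computes the one-sided Fisher exact p-value
$P(X \ge a)$ under the central hypergeometric law with the table's
margins — the probability of seeing at least the observed enrichment of
matches among downregulated genes if match status were independent of
regulation. The two-sided minimum-likelihood p-value is reported alongside
for completeness; the scientific claim ("enriched") is directional, so the
one-sided value is primary. All factorials are evaluated in log space
(`lchoose` + log-sum-exp), so the computation is exact and overflow-safe at
transcriptome scale and beyond (margins of 10^5 are unproblematic).

Gene-level *presence/absence* of a site (`count >= 1`) feeds the table:
the 2×2 test requires a dichotomy, and site-count dose-response modelling
is out of scope. Odds ratios use the Haldane 0.5 correction only when a
zero cell is present, and are flagged when they do.

A classified gene is `down` when its BH-adjusted p-value is at most
`alpha` (default 0.05, the conventional volcano-colouring threshold) *and*
its log2 fold change is negative; `up` symmetrically; `excluded` when the
adjusted p is missing (the upstream tool never tested it — such genes are
left out of the table rather than pooled with "unchanged", because they
carry no evidence either way). There is no fold-change cutoff by default
(`min_abs_lfc = 0`): seed-mediated repression is mostly sub-twofold, and a
cutoff would erase exactly the signal being tested.

## Scanning

UTRs are scanned for *exact, possibly overlapping* occurrences of the
site — the reverse complement of the seed window, written in DNA letters.
Coordinates are 1-based and fully closed; windows containing `N` never
match; matching is confined to the annotated 3′UTR (no CDS or 5′UTR).
When a gene has several isoform UTRs the default keeps the longest
(maximizing site sensitivity); `first` and `concatenate` rules are
available. Wobble pairing, single mismatches, and context/conservation
scores are deliberately out of scope: the tested hypothesis concerns
perfect seed complements only.

```{r toy}
dx <- complementary_duplex("UUACGCAUAAAGUCUUGGCUU")
extract_seed(dx)          # antisense nucleotides 2-8
seed_site(dx)             # the 7-mer a 3'UTR must contain
```

## The oligonucleotide model

A strand is an ordered list of residues (base, sugar, 3′ linkage) plus a
5′-cap and 3′-conjugate annotation; positions are numbered 1-based from
the 5′ end and caps are *not* residues, so "position 7" is unambiguous.
The text notation is compact: `m`/`f`/`d`/`l`/`(gna)` sugar prefixes,
`*` for phosphorothioate, `[iB]`/`[mor]`/`[5d]` caps, `[GalNAc]`
conjugate. Parsing and serialization are exact inverses on canonical
strings.

Duplexes pair antiparallel over their lengths minus a 3′ overhang
(default 2 nt, the canonical 21-mer architecture); U and T are equivalent
for pairing; abasic residues never pair and are only legal at termini.
Design operations preserve this invariant by construction and re-validate
it on every call:

* `set_cap()` — RISC-loading competence is `FALSE` exactly when the
  *antisense* 5′ end is capped; capping the sense strand alone changes
  nothing, mirroring the strand asymmetry of RISC loading.
* `swap_seed()` — transplants antisense bases 2–8 between compounds and
  repairs the paired sense bases, leaving every chemical annotation in
  place, so the seed sequence and the modification pattern can be varied
  independently.
* `place_gna()` — swaps the sugar at one antisense position (canonically
  7) to glycol nucleic acid; bases are untouched, so seed extraction is
  unaffected. Thermodynamic modelling of the destabilization is a
  non-goal; the operation records the design, it does not predict ΔTm.
* `mod_composition()` — percentage of each sugar chemistry over residues
  (phosphorothioate linkages counted separately), the accounting used to
  compare high-2′F and low-2′F designs.

## The synthetic transcriptome

The generator produces what the analysis consumes, with known ground
truth, so every stage and the end-to-end claim are testable without any
external download. One `synthetic_config()` drives three stages
(universe → counts → DE), each seeded deterministically from the master
`rng_seed`, so identical configs give byte-identical output.

Defaults describe the regime the analysis targets, and were fixed once:

| parameter | default | why |
|---|---|---|
| `n_genes` | 2000 | enough genes for a stable 2×2 table while keeping simulation studies fast |
| `utr_length_range` | 200–2000 nt | spans typical mammalian 3′UTR lengths; uniform for simplicity |
| `base_composition` | uniform A/C/G/T | no compositional structure is assumed by the test |
| `frac_seed_match` | 0.15 | planted antisense-site fraction; sense sites planted into a disjoint fraction of equal size |
| `offtarget_lfc_mean`, `offtarget_lfc_sd` | −0.6, 0.2 (log2) | mild, mostly sub-twofold repression |
| `offtarget_lfc_cap` | 1.0 (log2) | hard twofold ceiling on off-target magnitudes |
| `ontarget_lfc` | −2.5 | one strong on-target knockdown |
| `reps_per_group` | 3 | treated vs control group sizes |
| `mean_log_expression` | log(500) | log-normal control means (natural-log sd 1), median ≈ 500 counts |
| `dispersion` | 1000 (NB size) | near-Poisson noise, the technical-replicate / same-prep regime |

The noise level deserves a note. The emulated experiment uses *technical*
replicates of a cell transfection, and the regime the analysis assumes is
one in which sub-twofold repressions are individually detectable at
`padj <= 0.05` — that requires near-Poisson replicate noise
(count-model dispersion on the order of 10^-3), which is what same-prep
technical replicates deliver. With biological-replicate dispersions
(0.01–0.1) a 6-sample t-test cannot see 1.5-fold changes, the
downregulated class collapses, and no enrichment analysis of this design
is informative; that regime is *not* what the pipeline models.

Truth is **recomputed, never assumed**: after planting, the generator
re-scans its own UTRs, so chance seed matches (≈6–7% of genes at these
UTR lengths) are part of the recorded truth and receive planted repression
exactly like deliberately planted sites. On-target genes carry a
full-length antisense complement. Sense-site genes receive *no* effect,
and nothing is tied to upregulation — the two control panels are null by
construction.

### The stand-in DE caller

`call_de()` is deliberately simple and is **not** a DESeq2
re-implementation: log2 fold change of mean CPM with a 0.5 pseudocount, a
Welch t-test on `log2(CPM + 0.5)`, and Benjamini–Hochberg adjustment over
tested genes. All-zero genes are untested (`padj` missing, excluded
downstream); zero-variance genes with equal means get p = 1.

One consequence is documented rather than hidden: CPM normalization
carries a *composition bias*. When ~20% of genes lose ~35% of their
expression, treated library totals drop by ~7%, and every per-gene
estimate shifts by ≈ +0.10 log2 units. The median-of-ratios normalization
of a full count-model fit avoids this; the stand-in does not. Parameter-
recovery checks therefore see planted means recovered with a ≈0.1 upward
shift, right at the edge of their tolerance — a property of the simple
caller, not of the enrichment machinery, which conditions only on the
*ranking* into classes.

### Calibration null

For type-I calibration of the enrichment test, setting all true effects
to zero is degenerate: with BH control the downregulated class is almost
always empty, the table has an empty margin, and the one-sided p is
identically 1 (a unit test pins this behaviour). The informative null is
*repression that exists but ignores seed matches*:
`seed_dependent = FALSE` assigns the same truncated-normal repression to a
random gene subset of the same size, independent of match status. Under
that null the antisense-down p-value is approximately uniform and the
rejection rate at α = 0.05 sits near the nominal level (slightly below,
as expected for an exact conditional test).

## REVERSIR screening

`screen_reversir()` reports every miRNA window that is the exact reverse
complement of the whole oligo — the check that a REVERSIR compound (or a
scrambled control) cannot silence an endogenous liver miRNA instead of
its intended siRNA target. "Full complementarity" is taken strictly: G·U
wobble pairs do not count unless `wobble = TRUE` is requested. Which
miRNAs count as liver-expressed is the caller's responsibility; the
screen processes whatever list it is given. An empty hit table is the
"clean" verdict.

## Numerical and interface choices

* Fisher p-values: log-space tail sums; two-sided set selected with a
  1e-7 relative tie tolerance (matching the reference implementation in
  `stats::fisher.test`). Note the two-sided minimum-likelihood p can
  exceed twice the one-sided p when the observed table is modal.
* `padj = 0` is clamped to the smallest positive double before
  `-log10` in volcano exports.
* Per-stage RNG seeds derive from the master seed by a Lehmer step
  (`(seed * 48271 + stage) mod (2^31 - 1)`), keeping every derived seed a
  valid 32-bit integer and every stage independently reproducible.
* All user-facing functions take and return tibbles, so the pipeline
  composes with the usual tidyverse verbs; `tidy()`/`glance()` methods
  summarize enrichment results and simulation studies, `autoplot()`
  renders volcano and enrichment panels.
* Subcommands of the `exec/seedtox` script write TSV outputs plus a JSON
  run-manifest; `seedtox rerun --manifest <file>` regenerates any output
  from its manifest alone.

## Problem sizes used in the checks

The package's own simulation studies use 2000-gene transcriptomes with
3 vs 3 replicates: 200 repetitions for the power/asymmetry study and 1000
repetitions for type-I calibration, plus an exhaustive Fisher sweep over
all 2×2 tables with total ≤ 60 and a 1000-UTR scanning comparison against
naive enumeration. These sizes give binomial standard errors below one
percentage point on the reported rates while keeping a full re-run on a
single CPU in the minutes range.

## What passing tests do and do not show

The generator reproduces the *statistical skeleton* of a real
transcriptome response: mild seed-linked repression with a hard twofold
cap, one strong knockdown, null sense-strand and up-direction panels, and
NB counting noise. It does not model isoform structure, 5′UTR/CDS sites,
supplementary 3′-region pairing (available as nothing — deliberately
omitted), GC-content or conservation structure in UTRs, correlated genes,
library-size variation, or miRNA competition. Green simulation checks
therefore certify the pipeline's statistics and bookkeeping, not the
biology of any particular compound; on real data the usual caveats about
annotation quality and normalization apply, and the DE input should come
from a proper count model rather than the built-in stand-in.
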