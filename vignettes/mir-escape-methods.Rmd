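---
title: "Detecting miRNA target escape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA target escape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirEscape)
```

## The question

Over-expressing a miRNA should repress its predicted targets, yet in
over-expression screens a reproducible subset of seed-site-carrying genes
goes *up* instead. Two transcript-level mechanisms can explain such escape
without invoking any change in the miRNA machinery: **3'UTR shortening**
(alternative polyadenylation produces isoforms whose truncated 3'UTR no
longer contains the seed site) and **isoform variance** (expression shifts
toward pre-existing isoforms that never carried the targeted UTR).
`mirEscape` implements the full desk analysis of such a screen — seed-site
scanning, expression classification, coverage-based shortening calls,
isoform escape scoring, and pathway over-representation — together with a
synthetic-data generator that plants known structure so every stage can be
validated end to end. The worked reference throughout is a miR-155
over-expression screen in MCF-7 breast-cancer cells, whose published cohort
tables ship with the package (`transcribe_fixture_tables()`).

## Seed-site model

For a mature miRNA (5'->3', positions 1-based) the scanner derives the
three canonical site classes from the seed region (positions 2–8):

* **8mer** — reverse complement of positions 2–8, followed by an `A`
  opposite position 1;
* **7mer-m8** — reverse complement of positions 2–8;
* **7mer-A1** — reverse complement of positions 2–7, followed by `A`.

These are the community-standard definitions; the source screen used only
the labels "8-mer" and "7-mer", so adopting the canonical classes was a
design decision. Sites are reported with **maximal-type labelling**: a
position matching the 8mer is one 8mer site, never additionally its
embedded 7mers, so per-gene 7mer/8mer counts are disjoint, matching the
published tabulation. The 7mer column pools 7mer-m8 and 7mer-A1 by
default; `seven_mer = "m8_only"` restricts it, since the original screen's
definition of "7-mer" is not recorded. Wobble (G:U) pairing, 6mers,
conservation and context scoring are out of scope. Only the sense strand
of the provided UTR sequence is scanned; `extract_utrs()` resolves strand
at extraction time (minus-strand models are reverse-complemented), and
coordinate conventions are converted at the reader boundary (BED 0-based
half-open, GFF3 1-based inclusive; internally sites are 0-based
half-open).

## Expression classification

Expression is quantified as RPKM (reads per kilobase of exon model per
million mapped reads) per condition, and each gene's fold change is the
miR-155/vector RPKM ratio. Classification follows the screen's printed
rules, with boundary conventions fixed as:

| label | rule |
|---|---|
| `low_read_excluded` | both raw counts **strictly below 10** |
| `repressed` | fold **<= 0.5** (inclusive) |
| `increased` | fold **> 1.5** (strict) |
| `unchanged` | otherwise |

The screen applied the read filter only to its increased cohort; here the
filter is evaluated first for **all** genes (a symmetric rule), with
`filter_scope = "increased_only"` reproducing the original workflow
exactly. The read floor is interpreted in raw aligned reads, not RPKM
units. The fold-change pseudocount defaults to 0 with an explicit error on
zero denominators — shifting folds silently would move genes across the
printed thresholds; simulated single-library data typically needs
`pseudocount = 0.5`. With a single library per condition there is no
replicate-based inference here by design; `repressed`/`increased` are
threshold labels, not significance calls.

Fold histograms (`fold_histogram()`) use right-open bins `[a, b)` with the
final bin closed, so bin counts always sum to the number of selected
genes; selection can be restricted to genes with any site, an 8mer site,
or a 7mer site, mirroring the screen's three distribution views.

## Shortening and seed loss

The source screen called 3'UTR shortening by eye in a genome browser.
`mirEscape` formalises that read-off in the style of standard APA
analysis:

1. **Changepoint.** `fit_breakpoint()` fits a two-segment
   piecewise-constant model by exhaustive least squares on
   `log2(coverage + 1)` (the log transform stabilises high-coverage
   variance; a raw-scale option exists and is scale-invariant). Ties break
   to the smallest index; a split that does not reduce the one-segment RSS
   flags the track as flat.
2. **Distal usage index (DUI).** Mean coverage beyond the breakpoint over
   mean coverage before it, with a 0.5 pseudocount guarding empty
   segments. DUI near 1 means full-length usage; near 0, shortening.
3. **Between-condition call.** The breakpoint is fitted on the miR-155
   track only — the condition interrogated for shortening — and the same
   split is applied to the vector track (an asymmetric design matching the
   asymmetric question). The transcript is `shortened` when
   `dui_mir155 / dui_vector <= tau` (default 0.5), the miR-155 proximal
   mean clears 5x coverage, and the track is not flat. `seed_lost`
   additionally requires a seed site lying entirely at or beyond the
   breakpoint, and therefore always implies `shortened`.

Tracks with mean coverage below 1x in either condition fail QC and produce
no call (`NA`, not `FALSE`): absence of evidence is not called full-length
usage. A transcript whose *vector* track already shows negligible distal
usage (DUI <= 0.1) is annotated `lost_in_both`, the pattern the screen
observed for MAP3K10. The default minimum segment is 25 bp, capped at a
tenth of the UTR for short UTRs — small enough to localise breakpoints in
400 bp UTRs, large enough that single-base spikes cannot anchor a
segment. Multi-breakpoint segmentation and replicate-based DUI testing
are out of scope (the screen had one library per condition).

Isoform-level escape is scored separately: `seed_escape_fraction()` is the
expression-weighted fraction of a gene's isoforms that do not carry the
seed-bearing 3'UTR — e.g. truncated variants of a kinase whose other
isoforms are targeted.

## Over-representation

The screen's hosted pathway service scored pathways by an undocumented
affinity measure that cannot be reproduced; the package substitutes the
standard over-representation statistic, the hypergeometric upper tail
`P(X >= k)` for an overlap of `k` between a query list and a set of size
`K` in a universe of `N`, with Benjamini–Hochberg q-values (the original
analysis stated no multiplicity correction; q-values are additional
output, not a reinterpretation). The published pathway rankings are
therefore qualitative context, not a quantitative target. The universe
defaults to all genes with detectable expression in the counts table
(config-overridable to the GMT union); identifiers match
case-insensitively, and aliasing/ID-mapping is out of scope. Ties in the
ranking break by descending overlap, then set name, so output order is
deterministic.

## The synthetic screen

`simulate_screen()` emits a complete, truth-annotated screen: UTR FASTA
with planted sites, BED12 models, a two-condition counts table, two
bedGraph coverage tracks, a GMT collection and the truth table. Generative
assumptions:

* **Counts** are negative binomial, `NB(mu, phi)` with dispersion
  `phi = 0.05` and means log-uniform on 100–2000 — with one library per
  condition the dispersion models biological burstiness, not replicate
  variance. The miR-155 mean is `mu * fold`, with up-gene folds
  log-uniform on 2–6 and down-gene folds on 0.15–0.5. Ten genes default to
  mean 1 in both conditions, putting both counts below the read floor with
  probability >= 0.99.
* **Sequence.** Background UTRs (400–1200 bp) are drawn motif-free by
  rejection sampling; motifs are planted at recorded offsets (8mer distal,
  around 55–88 % of the UTR; 7mer proximal) and each record is re-scanned
  so the emitted truth is exact by construction.
* **Coverage** is per-base Poisson at 50x scaled by the condition's fold;
  for half of the increased 8mer targets the miR-155 rate drops by a
  factor of 8 beyond a breakpoint planted proximal to the seed — a
  seed-loss event. These defaults (depth 50, step 8) describe a clear but
  noisy event, the regime the detector is designed for.
* **Gene sets.** One planted set samples members with 8:1 odds in favour
  of true up-genes; the rest are uniform.

One seed drives all stages in a fixed order: a fixed configuration
reproduces every file byte for byte. What the generator does *not*
emulate: positional biases and mappability structure in real coverage,
correlated expression between genes, 3'-seq-style polyadenylation-site
evidence, sequencing error, and genuine biological APA heterogeneity.
Passing the planted-recovery tests therefore demonstrates that the
statistics detect the structure they define, under their stated noise
model — not performance on real libraries.

`mimic_screen()` is a separate, deterministic preset that reproduces the
published cohort structure exactly: 30 increased-expression 8mer targets,
14 below the read floor, 16 retained with fold changes equal to the
printed relative-expression values, and coverage steps following the
published per-gene shortening flags. Counts are constructed rather than
sampled because the preset's contract is cohort arithmetic, not noise.
The transcribed tables disagree internally in two places — one gene is
marked shortened in the target table but not in the site table, and the
narrative count (ten) differs from the eleven flagged rows — and the
package surfaces both tables verbatim rather than adjudicating.

## Problem sizes and numerical choices

The shipped validation uses desk-scale experiments chosen for statistical
resolution: 1000 random sequences against the brute-force scanner oracle;
500 random tracks (length <= 200) against exhaustive RSS minimisation;
200 simulated transcripts (about half planted) for seed-loss sensitivity
and false-positive rates; exhaustive hypergeometric enumeration for all
universes up to N = 12 plus a 500-run null calibration at universe 500 /
set 50 / query about 125, a size at which the discrete null is
fine-grained enough for rejection rates to sit near the nominal level.
Degenerate inputs are handled explicitly rather than coerced: empty
sequences scan to empty tables, flat tracks are flagged instead of called,
zero total isoform expression is an error, and inconsistent hypergeometric
counts are rejected.

## Known limitations

* Shortening calls are descriptive (threshold-based), not inferential;
  with n = 1 per condition no p-value is attached to a DUI ratio.
* The changepoint model allows exactly one breakpoint; tandem APA with
  multiple sites collapses to the strongest step.
* Identifier handling assumes symbol equality; cross-annotation mapping
  belongs upstream.
* The scanner treats all seed matches equally; site context (AU content,
  supplementary pairing) is deliberately out of scope.
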