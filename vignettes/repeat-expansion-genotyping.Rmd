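---
title: "Genotyping interrupted repeat expansions from noisy long reads"
author: "RepeatSpan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping interrupted repeat expansions from noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RepeatSpan)
```

## The problem

Spinocerebellar ataxia type 36 (SCA36) is caused by a GGCCTG
hexanucleotide repeat expansion in intron 1 of *NOP56*. Normal alleles
carry on the order of 3–14 units; pathogenic alleles carry more than 650
and up to several thousand, i.e. tracts of roughly 4–15 kb of
GC-rich repeat. Such tracts cannot be crossed by short reads or sized
precisely by fragment analysis, but single-molecule long reads (PacBio
CLR-class, with a random 11–15% per-base error rate dominated by indels)
can span them end to end. Three analysis questions follow:

1. **Which reads span the repeat?** Reads must be sorted by whether they
   cover the whole tract (on either strand) or only enter it from the 5'
   or 3' side.
2. **How many core units does each spanning read carry?** Per-read
   counts against the strict `> 650` pathogenic threshold give a
   per-sample diagnostic table, and their spread reflects somatic
   heterogeneity of the expansion.
3. **What is the tract made of?** Expansions are not pure
   (GGCCTG)~n~: variant units such as GGCTG, GGCCCTG, GGCCG and GGCCTTG
   interrupt the core. Decomposing each tract into motif tokens yields
   per-motif nucleotide ratios and per-read "waterfall" schematics.

RepeatSpan implements this workflow end to end, together with a
ground-truthed synthetic read generator so that every stage is testable
at desk scale without any sequencing download.

## Spanning-read classification

Rather than aligning reads to a whole genome, the classifier uses the
two *flank anchors* — the innermost `anchorK = 30` bp of the left and
right flank of the repeat locus. Each anchor is aligned semi-globally
(anchor end-to-end against the best-matching read infix, unit edit
costs) against the read and against its reverse complement. A hit is
accepted iff its edit distance is at most
`ceiling(maxEditFraction * anchorK)`; the default `maxEditFraction =
0.25` (8 of 30) tolerates the CLR error band affecting both the anchor
bases and the read. Classes follow from the hit pattern:

* both anchors on the forward read → `full_dGGCCTGn`;
* both on the reverse-complemented read → `full_dGGCCTGr`;
* a single left(+) or right(−) hit with at least `minTractBp = 1` bases
  beyond the anchor → `5p_GGCCTGn`; single right(+) or left(−) →
  `3p_GGCCTGn`;
* anything else (including contradictory hit order, which warns) →
  `non_spanning`.

The 5'/3' convention is read-orientation based, so reverse-complementing
every read swaps `full_dGGCCTGn` ↔ `full_dGGCCTGr` and `5p` ↔ `3p`
exactly — a property the test suite asserts. The tract is extracted
between the inner anchor ends (full) or from the single inner end to the
read end (partial), always reported 5'→3' on the repeat's plus strand.

The same contract can be realized by genome-scale alignment against a
*reference pair*: the native reference (flanks around the short native
run, default 4 units) and an expanded "fake" reference with a long core
run (default 1000 units) inserted before the native run, so that
expansion-carrying reads have somewhere to align. `buildReferencePair()`
constructs the pair with its 0-based half-open repeat intervals (FASTA +
BED); the package guarantees the pair's length identity and leaves
genome-scale mapping to external aligners.

## Counting and the per-sample table

`countCoreRepeats()` counts the tokens labelled with the core motif in
the minimum-cost tokenization of the tract (below). On clean
concatenations this equals the number of core units; under random errors
it degrades gracefully, unlike exact substring counting (available as
`mode = "exact"` for comparison, it loses every unit touched by any
error). `summarizeSample()` then emits one row per sample: all spanning
subreads, the number and percentage with count strictly above 650 (the
denominator is all spanning subreads; the ratio is rounded half-up to
two decimals), the full-length subread count, and min/mean/max tract
length and repeat number over full-length tracts only, means printed as
integers. Whether partial reads should enter the pathogenic numerator is
ambiguous in the field's reporting conventions; RepeatSpan counts every
spanning read in the numerator and reports the forward/reverse full
split in detail columns, so either convention can be reconstructed.

## Motif tokenization

`tokenize()` solves a shortest-path problem over tract positions: from
position `i` a step either consumes `u ∈ [unitMin, unitMax]` bases at
the edit distance of the best catalog motif (inadmissible above
`maxUnitCost`), or falls back to a single base labelled `"other"` at
cost 1. Defaults `unitMin = 4`, `unitMax = 8` cover the observed 5–7 nt
motifs with margin; `maxUnitCost = 2` lets a token absorb up to two
errors before the fallback takes over. Among equal-cost tilings the
trace-back prefers catalog steps over fallback, then the core label,
then the longer unit, then the lexicographically smaller label — a fixed
total order, so tokenization is deterministic and stable. Adjacent
fallback bases are merged into `"other"` runs; recurring unexplained
4–8 bp segments (≥ 3 occurrences per sample) are promoted to literal
sequence labels in ratio tables, which is how motifs beyond the four
named variants surface.

`motifRatios()` reports, per label, the percentage of tract nucleotides
its tokens cover — pooled over all full-length tracts of a sample by
default (a per-tract scope is also available, since "per expansion then
averaged" and "pooled over nucleotides" are both defensible readings of
the convention; pooling weights long reads more and is the default).
Overall percentages sum to 100 within 0.01; per-length groups (5/6/7 nt)
re-normalize within the group. `rareMotifLabels()` returns labels
strictly below 1%, which waterfall schematics render black;
`renderWaterfall()` emits deterministic SVG text, one rectangle per
token, row-wrapped 5' (upper left) to 3' (lower right).

## The synthetic data generator

`generateAllele()` draws tokens i.i.d.: core with probability
`1 - interruptionFraction`, otherwise a variant by weight, with token
count `round(nCoreTarget / (1 - interruptionFraction))`.
`generateLocus()` embeds the tract between unique flanks (flanks
containing a run of ≥ 2 core motifs are rejected — they would break
anchoring). `simulateReads()` samples fragments uniformly until the
requested coverage is reached, records each fragment's truth span class
and contained core count *before* error injection, reverse-complements
the configured strand fraction, and applies per-base i.i.d. errors.

Choices worth knowing about:

* **Error model.** Total rate 0.12 by default (inside the platform's
  11–15% band), split `{sub 0.25, ins 0.45, del 0.30}` — indel-dominant,
  matching CLR character. Errors are i.i.d.; there is no homopolymer
  context, chimera or adapter modelling, and base qualities are
  constant placeholders.
* **Read lengths.** Lognormal (`meanlog = log(5000)`, `sdlog = 0.5`)
  truncated to `[500, locus length]` by default, or fixed; no platform
  length distribution is claimed.
* **Truth geometry.** A flank anchor counts as covered by a fragment iff
  the overlap is at least `anchorK - ceiling(maxEditFraction * anchorK)`
  bp — the same detectability rule the classifier applies. Without this,
  fragments clipping an anchor by a few bases would make "predicted
  class equals truth" undecidable in principle at error 0.
* **Samples.** `simulateSample()` emulates somatic heterogeneity by
  drawing every read from a fresh allele whose core count is jittered
  normally (default sd 50) around the sample mean; the default
  three-sample design uses means 600/790/870. Jitter is a simulation
  feature describing read-to-read spread, taking no position on whether
  observed spread is somatic or technical — both knobs (`jitterSd`,
  `errorRate`) are exposed. Default `interruptionFraction = 0.05` with
  uniform variant weights keeps the core motif clearly dominant, as
  observed in real expansion tracts.

Passing tests on these synthetics demonstrates the pipeline's
*contracts* (classification, counting, decomposition, determinism); it
does not certify performance on real CLR data, whose errors are
context-dependent and whose flanks are fixed by the genome.

## Numerical choices and problem sizes

All coordinates are 0-based half-open. Ratios are rounded half away from
zero (`roundHalfUp()`), matching the reporting convention of per-sample
ratio cells such as 9/76 → 11.84. Every stochastic stage takes an
explicit seed and restores the caller's RNG stream; identical
configuration and seeds give byte-identical FASTQ and tables. The test
and acceptance runs use desk-scale problem sizes chosen to exercise
every code path quickly — coverage 5–25 with three samples (tens of
reads per sample, tracts of 3.5–5.5 kb) rather than the ×100 coverage a
real sequencing design would use; the statistical properties asserted do
not depend on the larger size.

## Known limitations

* **Indel errors mimic interruption motifs.** The named variant units
  are single-indel neighbours of the core: deleting a C from GGCCTG
  yields GGCTG exactly, deleting the T yields GGCCG, and inserting C or
  T yields GGCCCTG or GGCCTTG. Under an indel-dominant error model a
  minimum-cost tokenizer therefore *must* label a fraction of
  error-struck core units as variants: analytically about 5–6% of units
  at a 5% per-base error rate, and the per-read core count is biased low
  by roughly that fraction (observed ≈ 7% in the packaged acceptance
  checks, which report it without adjustment). At error 0 recovery is
  exact. Distinguishing true interruptions from indel errors at a single
  read requires either consensus across reads or context-aware error
  models — both out of scope here; per-read counts at realistic CLR
  error rates should be read as lower bounds on the core count.
* **No diploid deconvolution.** Samples are treated as a single
  expanded-allele population; the short normal allele (3–14 units) never
  yields spanning reads of interest and is not genotyped.
* **Anchor uniqueness is assumed.** Flanks must not resemble the repeat
  (enforced for simulated loci); pathological real flanks with
  repeat-like content would need longer anchors.
* **Figure-level conventions** (waterfall row width, colour palette) are
  free parameters; no published palette is reproduced.

## A worked run

```{r, eval = FALSE}
cfg <- defaultRunConfig(seed = 1, coverage = 5)
res <- runPipeline(cfg, "run1")
res$summary
```

This simulates the three samples, builds the reference pair, classifies
and quantifies every read, decomposes full-length tracts into motifs and
writes tables, waterfall SVGs, distribution plots and an HTML index
under `run1/`. The same stages are scriptable from a shell through
`inst/scripts/repeatspan.R`.
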