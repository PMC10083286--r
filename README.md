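# RepeatSpan

Characterization of large, interrupted tandem repeat expansions from
noisy single-molecule long reads — built around the GGCCTG
hexanucleotide expansion in intron 1 of *NOP56* that causes
spinocerebellar ataxia type 36 (SCA36), but parameterized by an
arbitrary motif catalog and locus.

Pathogenic SCA36 alleles carry more than 650 repeat units (up to
several thousand), far beyond short-read or fragment-analysis reach.
CLR-class long reads cross the whole tract but carry a random 11–15%
per-base, indel-dominant error rate. RepeatSpan provides the complete
desk-scale analysis path for this situation, for geneticists and
methods developers working on repeat-expansion disorders:

* **Synthetic data** (`generateAllele`, `generateLocus`,
  `simulateReads`, `simulateSample`): ground-truthed expansion alleles
  composed of a core motif (GGCCTG) with random interruptions drawn
  from {GGCTG, GGCCCTG, GGCCG, GGCCTTG}, embedded between unique
  flanks and read at configurable coverage with per-base i.i.d.
  substitution/insertion/deletion errors. Truth (span class, core
  count) is recorded per read before error injection.
* **Reference pair** (`buildReferencePair`): the native locus (4 core
  units) and an expanded "fake" reference with (GGCCTG)×1000 inserted
  before the native run, the construct that lets expansion-spanning
  reads align; FASTA + BED output, 0-based half-open intervals.
* **Spanning-read classification** (`findAnchors`, `classifyRead`,
  `extractTract`, `classifyReads`): semi-global alignment of 30 bp
  flank anchors against each read and its reverse complement sorts
  reads into `full_dGGCCTGn`, `5p_GGCCTGn`, `3p_GGCCTGn`,
  `full_dGGCCTGr` or `non_spanning`, and extracts the repeat tract
  5'→3'.
* **Quantification** (`countCoreRepeats`, `isPathogenic`,
  `summarizeSample`): per-read core repeat counts via minimum-cost
  motif tokenization, the strict `> 650` pathogenic test, and the
  per-sample table (spanning subreads, >650 count and ratio,
  full-length count, min/mean/max length and repeat number).
* **Motif decomposition** (`tokenize`, `motifRatios`, `topMotifs`,
  `rareMotifLabels`): dynamic-programming tokenization of each tract
  into catalog motifs (edit cost ≤ 2 per unit, fallback "other",
  de-novo promotion of recurring unexplained segments), per-motif
  nucleotide percentages with 5/6/7 nt groupings.
* **Reporting** (`renderWaterfall`, `plotDistributions`,
  `runPipeline`): deterministic SVG waterfall schematics (one
  rectangle per token, 5' upper-left to 3' lower-right, <1% motifs
  blacked out), class/length/repeat distribution plots, and a
  config-driven pipeline writing every stage product plus a manifest.
  `inst/scripts/repeatspan.R` is a thin CLI over the same functions.

## The core computation

For a tract *T* and motif catalog *M* (core *c* plus variants), the
tokenizer solves

    cost(i) = min( 1 + cost(i+1),                       # "other" base
                   min_{u,m} edit(T[i..i+u), m) + cost(i+u) )

over unit sizes *u* ∈ [4, 8] and motifs *m* ∈ *M*, with per-unit cost
capped at 2; the traceback prefers core, then longer units, then
lexicographic labels at ties. The core repeat count is the number of
tokens labelled *c*; a read is pathogenic iff count > 650. The
per-sample ratio is `100 · n_{>650} / n_spanning`, rounded half-up to
two decimals. Motif ratios are `100 · (nucleotides of label) / (total
nucleotides)`, pooled over full-length tracts.

## Worked example

```r
library(RepeatSpan)
cfg <- defaultRunConfig(seed = 1, coverage = 5)   # three synthetic carriers
res <- runPipeline(cfg, "run1")
res$summary
```

```
 sample_id subread_number n_650plus ratio_650plus full_count max_length_bp
      S600              4         0             0          4          4292
      S790              5         3            60          4          5246
      S870              4         2            50          3          6128
 mean_length_bp min_length_bp max_repeats mean_repeats min_repeats
           3847          3596         539          488         448
           5049          4767         688          652         596
           5584          5052         790          722         649
```

The three samples simulate carriers with mean true core counts
600/790/870 at 12% read error (coverage 5 here, so a handful of reads
each). Reads above 650 counted units appear only in the two larger
expansions; tract lengths sit where ~6 bp × count puts them. Counted
repeat numbers at 12% error run below the true means: indel errors
convert a fraction of core units into exact variant motifs, so
per-read counts at CLR error rates are lower bounds (see the methods
vignette, "Known limitations"). The pooled motif table for this run
(`run1/motifs/pooled.ratios.tsv`) starts:

```
   label length_nt nucleotides percent group
  GGCCTG         6       41591 79.4707   all
   GGCTG         5        3504  6.6953   all
 GGCCCTG         7        2861  5.4667   all
```

with the core motif dominant and the four variants sharing the rest —
the configured 5% interruption fraction plus error-derived variants.

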