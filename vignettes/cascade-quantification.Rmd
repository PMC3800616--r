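---
title: "Quantifying exosomal small-RNA cargo with iterative cascade mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exosomal small-RNA cargo with iterative cascade mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocascade)
```

## The problem

Exosomes are 30–150 nm extracellular vesicles that carry a diverse RNA
cargo — miRNA, tRNA and rRNA fragments, mRNA, Y RNAs and other noncoding
species. Characterizing that cargo from a small-RNA sequencing library is
complicated by the fact that no single reference database covers all of
it. exocascade implements the standard "catch-all" answer: reads are
cleaned, then aligned *sequentially* against an ordered series of
reference sets, with only the reads left unmapped at each stage passed to
the next. The conventional order is

1. miRNA hairpin precursors together with tRNA and rRNA,
2. RefSeq-style transcripts (protein-coding mRNA and RefSeq ncRNA,
   distinguished by their `NM_`/`NR_` accession prefixes),
3. a remaining noncoding-RNA catalogue (piRNA, scaRNA, snoRNA and
   similar).

A read that aligns to a transcript is one *count* for that transcript.
Because a read can map at most once, at the earliest accepting stage, the
per-stage mapped read sets and the final unmapped set exactly partition
the input — the invariant every downstream summary relies on.

## Read cleanup

Semiconductor sequencers show a characteristic 3′ quality decline, and
short-insert libraries read through into the 3′ ligation adapter. Cleanup
therefore runs in a fixed order: 3′ quality trimming, a length floor, 3′
adapter trimming, and the length floor again.

* **Quality trimming** removes trailing bases below a PHRED threshold
  (default Q17, about a 2% error probability), stopping at the first base
  from the 3′ end at or above it. Internal low-quality bases are kept.
  The threshold scan runs 5′→3′ but only the 3′ tail is trimmed, which is
  how the classic FASTQ quality trimmers behave.
* **The length floor** (default 17 nt) removes reads too short to map
  unambiguously.
* **Adapter trimming** finds the best semi-global match of a *prefix* of
  the adapter against a *suffix* of the read, allowing edits up to
  `floor(max_error_rate × matched_length)` (default rate 0.1) with a
  minimum matched length of 3, and removes everything from the match
  start to the read end. The longest qualifying match wins; ties go to
  fewest edits, then the leftmost start. The matcher is a single
  O(read × adapter) dynamic program with a free start inside the read,
  anchored at the 3′ end; `N` matches nothing. The quality threshold is
  not re-checked after adapter removal.

The defaults for the error rate and minimum overlap mirror the de-facto
standard adapter trimmer, since small-RNA protocols rarely publish their
own. One documented consequence of a 3-base minimum overlap: an insert
whose own last bases happen to equal the adapter start can be trimmed
again on a second pass, so cleanup is only idempotent for overlap
settings long enough to make such coincidences negligible (the property
suite uses 10).

The 3′ adapter sequence is platform-specific and must be supplied by the
user; the simulator uses a fixed, documented 23-mer
(`ATCACCGACTGCCCATAGAGAGG`).

## The aligner

Published small-RNA pipelines typically rely on an external short-read
aligner run with unpublished "special" parameter sets. exocascade instead
ships a transparent k-mer-seeded Smith–Waterman aligner whose behavior is
fully specified and testable against an exhaustive-alignment oracle:

* **Seeding.** A read is a candidate for a transcript only if the two
  share at least one exact `seed_k`-mer (default 10). The index maps each
  k-mer to its (transcript, offset) positions. A read with clustered
  errors may share no seed and go unmapped — a documented sensitivity
  limit of seeded alignment.
* **Scoring.** Full local dynamic programming (match +2, mismatch −2,
  linear gap −4 per base) over every candidate. Reads this short (≤ ~40
  nt) essentially never need affine gap structure, and the linear model
  keeps the independent oracle simple.
* **Mapping call.** A read is mapped when its best score reaches
  `min_score_fraction` (default 0.8) of its maximum attainable score
  (`match × read_length`). The fraction is exposed as a flag; 0.8 admits
  roughly one substitution per ten bases of a full-length match.
* **Determinism.** One best hit per read ("one read, one count"). Ties
  break by fewer edits, then transcript order in the reference; the
  traceback prefers diagonal moves, and the best cell is the smallest
  reference end among equals. Identical inputs always give identical
  outputs.
* **Strand.** `forward_only` by default, because directional ligation
  protocols produce stranded reads; `both` reverse-complements the read
  and reports minus-strand SAM records (flag 16, SEQ reverse-complemented).

Alignments are written as minimal SAM v1.6 (header plus the 11 mandatory
fields with `AS:i:`/`NM:i:` tags). `POS` is 1-based per the SAM standard
while all internal coordinates are 0-based half-open; read bases outside
the local alignment are soft-clipped so the CIGAR always accounts for the
full read.

## Counting and reports

Per-stage SAM records are tallied into per-transcript count tables; a
duplicate read within a stage is an error, so table sums always equal
mapped-read counts. On top of the tables sit:

* **Percent-of-mapped normalization** — each transcript's count as a
  percentage of all mapped reads across every stage of the sample
  (sums to 100 within 1e-9).
* **Composition profiles** — the same percentages aggregated by RNA
  class.
* **Replicate means** — per-transcript arithmetic means across replicate
  libraries, absent transcripts counting 0, reported to 2 decimals (the
  conventional table presentation). The packaged HeLa tables are means of
  3 replicate cultures and the serum tables means of 2 donors; where a
  source is ambiguous about replicate structure, the packaged values
  follow the printed half/third-integer means.
* **Top-N ranking and overlap** — the N highest-mean transcripts per
  class (ties lexicographic), compared between sample types by set
  overlap. Entries are keyed by accession when present: genes listed
  under several accessions (SIRPG in the serum tables, three accessions)
  count as distinct entries, which is required to reproduce the published
  serum mRNA overlap of 7/10.
* **Differential representation** — group means ± sample standard
  deviations (n−1; 0 for a single replicate) of the normalized percents,
  and their ratio. Transcripts present in either group are reported, an
  absent replicate contributing 0. The report is descriptive; no
  significance test is attached, because count dispersion modelling is
  out of scope.

## The simulator

Every stage of the pipeline is testable without reference downloads
through a deterministic generator that emulates the relevant features of
an exosomal small-RNA library:

* random uniform-composition transcripts per RNA class, routed to their
  cascade stage (hairpin/tRNA/rRNA first, `NM_`/`NR_` accessioned
  transcripts second, other ncRNA third);
* reads drawn by class mixture, transcript, and uniform insert position,
  with inserts of 15–40 nt (the sequenced portion of cargo that is mostly
  < 200 nt);
* substitution errors at a per-base rate (default 0.005; an indel-free
  error model keeps truth labels exact);
* full 3′ adapter read-through on a configurable fraction of reads
  (default 0.8);
* qualities from a plateau/decay model — Q34 plateau, decline of 0.75
  per cycle from cycle 30, ±2 jitter, floor Q2 — so that insert bases
  stay comfortably above the Q17 trim threshold while long read-through
  tails dip below it, as on real instruments.

Defaults were chosen once to represent a realistic library of this kind
and are not tuned per test. The generator does **not** emulate real
sequence motifs or secondary structure, PCR duplication, indel errors
(unless enabled), ligation bias, or donor-to-donor variability — so
passing tests demonstrate algorithmic correctness on reads with known
truth, not performance claims on biological data. Transcripts are not
forced to be seed-disjoint across stages; `references_seed_disjoint()`
reports whether cross-stage mapping is even possible, and the truth
comparison measures it rather than preventing it.

All randomness derives from the single config seed (the reference uses
`seed`, reads `seed + 1`), making every FASTA/FASTQ/truth-table output
byte-reproducible.

## Numerical and design choices

* PHRED offset fixed at +33 (Sanger scale), overridable.
* Quartiles in the QC report use linear interpolation (`quantile()`
  type 7); k-mer ties rank alphabetically; the QC k defaults to 8.
* Degenerate inputs: empty FASTQ yields empty outputs rather than
  errors; zero mapped reads make normalization an explicit error rather
  than silently producing NaN; an empty stage reference is a
  configuration error.
* Count-table schema is four TSV columns
  (`transcript_id`, `accession`, `rna_class`, `count`) with a header —
  a concrete choice where "tabular format" is all that convention
  dictates.

## Problem sizes

The test suite and the acceptance script measure the pipeline at sizes a
laptop handles in seconds: rank overlaps on the packaged 10-row tables,
alignment-oracle batteries of 120–500 read/transcript pairs,
preprocessing batches of 600–1000 reads, truth recovery on 3,000
error-free read-through reads, and a 10,000-read cascade partition
check. These sizes were chosen to make every property measurable with
tight determinism while keeping a full run fast.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, read_count = 2000)
ref <- generate_reference(cfg)
sim <- generate_reads(cfg, ref)

pre <- preprocess_stream(sim$reads,
                         preprocess_params(adapter_seq = cfg$adapter_seq))
casc <- run_cascade(pre$kept, cascade_config(ref$stages))

composition_profile(casc)
normalize_percent(casc) |> head()

fx <- packaged_fixtures()
topn_overlap(top_n(fx$hela$cells$tRNA, "tRNA", 10),
             top_n(fx$hela$exosomes$tRNA, "tRNA", 10))  # 7
```

## Known limitations

* Seeded alignment misses reads whose errors leave no exact 10-mer.
* The adapter matcher reports, per matched length, the minimal-edit
  leftmost match; exotic ties between equally long, equally edited
  matches resolve deterministically but are not enumerated.
* Multi-mapping reads are assigned a single best transcript; true
  multi-mapping ambiguity (e.g. tRNA isodecoders) is resolved by tie
  rules, not reported.
* The differential report is descriptive only.
* BAM/CRAM, paired-end data, spliced alignment and quality recalibration
  are out of scope.
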