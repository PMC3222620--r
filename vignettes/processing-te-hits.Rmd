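---
title: "Processing transposable-element hits: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing transposable-element hits: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tehits)
```

## The problem

A repeat library searched against a genome with BLAST or RepeatMasker
yields a hit report: thousands of matches per element family, each a pair
of coordinates on a database sequence plus quality measures. Downstream
work — building consensus sequences, recovering full-length elements,
studying insertion flanks — needs the *sequences* of those loci, usually
with flanking context, grouped per family, and restricted to matches of
adequate quality. `tehits` is that post-processing layer.

## The hit model

All three input dialects normalize to one row per match with:

* `location`, `seq_start`, `seq_end` — 1-based inclusive coordinates on
  the database sequence, always with `seq_start <= seq_end`. Orientation
  never lives in coordinate order: BLAST encodes a minus-strand subject
  match as `s.start > s.end`, and the parser swaps the pair and records
  `strand = "-"` instead.
* `seq_length = seq_end - seq_start + 1`. We use the inclusive length,
  consistent with BLAST's alignment-length semantics on 1-based inclusive
  coordinates; an exclusive difference (`end - start`) would undercount a
  single-base hit as zero.
* `group_label` — the BLAST query id, the RepeatMasker
  `element#class/family` pair, or the e-PCR marker id.
* quality fields (`mismatches`, `gaps`, `e_value`, `bit_score`) where the
  dialect reports them, `NA` elsewhere. Requesting a threshold on a field
  the dialect lacks is a configuration error rather than a silent pass:
  silently passing would make a `-bit 100` RepeatMasker run look stricter
  than it is.
* `hit_id` — `label_location_start_end`, with a numeric suffix when the
  same tuple recurs, so identifiers stay unique across a whole run even
  for duplicate loci in multi-file input.

e-PCR tabular output has no single canonical column set, so the package
fixes a five-column dialect (sequence id, marker id, strand, start, end)
and documents it; mismatch/gap counts are treated as absent for it.

## Pipeline order and why it matters

Stages run in a fixed order: parse → merge → filter → best-N → split →
table output → extract. Two orderings are load-bearing:

* **Filters run after merging**, so `min_length` applies to merged spans.
  This is what makes the fragment-reassembly workflow function: an old
  LINE insertion broken by indels into 300-base fragments fails a
  500-base filter individually but passes once `-overlap` merges the
  cluster.
* **Buffering happens at extraction, after merging**, and buffered
  extracts are never re-merged: each surviving locus yields exactly one
  output record even when neighbouring buffered windows overlap.

### Merging

Two hits merge when the intervening gap `next_start − prev_end − 1` is at
most the merge distance; distance 0 still merges overlapping and directly
adjacent hits. Buckets require the same location *and* group label *and*
strand by default. Merging across families or strands would destroy the
subsequent split and the orientation of extracted sequences, so the
conservative bucketing is the default; both `require_same_*` flags can be
relaxed for a literal coordinates-only merge. Merged quality fields are
aggregated so that filters stay meaningful afterwards: mismatch and gap
counts sum (a merged locus carries all its members' errors), bit score
takes the maximum and E-value the minimum (the locus is at least as good
as its best fragment).

### Best-N and ties

Best-N keeps the `n` smallest E-values per group, breaking ties by larger
bit score and then input order. The tie-break makes the selection fully
deterministic, which the reproducibility checks rely on.

## Extraction

The FASTA database is indexed (htslib faidx via `Rsamtools`), so random
access holds at most one sequence region in memory regardless of database
size. Flank buffering clamps at the sequence ends —
`[max(1, start − b), min(L, end + b)]` — extending "where data is
available" and never beyond.

Minus-strand extracts are reverse-complemented by default so that every
output sequence reads in query/element orientation. The package makes
this the default because the downstream use cases — prepending the query
consensus with `-qseq` and aligning hits against it — are only meaningful
when all sequences share the element's orientation. Flank-analysis
workflows that need genomic orientation set `revcomp_minus = FALSE`
(`-norc` on the command line).

Output FASTA headers are
`>{hit_id} {location}:{extract_start}-{extract_end}({strand})` with
60-column wrapping; fixing the format exactly makes byte-level round-trip
tests possible. Hit tables are re-serialized in the input dialect's own
layout (minus-strand BLAST coordinates re-inverted, `C` for RepeatMasker
complement) so the printed table re-parses to the same hit set; fields
that are not part of the hit model (BLAST query coordinates, RepeatMasker
Smith–Waterman scores) are reconstructed neutrally (q.start 1, q.end =
alignment length, identity from the stored mismatch count, SW score 0).
Merged hits serialize with their aggregated scores plus a `#` comment
line carrying the merge count, which dialect parsers skip.

## The synthetic fixture generator

`generate_fixture()` is the package's test bed: random background
scaffolds with element copies planted at recorded, non-overlapping
positions on random strands, each copy mutated by substitution at a fixed
per-base rate, plus hit files in both dialects describing the planted
loci and a truth table carrying every mutated copy. The defaults — 5
scaffolds × 10 kb, 20 insertions, 5% divergence, and a four-element
library spanning LINE (1200 nt), DNA (800 nt), SINE (300 nt) and a short
80-nt element — are sized so that a desk-scale run exercises every code
path: multiple scaffolds and strands, all split groups populated, and at
least one element that genuinely fails a `-minlength 100` filter. The
synthetic bit score `2(len − 2·mut)` and E-value `10^(−bit/10)` make
divergence move both quality axes, so score filters reject real records
rather than nothing.

With `fragments = k` each insertion is reported as `k` hit fragments
separated by gaps of at most `fragment_max_gap` bases, emulating
indel-broken annotations; planted copies are spaced at least 300 bases
apart so a 100-base merge distance can never join distinct insertions.

What the generator deliberately does **not** emulate: indels within
copies (substitution-only mutation keeps the mismatch bookkeeping exact),
nested insertions, 5′ truncation distributions, or compositional bias in
the background. Passing tests therefore demonstrate coordinate, strand,
merge and serialization correctness — not robustness to alignment
ambiguity in highly decayed real repeats, where the upstream search tool,
not this package, determines hit boundaries.

## Numerical and degenerate-input choices

* Coordinates are integers throughout; the merge sweep computes gaps in
  double precision to avoid integer overflow on its sentinel initial
  value.
* E-values are serialized with `%.6g` and identities with two decimals;
  a parse → write → parse cycle is a fixpoint on the hit tuple, and a
  second cycle is byte-stable.
* Empty inputs flow through: an empty hit file parses (with a warning) to
  an empty table, every stage maps empty to empty, and writing zero
  records creates an empty FASTA rather than failing.
* Hits on sequences missing from the database are skipped per-hit with a
  warning naming them; the run continues — one bad scaffold name should
  not discard an overnight search.
* Malformed hit lines abort with the line number by default;
  `-skipbad` downgrades them to counted warnings.
* `sample_records()` draws through an isolated seeded generator
  (`withr::with_seed`), so sampling never perturbs the caller's RNG
  state, and preserves the input's relative order.

## Open design points, resolved

* Whether the original-length semantics were inclusive or exclusive is
  ambiguous ("the distance between the two values"); inclusive was
  chosen and documented above.
* Whether minus-strand extracts should be reverse-complemented: both
  behaviours are provided; element orientation is the default for the
  reasons given.
* Whether hit splitting by file should go per query or per fixed chunk:
  `split_hitfile()` provides both.
* The external aligner hook (`-align`) only shells out to a configurable
  command template per output FASTA; a missing program downgrades to a
  warning and leaves all other outputs intact. It is excluded from the
  test surface, as re-running an aligner verifies the aligner, not this
  package.

## Problem sizes used in the checks

The bundled test and acceptance runs use fixtures of 4–5 scaffolds of
8–10 kb with 8–20 planted copies, 100–200 random interval sets of up to
50 intervals for the merge oracle, and 40–50 random files per dialect for
round-trip checks — sizes at which the brute-force oracles (pairwise
union-to-fixpoint merging, per-base coverage sets, raw-text FASTA
slicing) remain exact and fast while still covering every branch of the
pipeline.
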