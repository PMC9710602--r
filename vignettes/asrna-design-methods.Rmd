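---
title: "Designing genome-wide antisense RNA libraries: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genome-wide antisense RNA libraries: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrnadesign)
```

## The problem

Antisense RNAs (asRNAs) knock down bacterial gene expression by
base-pairing with a target mRNA around its translation-initiation region,
blocking ribosome loading and/or promoting degradation. Carried on an
inducible small-RNA (sRNA) scaffold, a designed asRNA gives a reversible,
portable knockdown — usable even for essential genes, where knockouts are
impossible. A *systematic* library needs one asRNA per annotated coding
sequence, and each candidate must be vetted against the whole genome for
off-target binding sites, because a 21-mer can easily match a recently
duplicated gene or a conserved domain elsewhere.

`asrnadesign` automates this: parse the annotation, design a perfect
reverse-complement asRNA per CDS, screen it genome-wide, redesign flagged
genes once at a new offset, and report everything with evidence.

## The design rule

Let mRNA coordinate 0 be the first base of the start codon, negative
values upstream. A design is the reverse complement of the window
covering mRNA positions $[\,o,\; o + \ell\,)$, where $\ell$ is the asRNA
length (default 21 nt) and $o$ the offset (default $-8$). Mapping to
genomic coordinates (0-based, half-open) is

* plus strand: $[\,\mathrm{start} + o,\; \mathrm{start} + o + \ell\,)$,
* minus strand: $[\,\mathrm{end} - o - \ell,\; \mathrm{end} - o\,)$,

with wrap-around modulo the contig length on circular replicons. The
default window $[-8, 13)$ spans the tail of the Shine–Dalgarno (SD)
motif, the start codon and the first codons — the region where antisense
occlusion most reliably blocks initiation. Both defaults are tunable; a
sufficiently positive offset places the window entirely inside the CDS
for users who want to leave the SD sequence free. The offset convention
(window *5'-most base* at $o$) is the simplest one that makes these
semantics exact; it is stated here prominently because other anchors
(window centre, window 3' end) are equally conceivable and would shift
every coordinate in the output.

Degenerate cases are errors with machine-readable reasons, never silent
adjustments: a window crossing a linear contig boundary, or a positive
offset pushing the window past the CDS 3' end, marks the gene
`undesignable` at that offset. Clamping would silently violate the
length contract of the library.

## The two-round workflow

Round 1 designs every selected gene at the configured offset and screens
it. A gene with at least one off-target hit is redesigned exactly once,
at offset $o + s$ where the step $s$ defaults to $\ell$ — the nearest
window that is completely disjoint from the duplicated round-1 window
while staying in the initiation region — and screened again. There is
deliberately **no third round**: with recent gene duplicates of high
identity, iterating would walk the window ever further downstream
without converging, eventually leaving the biologically useful region
altogether. Genes still flagged after round 2 ship their round-2 design
*with* the hit evidence, so the user decides; dropping them would hide
exactly the genes a screen designer most needs to know about. If the
round-2 window cannot be constructed (e.g. a very short gene near a
contig edge), the round-1 design is kept and the failure is recorded.

## The off-target screen

The binding footprint of an asRNA is the mRNA-sense window sequence; a
genomic locus matching that footprint (on either strand) above the
thresholds is a potential binding site. The built-in matcher and the
exhaustive reference scanner share one alignment contract:

> On each alignment diagonal (a placement of the footprint against one
> genomic strand), the reported alignment is the maximal-scoring ungapped
> segment under match $+1$ / mismatch $-2$, ties broken towards the
> longer and then the leftmost segment. It is reported iff its length is
> at least `min_match_length` (default 15 nt) and its identity at least
> `min_identity` (default 80%). One record is kept per (subject
> interval, strand).

`find_matches()` implements this with BLAST-style seeding: exact
`seed_word_size`-mers (default 11 nt) shared between footprint and
genome nominate diagonals, which are then extended and trimmed.
`brute_force_scan()` implements it by enumerating every sub-window of
every diagonal — $O(nL^2)$, feasible only for test-sized genomes, and
deliberately sharing no code path with the seeded matcher beyond the
scoring constants. Gaps are not modelled: in a 21-nt duplex a bulge is
thermodynamically marginal, and an ungapped model keeps the statistics
transparent. The built-in matcher reports no e-value (that would require
Karlin–Altschul calibration the ungapped short-query setting does not
warrant); the optional BLAST+ backend (`run_external_blast()`, or
`--backend blast` on the command line) reports the e-values `blastn
-task blastn-short` assigns and honours an e-value cutoff.

### Sensitivity of seeded search, and what the oracle tests show

A seeded matcher is complete only when every alignment passing the
thresholds must contain an exact seed. By pigeonhole, an alignment of
length $L_a$ with $m$ mismatches contains a mismatch-free run of at
least $\lceil (L_a - m)/(m+1) \rceil$ nt. At 100% identity every
qualifying alignment contains a full-length exact run, so an 11-mer seed
is provably complete; at 95%/15 nt a 7-mer seed is; at 90%/16 nt a
6-mer is. At the default 80%/15 nt, however, a qualifying alignment may
contain no run longer than 3 nt — such spread-mismatch near-matches are
invisible to *any* practical seed, here exactly as in BLAST itself. On
random fixture genomes they do occur (roughly one per few tens of
kilobases screened). Consequently the equivalence tests assert **exact
hit-set equality between the seeded matcher and the exhaustive scan in
the provably complete regimes**, and separately assert at the default
thresholds that (i) every seeded hit also appears in the exhaustive
scan's output with identical coordinates and identity (soundness) and
(ii) planted duplicates and the intended site are always found
(completeness at exact repeats, which always contain seeds). Users who
need guaranteed exhaustive sensitivity below ~90% identity should treat
the built-in screen as a high-confidence filter, not a proof of absence.

A hit is classified *intended* when it overlaps the design's own window
by at least 1 bp on the orientation of the intended duplex — any such
placement is the same binding locus, not an independent off-target.
Hits are counted wherever they fall, inside genes or not (a match in an
intergenic region may still titrate the asRNA); as context, each hit is
annotated with the CDS it overlaps, if any.

## Parameters at a glance

| parameter | default | unit | meaning |
|---|---|---|---|
| `asrna_length` | 21 | nt | asRNA / window length (min 10) |
| `offset` | −8 | nt | window 5' base relative to the start codon |
| `redesign_step` | `asrna_length` | nt | round-2 offset increment |
| rounds | 2 | — | fixed cap, not tunable |
| `min_identity` | 80 | % | minimum identity of a reported hit |
| `min_match_length` | 15 | nt | minimum length of a reported hit |
| `seed_word_size` | 11 | nt | exact-seed length of the built-in matcher |
| `evalue_threshold` | 1000 | — | external backend only; generous for short queries |

The screen thresholds are deliberately permissive defaults — they err
towards reporting marginal sites — and are plainly user-adjustable;
off-target counts are monotone in both (loosening a threshold can only
add hits), which the suite verifies.

## The synthetic genome generator

`make_genome()` builds deterministic fixtures: `n_genes` equal-length
CDSs (default 6 × 120 nt, ≥ three windows long so a round-2 window
always fits) separated by ≥ 30 nt intergenic spacers (room for upstream
windows and duplicate flanks), each gene `ATG` + i.i.d. random bases at
a set GC content, strands drawn at a set minus-strand fraction. Random
sequence is rejection-sampled until no 15-mer (canonicalised across
strands) occurs twice, so duplicate-free fixtures screen clean by
construction rather than with high probability. Planted duplicates are
then copied byte-identically in mRNA space into extra annotated loci:
an `sd_start_region` duplicate copies positions $[-20, 15)$ — upstream
flank, SD region, start codon and first codons, i.e. the whole round-1
window but not the round-2 one, so the workflow rescues such genes in
round 2; a `whole_gene_with_flanks` duplicate copies the gene ± 30 nt,
so both rounds stay duplicated and the gene ends `flagged`. These spans
are the two qualitative duplication regimes the workflow distinguishes;
the copied remainder of a duplicate locus is fresh random sequence.

What the fixtures *do not* emulate: real codon usage, operon structure,
promoters, rRNA/tRNA repeats, insertion sequences, or the genome-scale
repeat families of real bacteria. Passing tests therefore demonstrate
the correctness of the coordinate arithmetic, the matcher and the
workflow logic — not that any particular real genome yields a given
clean/flagged ratio. On real annotation, expect far more flagged genes
(paralog families, IS elements) than the fixtures show.

## Numerical and I/O choices

* Coordinates are 0-based half-open internally; GenBank/EMBL 1-based
  inclusive at the parsing boundary and again in the CSV output
  (`window_start_1based = start + 1`). The conversion is bijective and
  round-trip-tested.
* Alignment ties (equal score) resolve to the longer, then leftmost
  segment — both backends implement the identical total order, so hit
  sets compare exactly.
* `N` bases match nothing: they can neither seed nor count as identity.
* Compound (`join`) CDS locations have no well-defined start-codon
  anchor; they are skipped with a warning rather than guessed at.
* Hits wrapping a circular origin keep `subject_end > contig length`
  rather than being split, preserving the one-row-per-site invariant.
* CSV output is RFC-4180, UTF-8, with a fixed column order; with the
  timestamp row suppressed, identical inputs give byte-identical files.
  Spreadsheet export is not implemented; CSV loads directly into any
  spreadsheet program.

## Problem sizes used in the test suite

The suite exercises genomes of ~1–2 kb with 6–50 genes (the matcher
equivalence sweep uses 20 genomes with planted duplicates on both
topologies, four parameter combinations each), which keeps the full
suite under a minute while covering every code path; the exhaustive
scanner, not genome size, is the binding cost. The algorithms are
O(genome) per gene with the seeded matcher and have no fixture-specific
constants, so behaviour at megabase scale differs only in runtime.

## Known limitations

* No thermodynamic or secondary-structure scoring: a perfect-complement
  window can still be a poor binder if the target site is structured.
  Hybridisation prediction is outside this package's scope.
* The screen is genomic, not transcriptomic: matches in never-expressed
  regions count as off-targets (conservative), and antisense-strand
  transcription is not modelled.
* One contig per run; multi-replicon genomes are processed per record.
* The built-in matcher's sensitivity floor below ~90% identity is
  inherent to seeding (see above).
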