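# asrnadesign

Genome-wide design of bacterial antisense RNAs (asRNAs) with off-target
screening.

## What it does, and for whom

Antisense RNAs knock down bacterial gene expression by base-pairing with
a target mRNA around its translation-initiation region. Grafted onto an
inducible sRNA scaffold, they give reversible, portable knockdowns —
including of essential genes — and a *systematic* library (one designed
asRNA per gene, instead of a randomised pool) makes genome-scale screens
efficient and interpretable. This package is for microbiologists and
functional-genomics groups building such libraries.

For every annotated coding sequence of a GenBank/EMBL genome (or a
chosen subset), `asrnadesign`:

1. designs an asRNA of length *ℓ* (default **21 nt**) as the **perfect
   reverse complement** of the mRNA window `[o, o + ℓ)`, where mRNA
   position 0 is the first base of the start codon and the default
   offset **o = −8** makes the window span the Shine–Dalgarno tail, the
   start codon and the first codons;
2. screens the binding footprint against the whole genome, both strands:
   reported hits are maximal-scoring ungapped alignments (match +1 /
   mismatch −2) of length ≥ 15 nt at ≥ 80 % identity (all adjustable),
   found by an 11-mer seed-and-extend matcher (an external BLAST+
   backend is optional);
3. redesigns any gene with an off-target hit **exactly once**, one
   window downstream (offset `o + ℓ`, i.e. +13 by default), and screens
   again — never a third round, which with recent gene duplicates would
   only walk the window out of the initiation region;
4. writes the final library and *all* screening evidence as CSV.

A deterministic synthetic-genome generator (`make_genome()`) with
plantable gene duplicates makes the whole workflow testable without any
genome download.

## Worked example

A six-gene synthetic genome in which gene 1's Shine–Dalgarno/start
region has been duplicated into a seventh locus:

```r
library(asrnadesign)

g <- make_genome(synthetic_genome_spec(
  seed = 11,
  duplicate_pairs = list(duplicate_pair(1, "sd_start_region"))),
  path = "demo.gb")                      # also writes a GenBank file

res <- design_library(g, input_name = "demo.gb")
res
#> <design_report> SYNGENOME: 7 gene(s) designed
#>   clean_round1  5
#>   clean_round2  2
#>   flagged       0
#>   undesignable  0
#>   off-target hit rows: 2

head(res$outcomes[, c("locus_tag", "status", "round", "offset", "asrna_seq")], 4)
#>   locus_tag       status round offset             asrna_seq
#> 1  SYN_0001 clean_round2     2     13 CATGACTAGCAACCCGTACCG
#> 2  SYN_0002 clean_round1     1     -8 TTGTTCGTAGCATAAAGGTGT
#> 3  SYN_0003 clean_round1     1     -8 TACTTTAATACATACACAGAT
#> 4  SYN_0004 clean_round1     1     -8 AAGAGGTAGCCATTGGTTGCG

write_report(res, "demo", timestamp = FALSE)
# -> demo_designs.csv, demo_hits.csv, demo_run_info.csv
```

Reading the output: the duplicated pair (`SYN_0001` and its copy
`SYN_0007`) each picked up one off-target hit at the other's locus in
round 1 — those are the two off-target rows — so both were redesigned at
offset +13, where the duplication no longer covers the window, and both
screen clean (`clean_round2`). The five undisturbed genes keep their
round-1 design at offset −8. Every `asrna_seq` is 21 nt and is the
reverse complement of its `target_sense_seq` column; window coordinates
in the CSV are 1-based inclusive, matching the GenBank convention.

The same run from a shell:

```sh
exec/asrna-design --genome demo.gb --out demo --no-timestamp
```

Genes that remain `flagged` after round 2 (e.g. whole-gene duplicates)
are still delivered, with their hit tables — the evidence is the point.

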