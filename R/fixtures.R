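#' Specification for a synthetic annotated genome
#'
#' Describes a deterministic random genome used for testing and
#' demonstration: `n_genes` coding sequences of equal length separated by
#' intergenic spacers, each gene starting with ATG, strands drawn at
#' `fraction_minus_strand`, plus optional planted duplicates that force
#' off-target hits. Duplicate loci are appended as extra annotated genes:
#' a `"sd_start_region"` duplicate shares the source gene's sequence over
#' mRNA positions [-20, +15) (upstream flank, Shine-Dalgarno region,
#' start codon and first codons — covering the default round-1 design
#' window but not the round-2 one); a `"whole_gene_with_flanks"`
#' duplicate shares the entire gene plus 30 nt flanks (so both design
#' rounds stay duplicated).
#'
#' @param n_genes Number of non-duplicate genes (>= 1; default 6).
#' @param gene_length CDS length in nt (>= 63, i.e. three default
#'   windows; default 120).
#' @param intergenic_length Spacer length in nt (>= 30; default 60).
#' @param fraction_minus_strand Probability a gene lands on the minus
#'   strand (default 0.25).
#' @param duplicate_pairs List of [duplicate_pair()] entries.
#' @param topology `"linear"` or `"circular"`.
#' @param gc_content GC proportion of random sequence (default 0.5).
#' @param seed Integer seed; the same spec always yields byte-identical
#'   output.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_genes = 6L, gene_length = 120L,
                                  intergenic_length = 60L,
                                  fraction_minus_strand = 0.25,
                                  duplicate_pairs = list(),
                                  topology = c("linear", "circular"),
                                  gc_content = 0.5, seed = 1L) {
  topology <- match.arg(topology)
  n_genes <- as.integer(n_genes)
  gene_length <- as.integer(gene_length)
  intergenic_length <- as.integer(intergenic_length)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (gene_length < 63L) {
    stop("gene_length must be >= 63 nt so that redesign windows fit")
  }
  if (intergenic_length < 30L) {
    stop("intergenic_length must be >= 30 nt to leave room for upstream windows")
  }
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)")
  for (dp in duplicate_pairs) {
    if (!inherits(dp, "duplicate_pair")) {
      stop("duplicate_pairs must be a list of duplicate_pair() entries")
    }
    if (dp$source < 1L || dp$source > n_genes) {
      stop("duplicate_pair source index out of range: ", dp$source)
    }
  }
  structure(list(n_genes = n_genes, gene_length = gene_length,
                 intergenic_length = intergenic_length,
                 fraction_minus_strand = fraction_minus_strand,
                 duplicate_pairs = duplicate_pairs, topology = topology,
                 gc_content = gc_content, seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

#' @rdname synthetic_genome_spec
#' @param source Index (1-based) of the gene to duplicate.
#' @param span `"sd_start_region"` or `"whole_gene_with_flanks"`.
#' @export
duplicate_pair <- function(source,
                           span = c("sd_start_region",
                                    "whole_gene_with_flanks")) {
  span <- match.arg(span)
  structure(list(source = as.integer(source), span = span),
            class = "duplicate_pair")
}

# mRNA-space span copied for each duplicate kind, relative to the start
# codon (0 = first base of ATG).
duplicate_span_range <- function(span, gene_length) {
  switch(span,
         sd_start_region = c(-20L, 15L),
         whole_gene_with_flanks = c(-30L, gene_length + 30L))
}

#' Generate a synthetic annotated genome
#'
#' Builds the genome described by a [synthetic_genome_spec()]. Random
#' sequence is rejection-sampled until no 15-mer (canonicalised across
#' both strands) occurs twice, so that planted duplicates are the only
#' long exact repeats and screens of duplicate-free fixtures are
#' deterministically clean. Duplicate regions are then copied byte-
#' identically in mRNA (sense) space from their source gene; duplicate
#' loci sit on the plus strand. The caller's random number generator
#' state is left untouched.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param path Optional path; when given, the genome is also written as a
#'   GenBank flat file via [write_genbank()].
#' @return A [new_genome()] object.
#' @export
make_genome <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  g <- withr::with_seed(spec$seed, build_synthetic_genome(spec))
  if (!is.null(path)) write_genbank(g, path)
  g
}

build_synthetic_genome <- function(spec) {
  m <- spec$n_genes + length(spec$duplicate_pairs)
  for (attempt in seq_len(100L)) {
    parts <- character(0)
    starts <- integer(m)
    strands <- integer(m)
    pos <- 0L
    for (i in seq_len(m)) {
      spacer <- random_dna(spec$intergenic_length, spec$gc_content)
      gene <- paste0("ATG", random_dna(spec$gene_length - 3L, spec$gc_content))
      is_dup_locus <- i > spec$n_genes
      strands[i] <- if (!is_dup_locus && runif(1) < spec$fraction_minus_strand)
        -1L else 1L
      placed <- if (strands[i] == -1L) reverse_complement(gene) else gene
      parts <- c(parts, spacer, placed)
      starts[i] <- pos + spec$intergenic_length
      pos <- pos + spec$intergenic_length + spec$gene_length
    }
    parts <- c(parts, random_dna(spec$intergenic_length, spec$gc_content))
    sequence <- paste(parts, collapse = "")
    if (repeat_free(sequence, 15L)) break
    if (attempt == 100L) {
      stop("could not generate a repeat-free genome in 100 attempts; ",
           "reduce genome size or gc bias")
    }
  }
  features <- data.frame(
    locus_tag = sprintf("SYN_%04d", seq_len(m)),
    gene_name = sprintf("syg%04d", seq_len(m)),
    product = "hypothetical protein",
    start = starts,
    end = starts + spec$gene_length,
    strand = strands,
    kind = "CDS",
    stringsAsFactors = FALSE)
  g <- new_genome("SYNGENOME", sequence, spec$topology, features)
  for (j in seq_along(spec$duplicate_pairs)) {
    dp <- spec$duplicate_pairs[[j]]
    rng <- duplicate_span_range(dp$span, spec$gene_length)
    src <- g$features[dp$source, ]
    win <- compute_window(src, rng[1], rng[2] - rng[1], g)
    sense <- extract_target_sense(g, win)
    dst <- g$features[spec$n_genes + j, ]           # plus strand by design
    a <- dst$start + rng[1]
    substr(g$sequence, a + 1L, a + nchar(sense)) <- sense
  }
  g
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# TRUE iff no w-mer, canonicalised across strands, occurs twice.
repeat_free <- function(sequence, w) {
  n <- nchar(sequence)
  if (n < w) return(TRUE)
  fw <- substring(sequence, 1:(n - w + 1L), w:n)
  rcseq <- reverse_complement(sequence)
  rc <- substring(rcseq, (n - w + 1L):1L, n:w)   # rc[i] = revcomp of fw[i]
  canon <- ifelse(fw <= rc, fw, rc)
  anyDuplicated(canon) == 0L
}
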