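# Fixture builders and comparison helpers shared across the suite.

clean_fixture <- function(seed = 7, n_genes = 6, ...) {
  make_genome(synthetic_genome_spec(n_genes = n_genes, seed = seed, ...))
}

dup_fixture <- function(seed = 11, span = "whole_gene_with_flanks",
                        source = 1, n_genes = 6, ...) {
  make_genome(synthetic_genome_spec(
    n_genes = n_genes, seed = seed,
    duplicate_pairs = list(duplicate_pair(source, span)), ...))
}

# Hit table reduced to its alignment identity, sorted, for set comparison.
norm_hits <- function(h) {
  h <- h[, c("subject_start", "subject_end", "subject_strand",
             "aligned_length", "identity")]
  h <- h[do.call(order, h), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Mirror image of a genome: reverse-complement the sequence and remap all
# feature coordinates/strands. Designs must be invariant under this.
flip_genome <- function(g) {
  n <- nchar(g$sequence)
  f <- g$features
  new_start <- n - f$end
  f$end <- n - f$start
  f$start <- new_start
  f$strand <- -f$strand
  f <- f[order(f$start), ]
  new_genome(g$id, reverse_complement(g$sequence), g$topology, f)
}

# Screen-parameter combinations for which an exact seed is guaranteed to
# lie inside every alignment passing the thresholds (pigeonhole on the
# longest mismatch-free run), so seeded search provably finds everything
# the exhaustive scan finds.
guaranteed_param_grid <- function() {
  list(screen_params(min_identity = 100, min_match_length = 15,
                     seed_word_size = 11),
       screen_params(min_identity = 100, min_match_length = 21,
                     seed_word_size = 11),
       screen_params(min_identity = 95, min_match_length = 15,
                     seed_word_size = 7),
       screen_params(min_identity = 90, min_match_length = 16,
                     seed_word_size = 6))
}

# Minimal single-gene GenBank record used by the parser unit tests.
minimal_genbank <- function(location = "101..400") {
  seq_len_total <- 450L
  set.seed(42)
  s <- paste(sample(c("a", "c", "g", "t"), seq_len_total, replace = TRUE),
             collapse = "")
  c(sprintf("LOCUS       TESTREC %d bp    DNA     linear   BCT 01-JAN-1980",
            seq_len_total),
    "DEFINITION  parser unit fixture.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", seq_len_total),
    sprintf("     CDS             %s", location),
    "                     /locus_tag=\"TST_0001\"",
    "                     /gene=\"tstA\"",
    "                     /product=\"test protein\"",
    "ORIGIN",
    sprintf("%9d %s", 1, substr(s, 1, 60)),
    sprintf("%9d %s", 61, substr(s, 61, 120)),
    sprintf("%9d %s", 121, substr(s, 121, seq_len_total)),
    "//")
}
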