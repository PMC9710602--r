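test_that("a unique design yields exactly its intended site at full identity", {
  g <- clean_fixture(seed = 21)
  for (i in c(1, 4)) {
    d <- design_asrna(g, g$features[i, ])
    hits <- find_matches(d, g, screen_params())
    expect_equal(nrow(hits), 1L)
    expect_true(hits$is_intended)
    expect_equal(hits$identity, 100)
    expect_equal(hits$aligned_length, 21L)
    expect_equal(hits$subject_start, d$window$genomic_start)
    expect_equal(hits$overlapping_feature, d$locus_tag)
    expect_identical(norm_hits(hits),
                     norm_hits(brute_force_scan(d$target_sense_seq, g,
                                                screen_params())))
  }
})

test_that("a byte-identical gene duplicate is reported as one off-target", {
  g <- dup_fixture(seed = 13, span = "whole_gene_with_flanks")
  d <- design_asrna(g, g$features[1, ])
  hits <- find_matches(d, g, screen_params())
  expect_equal(nrow(hits), 2L)
  expect_equal(sum(hits$is_intended), 1L)
  off <- hits[!hits$is_intended, ]
  expect_equal(off$identity, 100)
  expect_equal(off$overlapping_feature, "SYN_0007")
  expect_identical(norm_hits(hits),
                   norm_hits(brute_force_scan(d$target_sense_seq, g,
                                              screen_params())))
})

test_that("an all-N footprint produces no hits", {
  g <- clean_fixture(seed = 2)
  d <- design_asrna(g, g$features[1, ])
  d$target_sense_seq <- strrep("N", 21)
  d$asrna_seq <- strrep("N", 21)
  expect_equal(nrow(find_matches(d, g, screen_params())), 0L)
  expect_equal(nrow(brute_force_scan(strrep("N", 21), g, screen_params())), 0L)
})

test_that("the exhaustive scan finds a planted 21-mer and its reverse complement", {
  withr::with_seed(99, {
    backbone <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                      collapse = "")
  })
  probe <- "ATGAAACCCGGGTTTACGTAC"
  seqn <- paste0(substr(backbone, 1, 2000), probe, substr(backbone, 2001, 5000))
  g <- new_genome("P", seqn, "linear")
  hits <- brute_force_scan(probe, g, screen_params(min_identity = 100,
                                                   min_match_length = 21))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$subject_start, 2000L)
  expect_equal(hits$subject_strand, 1L)

  rc_hits <- brute_force_scan(reverse_complement(probe), g,
                              screen_params(min_identity = 100,
                                            min_match_length = 21))
  expect_equal(rc_hits$subject_start, 2000L)
  expect_equal(rc_hits$subject_strand, -1L)

  # at 100%/full-length the scan is exactly naive substring search
  naive <- as.integer(gregexpr(probe, seqn, fixed = TRUE)[[1]]) - 1L
  expect_equal(hits$subject_start, naive)
})

test_that("builtin and exhaustive matcher agree exactly when seeding is guaranteed", {
  for (s in 1:8) {
    g <- make_genome(synthetic_genome_spec(
      n_genes = 6, seed = 300 + s,
      topology = if (s %% 2) "linear" else "circular",
      duplicate_pairs = list(duplicate_pair(1, "whole_gene_with_flanks"),
                             duplicate_pair(2, "sd_start_region"))))
    for (i in 1:2) {
      d <- design_asrna(g, g$features[i, ])
      for (sp in guaranteed_param_grid()) {
        expect_identical(norm_hits(find_matches(d, g, sp)),
                         norm_hits(brute_force_scan(d$target_sense_seq, g, sp)))
      }
    }
  }
})

test_that("every builtin hit is sound and also found by the exhaustive scan", {
  sp <- screen_params()          # permissive defaults: 80% / 15 nt
  for (s in c(8, 12)) {          # genomes with background near-matches
    g <- make_genome(synthetic_genome_spec(
      n_genes = 8, seed = s,
      duplicate_pairs = list(duplicate_pair(1, "whole_gene_with_flanks"))))
    d <- design_asrna(g, g$features[1, ])
    a <- find_matches(d, g, sp)
    b <- brute_force_scan(d$target_sense_seq, g, sp)
    expect_true(all(a$aligned_length >= sp$min_match_length))
    expect_true(all(a$identity >= sp$min_identity))
    expect_true(all(do.call(paste, norm_hits(a)) %in%
                      do.call(paste, norm_hits(b))))
    # the intended site is always among the builtin hits
    expect_true(any(a$is_intended))
  }
})

test_that("screening the mirror-image genome yields the mirror-image hit set", {
  g <- dup_fixture(seed = 17)
  gf <- flip_genome(g)
  n <- nchar(g$sequence)
  d <- design_asrna(g, g$features[1, ])
  df <- design_asrna(gf, gf$features[gf$features$locus_tag == "SYN_0001", ])
  h <- norm_hits(find_matches(d, g, screen_params()))
  hf <- find_matches(df, gf, screen_params())
  # map mirrored hits back into original coordinates
  hf_mapped <- data.frame(subject_start = n - hf$subject_end,
                          subject_end = n - hf$subject_start,
                          subject_strand = -hf$subject_strand,
                          aligned_length = hf$aligned_length,
                          identity = hf$identity)
  expect_identical(h, norm_hits(hf_mapped))
})

test_that("intended-site classification is 1 bp overlap on the right strand", {
  g <- clean_fixture(seed = 4)
  d <- design_asrna(g, g$features[1, ])
  w <- d$window
  hit <- function(s, e, strand = w$strand, contig = g$id) {
    data.frame(subject_contig = contig, subject_start = s, subject_end = e,
               subject_strand = strand)
  }
  expect_true(classify_hit(hit(w$genomic_start, w$genomic_end), w, g))
  # adjacent interval shifted by one asRNA length: zero overlap
  expect_false(classify_hit(hit(w$genomic_start + 21L, w$genomic_end + 21L),
                            w, g))
  # single-base overlap still counts as the same binding locus
  expect_true(classify_hit(hit(w$genomic_end - 1L, w$genomic_end + 20L), w, g))
  expect_false(classify_hit(hit(w$genomic_start, w$genomic_end, -w$strand),
                            w, g))
  expect_false(classify_hit(hit(w$genomic_start, w$genomic_end,
                                contig = "other"), w, g))
})

test_that("screen parameters enforce their invariants", {
  expect_error(screen_params(min_identity = 40), "between 50 and 100")
  expect_error(screen_params(seed_word_size = 16, min_match_length = 15),
               "seed_word_size")
  expect_error(find_matches(design_asrna(clean_fixture(), clean_fixture()$features[1, ]),
                            clean_fixture(),
                            screen_params(min_match_length = 22)),
               "exceeds")
})
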