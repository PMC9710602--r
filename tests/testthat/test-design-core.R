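test_that("reverse complement follows Watson-Crick pairing and rejects non-DNA", {
  expect_equal(reverse_complement("ATGC"), "GCAT")
  expect_equal(reverse_complement("AAAA"), "TTTT")
  expect_equal(reverse_complement("ANT"), "ANT")
  expect_error(reverse_complement("ATGU"), "outside")
})

test_that("reverse complement is an involution on random sequences", {
  withr::with_seed(123, {
    for (i in 1:200) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), sample(5:60, 1),
                        replace = TRUE), collapse = "")
      expect_identical(reverse_complement(reverse_complement(s)), s)
    }
  })
})

test_that("window arithmetic anchors on the start codon for both strands", {
  g <- new_genome("W", strrep("ACGT", 150), "linear",
                  data.frame(locus_tag = c("plus", "minus"),
                             gene_name = NA, product = NA,
                             start = c(100L, 100L), end = c(400L, 400L),
                             strand = c(1L, -1L), kind = "CDS"))
  wp <- compute_window(g$features[1, ], offset = -8, length = 21, genome = g)
  expect_equal(c(wp$genomic_start, wp$genomic_end), c(92L, 113L))

  w0 <- compute_window(g$features[1, ], offset = 0, length = 21, genome = g)
  expect_equal(c(w0$genomic_start, w0$genomic_end), c(100L, 121L))

  # minus strand, checked against coordinate-by-coordinate enumeration:
  # mRNA position c maps to genomic (end - 1) - c
  wm <- compute_window(g$features[2, ], offset = -8, length = 21, genome = g)
  gpos <- (400L - 1L) - (-8L:12L)
  expect_equal(wm$genomic_start, min(gpos))
  expect_equal(wm$genomic_end, max(gpos) + 1L)
  expect_equal(c(wm$genomic_start, wm$genomic_end), c(387L, 408L))
})

test_that("impossible windows raise undesignable conditions with reasons", {
  g <- clean_fixture()
  f <- g$features[1, ]
  err <- tryCatch(compute_window(f, offset = -1000, length = 21, genome = g),
                  undesignable_window = function(e) e)
  expect_s3_class(err, "undesignable_window")
  expect_equal(err$reason, "window_outside_contig")

  cds_len <- f$end - f$start
  err2 <- tryCatch(compute_window(f, offset = cds_len - 10L, length = 21,
                                  genome = g),
                   undesignable_window = function(e) e)
  expect_equal(err2$reason, "window_past_cds_3prime")
})

test_that("sense extraction handles both strands and circular wrap-around", {
  g <- new_genome("E", "AAATGGGCCC", "linear",
                  data.frame(locus_tag = "x", gene_name = NA, product = NA,
                             start = 2L, end = 8L, strand = 1L, kind = "CDS"))
  wplus <- structure(list(contig_id = "E", genomic_start = 2L, genomic_end = 5L,
                          strand = 1L, offset = 0L), class = "target_window")
  expect_equal(extract_target_sense(g, wplus), "ATG")
  wminus <- wplus; wminus$strand <- -1L
  expect_equal(extract_target_sense(g, wminus), "CAT")

  # circular wrap: oracle = rotate the sequence, then take a plain substring
  gc <- new_genome("C", "AAATGGGCCC", "circular",
                   data.frame(locus_tag = "x", gene_name = NA, product = NA,
                              start = 0L, end = 6L, strand = 1L, kind = "CDS"))
  wrap <- structure(list(contig_id = "C", genomic_start = 8L, genomic_end = 12L,
                         strand = 1L, offset = 0L), class = "target_window")
  rotated <- paste0(substr(gc$sequence, 9, 10), substr(gc$sequence, 1, 8))
  expect_equal(extract_target_sense(gc, wrap), substr(rotated, 1, 4))
})

test_that("the designed asRNA is the reverse complement of its window", {
  # hand-placed window with an independently computed reverse complement
  sense <- "ATGAAACCCGGGTTTACGTAC"
  g <- new_genome("F", paste0(strrep("CA", 15), sense, strrep("TG", 25)),
                  "linear",
                  data.frame(locus_tag = "fix", gene_name = NA, product = NA,
                             start = 30L, end = 30L + 21L + 50L,
                             strand = 1L, kind = "CDS"))
  d <- design_asrna(g, g$features[1, ], design_params(), offset = 0L)
  expect_equal(d$target_sense_seq, sense)
  expect_equal(d$asrna_seq, "GTACGTAAACCCGGGTTTCAT")

  # definitional invariant over many random fixture genes
  for (seed in c(5, 6)) {
    gg <- clean_fixture(seed = seed, n_genes = 25, fraction_minus_strand = 0.5)
    for (i in seq_len(nrow(gg$features))) {
      d <- design_asrna(gg, gg$features[i, ])
      expect_equal(nchar(d$asrna_seq), 21L)
      expect_identical(d$asrna_seq, reverse_complement(d$target_sense_seq))
      f <- gg$features[i, ]
      if (f$strand == 1L) {
        expect_equal(d$window$genomic_start - f$start, -8L)
      } else {
        expect_equal(f$end - d$window$genomic_end, -8L)
      }
    }
  }
})

test_that("designs are deterministic and strand-symmetric", {
  g <- clean_fixture(seed = 9, fraction_minus_strand = 0.5)
  gf <- flip_genome(g)
  for (lt in g$features$locus_tag) {
    f1 <- g$features[g$features$locus_tag == lt, ]
    f2 <- gf$features[gf$features$locus_tag == lt, ]
    d1a <- design_asrna(g, f1)
    d1b <- design_asrna(g, f1)
    d2 <- design_asrna(gf, f2)
    expect_identical(d1a, d1b)
    expect_identical(d1a$asrna_seq, d2$asrna_seq)
    expect_identical(d1a$target_sense_seq, d2$target_sense_seq)
  }
})

test_that("design parameters enforce their invariants", {
  expect_error(design_params(asrna_length = 9), ">= 10")
  expect_error(design_params(redesign_step = 0), "positive")
  p <- design_params()
  expect_equal(p$asrna_length, 21L)
  expect_equal(p$offset, -8L)
  expect_equal(p$redesign_step, 21L)
  expect_equal(p$max_rounds, 2L)
})
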