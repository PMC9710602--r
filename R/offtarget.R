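#' Off-target screening parameters
#'
#' Thresholds for the genome-wide screen of each asRNA's binding
#' footprint. A reported match must be at least `min_match_length` nt
#' long at `min_identity` percent identity or better. The built-in
#' matcher seeds on exact `seed_word_size`-mers; `evalue_threshold` is
#' used only by the external BLAST backend (the built-in matcher has no
#' e-value model and reports `NA`).
#'
#' @param min_identity Minimum percent identity (50-100; default 80).
#' @param min_match_length Minimum alignment length in nt (default 15).
#' @param seed_word_size Exact-seed length in nt (default 11).
#' @param evalue_threshold E-value cutoff for the external backend
#'   (default 1000, appropriate for short queries).
#' @param backend `"builtin"` or `"external_blast"`.
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(min_identity = 80, min_match_length = 15L,
                          seed_word_size = 11L, evalue_threshold = 1000,
                          backend = c("builtin", "external_blast")) {
  backend <- match.arg(backend)
  min_match_length <- as.integer(min_match_length)
  seed_word_size <- as.integer(seed_word_size)
  if (min_identity < 50 || min_identity > 100) {
    stop("min_identity must be between 50 and 100")
  }
  if (seed_word_size < 4L || seed_word_size > min_match_length) {
    stop("seed_word_size must be between 4 and min_match_length")
  }
  structure(list(min_identity = min_identity,
                 min_match_length = min_match_length,
                 seed_word_size = seed_word_size,
                 evalue_threshold = evalue_threshold,
                 backend = backend),
            class = "screen_params")
}

empty_hits <- function() {
  data.frame(locus_tag = character(), round = integer(),
             subject_contig = character(), subject_start = integer(),
             subject_end = integer(), subject_strand = integer(),
             aligned_length = integer(), identity = numeric(),
             score = integer(), evalue = numeric(),
             is_intended = logical(), overlapping_feature = character(),
             stringsAsFactors = FALSE)
}

# A=1 C=2 G=3 T=4, N (and anything else) = 0: code 0 never matches.
code_seq <- function(s) {
  v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  v[is.na(v)] <- 0L
  v
}

# Both backends report, per (diagonal, strand), the maximal-scoring
# ungapped segment under match=+1/mismatch=-2 (ties broken towards the
# longer, then leftmost segment), kept iff it passes the length and
# identity thresholds. OOB_SCORE poisons positions beyond a linear contig
# so no reported segment can include them.
OOB_SCORE <- -1e9

## ---- exhaustive oracle ----------------------------------------------------

#' Exhaustive off-target scan (test oracle)
#'
#' Evaluates every placement of the binding footprint on both genomic
#' strands by enumerating all sub-windows of every diagonal — no seeding,
#' no heuristics. O(genome length x footprint length^2); intended as the
#' independent reference for [find_matches()] on small genomes, not for
#' production use.
#'
#' @param footprint mRNA-sense binding footprint (the sequence the asRNA
#'   base-pairs with), as a DNA string.
#' @param genome A [new_genome()] object.
#' @param params A [screen_params()] object.
#' @return Hit `data.frame` (see [find_matches()]); `locus_tag`, `round`
#'   and `is_intended` are `NA` because the oracle knows no design
#'   context.
#' @export
brute_force_scan <- function(footprint, genome, params = screen_params()) {
  L <- nchar(footprint)
  stopifnot(L >= params$min_match_length)
  n <- genome_length(genome)
  hits <- empty_hits()
  for (strand in c(1L, -1L)) {
    p_seq <- if (strand == 1L) footprint else reverse_complement(footprint)
    qv <- code_seq(p_seq)
    if (genome$topology == "circular") {
      gx <- code_seq(genome$sequence)
      gx <- c(gx, gx[seq_len(min(L - 1L, n))])
      d_vec <- 0:(n - 1L)
      idx_of <- function(pos) pos + 1L
    } else {
      gx <- c(rep(-1L, L - 1L), code_seq(genome$sequence), rep(-1L, L - 1L))
      d_vec <- (1L - L):(n - 1L)
      idx_of <- function(pos) pos + L
    }
    # all (start, end] sub-windows of a footprint-length diagonal
    ii <- unlist(lapply(0:(L - 1L), function(i) rep(i, L - i)))
    jj <- unlist(lapply(0:(L - 1L), function(i) (i + 1L):L))
    seg_len <- jj - ii
    for (chunk in split(d_vec, ceiling(seq_along(d_vec) / 4096))) {
      nd <- length(chunk)
      gidx <- idx_of(outer(0:(L - 1L), chunk, "+"))
      gm <- matrix(gx[gidx], nrow = L)
      m <- (gm == qv) & (qv > 0L)
      sc <- ifelse(m, 1, -2)
      sc[gm < 0L] <- OOB_SCORE
      scum <- rbind(0, apply(sc, 2, cumsum))
      mcum <- rbind(0L, apply(m + 0L, 2, cumsum))
      seg_score <- scum[jj + 1L, , drop = FALSE] - scum[ii + 1L, , drop = FALSE]
      seg_match <- mcum[jj + 1L, , drop = FALSE] - mcum[ii + 1L, , drop = FALSE]
      key <- seg_score * 1e4 + seg_len * 100 + (99 - ii)
      best <- max.col(t(key), ties.method = "first")
      pick <- cbind(best, seq_len(nd))
      b_sc <- seg_score[pick]
      b_mt <- seg_match[pick]
      b_i <- ii[best]
      b_len <- seg_len[best]
      ident <- 100 * b_mt / b_len
      ok <- b_len >= params$min_match_length &
        ident >= params$min_identity & b_sc > OOB_SCORE / 2
      if (!any(ok)) next
      s0 <- chunk[ok] + b_i[ok]
      if (genome$topology == "circular") s0 <- s0 %% n
      hits <- rbind(hits, data.frame(
        locus_tag = NA_character_, round = NA_integer_,
        subject_contig = genome$id,
        subject_start = as.integer(s0),
        subject_end = as.integer(s0 + b_len[ok]),
        subject_strand = strand,
        aligned_length = as.integer(b_len[ok]),
        identity = ident[ok],
        score = as.integer(b_sc[ok]),
        evalue = NA_real_,
        is_intended = NA,
        overlapping_feature = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  hits <- dedupe_hits(hits)
  hits$overlapping_feature <- annotate_overlaps(hits, genome)
  hits
}

## ---- builtin seed-and-extend matcher --------------------------------------

#' Screen one asRNA design against the whole genome
#'
#' Built-in matcher: every exact `seed_word_size`-mer shared between the
#' design's binding footprint and the genome (both strands) nominates a
#' diagonal; each seeded diagonal is extended ungapped in both directions
#' under match=+1/mismatch=-2 and trimmed to its maximal-scoring segment;
#' extensions from multiple seeds on one diagonal merge into the same
#' segment. Surviving alignments with `aligned_length >=
#' min_match_length` and `identity >= min_identity` are reported,
#' deduplicated by (subject interval, strand), and classified against the
#' design's intended window by [classify_hit()].
#'
#' @param design An [design_asrna()] result.
#' @param genome A [new_genome()] object.
#' @param params A [screen_params()] object.
#' @return `data.frame` with one row per hit: `locus_tag`, `round`,
#'   `subject_contig`, `subject_start`/`subject_end` (0-based half-open;
#'   `subject_end` may exceed the contig length when a hit wraps a
#'   circular origin), `subject_strand`, `aligned_length`, `identity`,
#'   `score`, `evalue` (`NA` for this backend), `is_intended`,
#'   `overlapping_feature`.
#' @export
find_matches <- function(design, genome, params = screen_params()) {
  L <- nchar(design$target_sense_seq)
  if (params$min_match_length > L) {
    stop("min_match_length exceeds the asRNA length")
  }
  hits <- empty_hits()
  n <- genome_length(genome)
  k <- params$seed_word_size
  circular <- genome$topology == "circular"
  gseq <- if (circular) {
    paste0(genome$sequence, substr(genome$sequence, 1L, min(L - 1L, n)))
  } else {
    genome$sequence
  }
  m_ext <- nchar(gseq)
  genome_kmers <- substring(gseq, 1:(m_ext - k + 1L), k:m_ext)
  gv <- code_seq(genome$sequence)
  gx <- c(rep(-1L, L - 1L), gv, rep(-1L, L - 1L))   # linear OOB padding

  for (strand in c(1L, -1L)) {
    p_seq <- if (strand == 1L) design$target_sense_seq
    else reverse_complement(design$target_sense_seq)
    qv <- code_seq(p_seq)
    q_kmers <- substring(p_seq, 1:(L - k + 1L), k:L)
    diagonals <- integer()
    for (qi in seq_along(q_kmers)) {
      if (grepl("N", q_kmers[qi], fixed = TRUE)) next
      pos <- which(genome_kmers == q_kmers[qi]) - 1L   # 0-based genomic
      if (length(pos) == 0L) next
      d <- pos - (qi - 1L)
      if (circular) d <- d %% n
      diagonals <- c(diagonals, d)
    }
    for (d in unique(diagonals)) {
      gpos <- d + 0:(L - 1L)
      gcodes <- if (circular) gv[(gpos %% n) + 1L] else gx[gpos + L]
      seg <- best_segment(gcodes, qv)
      if (is.null(seg)) next
      ident <- 100 * seg$matches / seg$len
      if (seg$len < params$min_match_length ||
          ident < params$min_identity) next
      s0 <- d + seg$i
      if (circular) s0 <- s0 %% n
      hits <- rbind(hits, data.frame(
        locus_tag = design$locus_tag, round = design$round,
        subject_contig = genome$id,
        subject_start = as.integer(s0),
        subject_end = as.integer(s0 + seg$len),
        subject_strand = strand,
        aligned_length = as.integer(seg$len),
        identity = ident,
        score = as.integer(seg$score),
        evalue = NA_real_,
        is_intended = NA,
        overlapping_feature = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  hits <- dedupe_hits(hits)
  if (nrow(hits) > 0L) {
    hits$is_intended <- vapply(seq_len(nrow(hits)), function(i) {
      classify_hit(hits[i, ], design$window, genome)
    }, logical(1))
  }
  hits$overlapping_feature <- annotate_overlaps(hits, genome)
  hits
}

# Maximal-scoring ungapped segment of one diagonal, by a linear
# prefix-minimum scan (independent of the oracle's exhaustive
# enumeration). Returns NULL when every segment is negative or the
# diagonal has no match at all. Ties: higher score, then longer, then
# leftmost.
best_segment <- function(gcodes, qv) {
  L <- length(qv)
  s <- ifelse(gcodes == qv & qv > 0L, 1, -2)
  s[gcodes < 0L] <- OOB_SCORE
  cum <- c(0, cumsum(s))
  # fmin[j] = index (into cum) of the first minimum of cum[1..j]
  fmin <- integer(L)
  fmin[1] <- 1L
  for (t in 2:L) {
    fmin[t] <- if (cum[t] < cum[fmin[t - 1L]]) t else fmin[t - 1L]
  }
  best <- NULL
  for (j in seq_len(L)) {
    i_cum <- fmin[j]
    sc <- cum[j + 1L] - cum[i_cum]
    i0 <- i_cum - 1L                     # 0-based segment start
    len <- j - i0
    if (is.null(best) || sc > best$score ||
        (sc == best$score && (len > best$len ||
                              (len == best$len && i0 < best$i)))) {
      best <- list(i = i0, len = len, score = sc)
    }
  }
  if (best$score <= 0) return(NULL)
  idx <- best$i + seq_len(best$len)
  best$matches <- sum(gcodes[idx] == qv[idx] & qv[idx] > 0L)
  best
}

# Keep the highest-identity record per (interval, strand).
dedupe_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$subject_start, hits$subject_end, hits$subject_strand,
             -hits$identity)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$subject_start, hits$subject_end, hits$subject_strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

## ---- classification -------------------------------------------------------

# Decompose a possibly origin-wrapping [s, e) interval into linear arcs.
interval_arcs <- function(s, e, n) {
  if (e <= n) list(c(s, e)) else list(c(s, n), c(0L, e - n))
}

#' Is a hit the intended binding site?
#'
#' A hit is intended iff it lies on the same contig, in the orientation of
#' the intended binding site (the gene's coding strand), and its subject
#' interval overlaps the intended window by at least 1 bp. Everything
#' else is an off-target.
#'
#' @param hit One row of a hit `data.frame`.
#' @param intended The design's [compute_window()] result.
#' @param genome The screened genome (needed to resolve origin-wrapping
#'   intervals on circular contigs).
#' @return `TRUE` if intended, `FALSE` if off-target.
#' @export
classify_hit <- function(hit, intended, genome) {
  if (hit$subject_contig != intended$contig_id) return(FALSE)
  if (hit$subject_strand != intended$strand) return(FALSE)
  n <- genome_length(genome)
  a1 <- interval_arcs(hit$subject_start, hit$subject_end, n)
  a2 <- interval_arcs(intended$genomic_start, intended$genomic_end, n)
  for (x in a1) for (y in a2) {
    if (max(x[1], y[1]) < min(x[2], y[2])) return(TRUE)
  }
  FALSE
}

# Annotation context: which CDS (if any) each hit's interval overlaps.
annotate_overlaps <- function(hits, genome) {
  if (nrow(hits) == 0L) return(character(0))
  cds <- cds_features(genome)
  n <- genome_length(genome)
  vapply(seq_len(nrow(hits)), function(i) {
    arcs <- interval_arcs(hits$subject_start[i], hits$subject_end[i], n)
    for (j in seq_len(nrow(cds))) {
      for (a in arcs) {
        if (max(a[1], cds$start[j]) < min(a[2], cds$end[j])) {
          return(cds$locus_tag[j])
        }
      }
    }
    NA_character_
  }, character(1))
}
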