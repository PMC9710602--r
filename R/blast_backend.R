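#' Screen designs with an external BLAST+ installation
#'
#' Optional backend: exports the genome and the asRNA binding footprints
#' to FASTA, formats a nucleotide database with `makeblastdb`, runs
#' `blastn -task blastn-short` with the user's e-value and identity
#' thresholds, and parses the 12-column tabular output (outfmt 6) into
#' the same hit table as [find_matches()], with `evalue` populated and
#' coordinates converted to the internal 0-based half-open convention.
#' Gapped alignments are discarded (the screening contract is ungapped).
#'
#' @param designs List of [design_asrna()] results.
#' @param genome A [new_genome()] object.
#' @param params A [screen_params()] object (`evalue_threshold`,
#'   `min_identity`, `min_match_length`, `seed_word_size` are honoured).
#' @return Hit `data.frame` as in [find_matches()], rows for all designs.
#' @export
run_external_blast <- function(designs, genome, params = screen_params()) {
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (blastn == "" || makedb == "") {
    stop("BLAST+ (blastn/makeblastdb) not found on PATH; ",
         "use screen_params(backend = \"builtin\") instead")
  }
  td <- tempfile("blastscreen")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  db_fa <- file.path(td, "genome.fasta")
  q_fa <- file.path(td, "queries.fasta")
  gset <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, genome$id))
  Biostrings::writeXStringSet(gset, db_fa)
  foot <- vapply(designs, function(d) d$target_sense_seq, character(1))
  names(foot) <- vapply(designs, function(d) d$locus_tag, character(1))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(foot), q_fa)

  run <- function(cmd, args) {
    out <- suppressWarnings(system2(cmd, args, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop(basename(cmd), " failed (exit ", status, "): ",
           paste(out, collapse = "\n"))
    }
    out
  }
  run(makedb, c("-in", db_fa, "-dbtype", "nucl"))
  tab <- file.path(td, "hits.tsv")
  run(blastn, c("-task", "blastn-short", "-query", q_fa, "-db", db_fa,
                "-evalue", format(params$evalue_threshold, scientific = FALSE),
                "-perc_identity", params$min_identity,
                "-word_size", params$seed_word_size,
                "-dust", "no", "-outfmt", "6", "-out", tab))
  hits <- parse_blast_tabular(readLines(tab), contig = genome$id)
  hits <- hits[hits$aligned_length >= params$min_match_length, , drop = FALSE]
  hits <- dedupe_hits_by_query(hits)
  by_tag <- stats::setNames(designs,
                            vapply(designs, `[[`, character(1), "locus_tag"))
  if (nrow(hits) > 0L) {
    hits$round <- vapply(hits$locus_tag, function(lt) by_tag[[lt]]$round,
                         integer(1))
    hits$is_intended <- vapply(seq_len(nrow(hits)), function(i) {
      classify_hit(hits[i, ], by_tag[[hits$locus_tag[i]]]$window, genome)
    }, logical(1))
  }
  hits$overlapping_feature <- annotate_overlaps(hits, genome)
  rownames(hits) <- NULL
  hits
}

# outfmt 6: qseqid sseqid pident length mismatch gapopen qstart qend
# sstart send evalue bitscore. sstart > send marks a minus-strand hit.
parse_blast_tabular <- function(lines, contig) {
  hits <- empty_hits()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L) {
      stop("malformed BLAST tabular line (expected 12 fields): ", ln)
    }
    suppressWarnings({
      sstart <- as.integer(f[9]); send <- as.integer(f[10])
      len <- as.integer(f[4]); ident <- as.numeric(f[3])
      gapopen <- as.integer(f[6])
    })
    if (anyNA(c(sstart, send, len, ident, gapopen))) {
      stop("malformed BLAST tabular line (non-numeric field): ", ln)
    }
    if (gapopen > 0L) next
    strand <- if (sstart <= send) 1L else -1L
    lo <- min(sstart, send)
    matches <- round(len * ident / 100)
    hits <- rbind(hits, data.frame(
      locus_tag = f[1], round = NA_integer_, subject_contig = f[2],
      subject_start = lo - 1L,                 # 1-based inclusive -> 0-based
      subject_end = lo - 1L + len,
      subject_strand = strand,
      aligned_length = len, identity = ident,
      score = as.integer(matches - 2L * (len - matches)),
      evalue = as.numeric(f[11]),
      is_intended = NA, overlapping_feature = NA_character_,
      stringsAsFactors = FALSE))
  }
  hits
}

dedupe_hits_by_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$locus_tag, hits$subject_start, hits$subject_end,
             hits$subject_strand, -hits$identity)
  hits <- hits[o, , drop = FALSE]
  key <- paste(hits$locus_tag, hits$subject_start, hits$subject_end,
               hits$subject_strand)
  hits[!duplicated(key), , drop = FALSE]
}
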