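#' Design parameters
#'
#' Bundles the tunables of asRNA construction. The defaults — a 21 nt
#' asRNA anchored at offset -8 so its window spans the tail of the
#' Shine-Dalgarno region, the start codon and the first codons — follow
#' established design practice for translation-blocking antisense RNAs.
#' `offset` is the mRNA-relative position of the window's 5'-most base,
#' with 0 at the first base of the start codon and negative values
#' upstream. The redesign step defaults to the asRNA length so that a
#' second-round window is disjoint from the first. The workflow performs
#' at most two design rounds; this cap is fixed, not a parameter.
#'
#' @param asrna_length asRNA length in nt (>= 10; default 21).
#' @param offset Signed window offset in nt (default -8).
#' @param redesign_step Offset increment for round 2 (default
#'   `asrna_length`).
#' @return A list of class `design_params`.
#' @export
design_params <- function(asrna_length = 21L, offset = -8L,
                          redesign_step = asrna_length) {
  asrna_length <- as.integer(asrna_length)
  offset <- as.integer(offset)
  redesign_step <- as.integer(redesign_step)
  if (is.na(asrna_length) || asrna_length < 10L) {
    stop("asrna_length must be an integer >= 10 (shorter queries make the ",
         "off-target screen meaningless)")
  }
  if (is.na(redesign_step) || redesign_step < 1L) {
    stop("redesign_step must be a positive integer")
  }
  structure(list(asrna_length = asrna_length, offset = offset,
                 redesign_step = redesign_step, max_rounds = 2L),
            class = "design_params")
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick reverse complement over the alphabet
#' `{A,C,G,T,N}`; `N` maps to `N`. Any other character is an error.
#'
#' @param seq DNA string.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ATGC")  # "GCAT"
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Condition constructor: a gene/offset combination for which no window of
# the requested length exists. Carried as a classed condition so the
# pipeline can record the reason instead of aborting a batch.
undesignable_window <- function(reason, locus_tag, detail) {
  structure(class = c("undesignable_window", "error", "condition"),
            list(message = sprintf("gene %s undesignable: %s (%s)",
                                   locus_tag, reason, detail),
                 call = NULL, reason = reason, locus_tag = locus_tag))
}

#' Compute the genomic target window for a gene
#'
#' Maps an mRNA-relative window onto genomic coordinates. mRNA coordinate
#' 0 is the first base of the start codon; the window covers mRNA
#' positions `[offset, offset + length)`. For a plus-strand gene this is
#' genomic `[start + offset, start + offset + length)`; for a minus-strand
#' gene, `[end - offset - length, end - offset)`. On circular contigs the
#' window may wrap across the origin (`genomic_end` then exceeds the
#' contig length). On linear contigs a window crossing a contig boundary
#' is an error, as is a positive offset pushing the window past the
#' annotated CDS 3' end — both raised as `undesignable_window` conditions
#' with a machine-readable `reason`.
#'
#' @param feature One row of a genome's feature table (a CDS).
#' @param offset Signed offset in nt.
#' @param length Window length in nt.
#' @param genome The [new_genome()] the feature belongs to.
#' @return A list of class `target_window` with fields `contig_id`,
#'   `genomic_start`, `genomic_end`, `strand`, `offset`.
#' @export
compute_window <- function(feature, offset, length, genome) {
  offset <- as.integer(offset)
  length <- as.integer(length)
  stopifnot(length > 0L)
  n <- genome_length(genome)
  cds_len <- feature$end - feature$start
  if (offset > 0L && offset + length > cds_len) {
    stop(undesignable_window("window_past_cds_3prime", feature$locus_tag,
                             sprintf("offset %d + length %d exceeds CDS length %d",
                                     offset, length, cds_len)))
  }
  if (feature$strand == 1L) {
    gs <- feature$start + offset
  } else {
    gs <- feature$end - offset - length
  }
  ge <- gs + length
  if (genome$topology == "linear") {
    if (gs < 0L || ge > n) {
      stop(undesignable_window("window_outside_contig", feature$locus_tag,
                               sprintf("window [%d, %d) outside contig [0, %d)",
                                       gs, ge, n)))
    }
  } else {
    gs <- gs %% n
    ge <- gs + length
  }
  structure(list(contig_id = genome$id, genomic_start = gs, genomic_end = ge,
                 strand = feature$strand, offset = offset),
            class = "target_window")
}

#' Extract the mRNA-sense sequence of a target window
#'
#' Returns the coding-strand sequence of the window, 5' to 3': for a
#' plus-strand window the stored substring, for a minus-strand window its
#' reverse complement. Windows wrapping the origin of a circular contig
#' concatenate both arcs.
#'
#' @param genome A [new_genome()] object.
#' @param window A [compute_window()] result.
#' @return DNA string of length `genomic_end - genomic_start`.
#' @export
extract_target_sense <- function(genome, window) {
  n <- genome_length(genome)
  gs <- window$genomic_start
  ge <- window$genomic_end
  if (ge <= n) {
    s <- substr(genome$sequence, gs + 1L, ge)
  } else {
    if (genome$topology != "circular") {
      stop("window [", gs, ", ", ge, ") out of bounds for linear contig ",
           genome$id)
    }
    s <- paste0(substr(genome$sequence, gs + 1L, n),
                substr(genome$sequence, 1L, ge - n))
  }
  if (window$strand == -1L) s <- reverse_complement(s)
  s
}

#' Design one asRNA for one gene
#'
#' Composes [compute_window()], [extract_target_sense()] and
#' [reverse_complement()]: the asRNA is the perfect reverse complement of
#' the window's mRNA-sense sequence.
#'
#' @param genome A [new_genome()] object.
#' @param feature One CDS row of the genome's feature table.
#' @param params A [design_params()] object.
#' @param offset Window offset to use (defaults to `params$offset`).
#' @param round Design round, 1 or 2.
#' @return A list of class `asrna_design` with the window, the target
#'   sense sequence and the asRNA sequence.
#' @export
design_asrna <- function(genome, feature, params = design_params(),
                         offset = params$offset, round = 1L) {
  window <- compute_window(feature, offset, params$asrna_length, genome)
  sense <- extract_target_sense(genome, window)
  structure(list(locus_tag = feature$locus_tag,
                 round = as.integer(round),
                 window = window,
                 target_sense_seq = sense,
                 asrna_seq = reverse_complement(sense)),
            class = "asrna_design")
}

#' @export
print.asrna_design <- function(x, ...) {
  cat(sprintf("<asrna_design> %s round %d: offset %+d, window [%d, %d) strand %+d\n  5'-%s-3'\n",
              x$locus_tag, x$round, x$window$offset, x$window$genomic_start,
              x$window$genomic_end, x$window$strand, x$asrna_seq))
  invisible(x)
}
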