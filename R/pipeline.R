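#' Offset for the redesign round
#'
#' A gene flagged with off-target hits in round 1 is redesigned exactly
#' once, at the round-1 offset plus `redesign_step`. With the default
#' step (one asRNA length) the round-2 window is disjoint from, and
#' immediately downstream of, the round-1 window — still inside the
#' translation-initiation region but clear of a local duplication.
#'
#' @param params A [design_params()] object.
#' @param round1_offset Offset used in round 1 (defaults to
#'   `params$offset`).
#' @return Integer offset for round 2.
#' @export
#' @examples
#' next_offset(design_params())  # -8 + 21 = 13
next_offset <- function(params, round1_offset = params$offset) {
  as.integer(round1_offset) + params$redesign_step
}

#' Design an asRNA library for a genome
#'
#' Runs the full workflow: select targets, design each gene's asRNA at
#' the configured offset, screen it genome-wide, redesign genes with at
#' least one off-target hit once at [next_offset()], screen again, and
#' assemble per-gene outcomes plus all screening evidence. There is never
#' a third design round: with highly similar recent gene duplicates,
#' iterating would walk the window out of the translation-initiation
#' region without converging.
#'
#' Per-gene outcome statuses:
#' \describe{
#'   \item{clean_round1}{no off-target hit; the round-1 design is final.}
#'   \item{clean_round2}{round 1 was flagged, the redesign screens clean.}
#'   \item{flagged}{both rounds have off-target hits; the round-2 design
#'     ships anyway, carrying its evidence, so users can judge. (If the
#'     round-2 window cannot be constructed, the round-1 design is kept
#'     and the failure recorded in `undesignable_reason`.)}
#'   \item{undesignable}{no round-1 window exists for this gene at the
#'     requested offset; `undesignable_reason` says why.}
#' }
#' Per-gene failures never abort the batch.
#'
#' @param genome A [new_genome()] object.
#' @param targets Optional identifier vector ([read_target_list()]); all
#'   CDS features when `NULL`.
#' @param dparams A [design_params()] object.
#' @param sparams A [screen_params()] object; its `backend` selects the
#'   built-in matcher or external BLAST.
#' @param input_name Optional provenance string (e.g. the genome file).
#' @param screen_fun Screening function `(design, genome, sparams)`;
#'   overridable for instrumentation, defaults to the backend named in
#'   `sparams`.
#' @return A list of class `design_report` with elements `genome_id`,
#'   `dparams`, `sparams`, `outcomes` (one row per target), `hits` (all
#'   rounds), `provenance`.
#' @export
design_library <- function(genome, targets = NULL,
                           dparams = design_params(),
                           sparams = screen_params(),
                           input_name = NA_character_,
                           screen_fun = NULL) {
  sel <- select_targets(genome, targets)
  if (nrow(sel) == 0L) stop("no design targets: the genome has no CDS features")
  if (is.null(screen_fun)) {
    screen_fun <- if (sparams$backend == "external_blast") {
      function(design, genome, sparams) {
        run_external_blast(list(design), genome, sparams)
      }
    } else {
      find_matches
    }
  }
  outcomes <- list()
  all_hits <- empty_hits()
  for (i in seq_len(nrow(sel))) {
    feature <- sel[i, ]
    res <- design_one_gene(genome, feature, dparams, sparams, screen_fun)
    outcomes[[i]] <- res$outcome
    all_hits <- rbind(all_hits, res$hits)
  }
  outcomes <- do.call(rbind, outcomes)
  rownames(outcomes) <- NULL
  rownames(all_hits) <- NULL
  structure(list(genome_id = genome$id,
                 dparams = dparams, sparams = sparams,
                 outcomes = outcomes, hits = all_hits,
                 provenance = list(input = input_name, genome_id = genome$id,
                                   tool_version = as.character(
                                     utils::packageVersion("asrnadesign")))),
            class = "design_report")
}

design_one_gene <- function(genome, feature, dparams, sparams, screen_fun) {
  row <- function(status, design = NULL, off1 = NA_integer_,
                  off2 = NA_integer_, reason = NA_character_) {
    data.frame(
      locus_tag = feature$locus_tag,
      gene_name = feature$gene_name,
      product = feature$product,
      strand = feature$strand,
      status = status,
      round = if (is.null(design)) NA_integer_ else design$round,
      offset = if (is.null(design)) NA_integer_ else design$window$offset,
      window_start = if (is.null(design)) NA_integer_
                     else design$window$genomic_start,
      window_end = if (is.null(design)) NA_integer_
                   else design$window$genomic_end,
      target_sense_seq = if (is.null(design)) NA_character_
                         else design$target_sense_seq,
      asrna_seq = if (is.null(design)) NA_character_ else design$asrna_seq,
      round1_offtarget_count = off1,
      round2_offtarget_count = off2,
      undesignable_reason = reason,
      stringsAsFactors = FALSE)
  }
  d1 <- tryCatch(design_asrna(genome, feature, dparams,
                              offset = dparams$offset, round = 1L),
                 undesignable_window = function(e) e)
  if (inherits(d1, "undesignable_window")) {
    return(list(outcome = row("undesignable", reason = d1$reason),
                hits = empty_hits()))
  }
  hits1 <- screen_fun(d1, genome, sparams)
  off1 <- sum(!hits1$is_intended)
  if (off1 == 0L) {
    return(list(outcome = row("clean_round1", d1, off1 = 0L), hits = hits1))
  }
  offset2 <- next_offset(dparams, dparams$offset)
  d2 <- tryCatch(design_asrna(genome, feature, dparams,
                              offset = offset2, round = 2L),
                 undesignable_window = function(e) e)
  if (inherits(d2, "undesignable_window")) {
    return(list(outcome = row("flagged", d1, off1 = off1, reason = d2$reason),
                hits = hits1))
  }
  hits2 <- screen_fun(d2, genome, sparams)
  off2 <- sum(!hits2$is_intended)
  status <- if (off2 == 0L) "clean_round2" else "flagged"
  list(outcome = row(status, d2, off1 = off1, off2 = off2),
       hits = rbind(hits1, hits2))
}

#' @export
print.design_report <- function(x, ...) {
  tab <- table(factor(x$outcomes$status,
                      levels = c("clean_round1", "clean_round2", "flagged",
                                 "undesignable")))
  cat(sprintf("<design_report> %s: %d gene(s) designed\n",
              x$genome_id, nrow(x$outcomes)))
  for (s in names(tab)) cat(sprintf("  %-13s %d\n", s, tab[[s]]))
  cat(sprintf("  off-target hit rows: %d\n", sum(!x$hits$is_intended,
                                                 na.rm = TRUE)))
  invisible(x)
}
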