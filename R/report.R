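#' Write a design report to CSV
#'
#' Serialises a [design_library()] result as three UTF-8, RFC-4180 CSV
#' files sharing a path prefix:
#' \describe{
#'   \item{`<prefix>_designs.csv`}{one row per gene: `locus_tag`,
#'     `gene_name`, `product`, `strand`, `round`, `offset`,
#'     `window_start_1based`, `window_end_1based` (1-based inclusive
#'     span, as GenBank prints it), `target_sense_seq`, `asrna_seq`,
#'     `status`, `offtarget_count` (final round), plus
#'     `undesignable_reason`.}
#'   \item{`<prefix>_hits.csv`}{one row per screening hit, both rounds:
#'     coordinates 1-based inclusive, strand, `aligned_length`,
#'     `identity`, `score`, `evalue` (empty for the built-in backend),
#'     `is_intended`, `overlapping_feature`.}
#'   \item{`<prefix>_run_info.csv`}{key/value provenance and parameters;
#'     the timestamp row is omitted with `timestamp = FALSE`, making
#'     output byte-identical across reruns.}
#' }
#' Spreadsheet (`xlsx`) encoding of the same tables is not implemented;
#' requesting it is an error.
#'
#' @param report A [design_library()] result.
#' @param prefix Output path prefix.
#' @param format Only `"csv"` is supported.
#' @param timestamp Include a timestamp row in the run-info file?
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, prefix, format = c("csv", "xlsx"),
                         timestamp = TRUE) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("spreadsheet output is not implemented; use format = \"csv\"")
  }
  stopifnot(inherits(report, "design_report"))
  o <- report$outcomes
  final_count <- ifelse(is.na(o$round), NA_integer_,
                        ifelse(o$round == 2L & !is.na(o$round2_offtarget_count),
                               o$round2_offtarget_count,
                               o$round1_offtarget_count))
  designs <- data.frame(
    locus_tag = o$locus_tag,
    gene_name = o$gene_name,
    product = o$product,
    strand = ifelse(o$strand == 1L, "+", "-"),
    round = o$round,
    offset = o$offset,
    window_start_1based = o$window_start + 1L,
    window_end_1based = o$window_end,
    target_sense_seq = o$target_sense_seq,
    asrna_seq = o$asrna_seq,
    status = o$status,
    offtarget_count = final_count,
    undesignable_reason = o$undesignable_reason,
    stringsAsFactors = FALSE)
  h <- report$hits
  hits <- data.frame(
    locus_tag = h$locus_tag,
    round = h$round,
    subject_contig = h$subject_contig,
    subject_start_1based = h$subject_start + 1L,
    subject_end_1based = h$subject_end,
    subject_strand = ifelse(h$subject_strand == 1L, "+", "-"),
    aligned_length = h$aligned_length,
    identity = h$identity,
    score = h$score,
    evalue = h$evalue,
    is_intended = h$is_intended,
    overlapping_feature = h$overlapping_feature,
    stringsAsFactors = FALSE)
  info <- rbind(
    data.frame(key = "input", value = as.character(report$provenance$input)),
    data.frame(key = "genome_id", value = report$genome_id),
    data.frame(key = "tool_version",
               value = report$provenance$tool_version),
    data.frame(key = "asrna_length",
               value = as.character(report$dparams$asrna_length)),
    data.frame(key = "offset", value = as.character(report$dparams$offset)),
    data.frame(key = "redesign_step",
               value = as.character(report$dparams$redesign_step)),
    data.frame(key = "min_identity",
               value = as.character(report$sparams$min_identity)),
    data.frame(key = "min_match_length",
               value = as.character(report$sparams$min_match_length)),
    data.frame(key = "seed_word_size",
               value = as.character(report$sparams$seed_word_size)),
    data.frame(key = "backend", value = report$sparams$backend))
  if (timestamp) {
    info <- rbind(info, data.frame(
      key = "timestamp",
      value = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  }
  paths <- paste0(prefix, c("_designs.csv", "_hits.csv", "_run_info.csv"))
  write.csv(designs, paths[1], row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  write.csv(hits, paths[2], row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  write.csv(info, paths[3], row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(paths)
}
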