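#' Construct a genome object
#'
#' Container for one contig: its sequence, topology, and annotated
#' features. Coordinates in `features` are 0-based half-open; strand is
#' `+1L` or `-1L`. Most users obtain genomes from [parse_genome()] or
#' [make_genome()] rather than calling this directly.
#'
#' @param id Contig identifier.
#' @param sequence DNA string over `A,C,G,T,N` (uppercased on input).
#' @param topology `"linear"` or `"circular"`.
#' @param features `data.frame` with columns `locus_tag`, `gene_name`,
#'   `product`, `start`, `end`, `strand`, `kind`. May have zero rows.
#' @return An object of class `genome`.
#' @export
new_genome <- function(id, sequence, topology = c("linear", "circular"),
                       features = empty_features()) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("locus_tag", "gene_name", "product", "start", "end",
                "strand", "kind")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0L) {
    stop("features is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  features <- features[required]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  n <- nchar(sequence)
  if (nrow(features) > 0L) {
    bad <- features$start < 0L | features$start >= features$end |
      (topology == "linear" & features$end > n)
    if (any(bad)) {
      stop("feature(s) out of bounds or malformed: ",
           paste(features$locus_tag[bad], collapse = ", "))
    }
    if (anyDuplicated(features$locus_tag)) {
      dup <- unique(features$locus_tag[duplicated(features$locus_tag)])
      stop("duplicate locus_tag(s): ", paste(dup, collapse = ", "))
    }
    if (!all(features$strand %in% c(1L, -1L))) {
      stop("feature strand must be +1 or -1")
    }
  }
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "genome")
}

empty_features <- function() {
  data.frame(locus_tag = character(), gene_name = character(),
             product = character(), start = integer(), end = integer(),
             strand = integer(), kind = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.genome <- function(x, ...) {
  ncds <- sum(x$features$kind == "CDS")
  cat(sprintf("<genome> %s: %d bp, %s, %d feature(s) (%d CDS)\n",
              x$id, nchar(x$sequence), x$topology, nrow(x$features), ncds))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

cds_features <- function(genome) {
  f <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  rownames(f) <- NULL
  f
}

## ---- flat-file parsing ----------------------------------------------------

#' Read an annotated genome from a GenBank or EMBL flat file
#'
#' Parses the sequence, topology and feature table of the first (and, for
#' this tool, only) record in the file. Coordinates are converted from the
#' 1-based inclusive convention of both formats to the internal 0-based
#' half-open convention; `complement(...)` locations get strand `-1`.
#' Compound (`join(...)`) locations have no well-defined start-codon anchor
#' and are skipped with a warning. Features other than CDS are retained
#' with `kind = "other"` but are never design targets.
#'
#' @param path Path to the flat file.
#' @param format `"genbank"`, `"embl"`, or `"auto"` (sniff the first line).
#' @return A [new_genome()] object.
#' @export
parse_genome <- function(path, format = c("auto", "genbank", "embl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genome file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty genome file: ", path)
  if (format == "auto") {
    first <- lines[grepl("\\S", lines)][1]
    format <- if (grepl("^LOCUS", first)) "genbank"
    else if (grepl("^ID ", first)) "embl"
    else stop("cannot auto-detect format of ", path,
              " (expected a LOCUS or ID header line)")
  }
  g <- switch(format,
              genbank = parse_genbank_lines(lines),
              embl = parse_embl_lines(lines))
  if (sum(g$features$kind == "CDS") == 0L) {
    warning("no CDS features found in ", path,
            "; nothing will be designable", call. = FALSE)
  }
  g
}

# Shared feature-table walker: `rows` is a data.frame with columns
# key, loc, quals (list of qualifier strings, already unwrapped).
features_from_table <- function(entries) {
  feats <- empty_features()
  skipped <- character()
  for (e in entries) {
    if (e$key == "source") next
    loc <- e$loc
    strand <- 1L
    if (grepl("^complement\\(", loc)) {
      strand <- -1L
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("join|order", loc)) {
      skipped <- c(skipped, qualifier_value(e$quals, "locus_tag",
                                            default = loc))
      next
    }
    loc <- gsub("[<>]", "", loc)
    m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
    if (length(m) != 3L) {
      skipped <- c(skipped, qualifier_value(e$quals, "locus_tag",
                                            default = loc))
      next
    }
    start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
    lt <- qualifier_value(e$quals, "locus_tag")
    if (is.na(lt)) lt <- qualifier_value(e$quals, "gene")
    if (is.na(lt)) lt <- sprintf("feature_%d_%d", start1, end1)
    feats <- rbind(feats, data.frame(
      locus_tag = lt,
      gene_name = qualifier_value(e$quals, "gene"),
      product = qualifier_value(e$quals, "product"),
      start = start1 - 1L,          # 1-based inclusive -> 0-based half-open
      end = end1,
      strand = strand,
      kind = if (e$key == "CDS") "CDS" else "other",
      stringsAsFactors = FALSE))
  }
  if (length(skipped) > 0L) {
    warning("skipped ", length(skipped),
            " feature(s) with compound or unsupported locations: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  feats
}

qualifier_value <- function(quals, name, default = NA_character_) {
  pat <- paste0("^/", name, "=")
  hit <- quals[grepl(pat, quals)]
  if (length(hit) == 0L) return(default)
  v <- sub(pat, "", hit[1])
  gsub("^\"|\"$", "", v)
}

parse_genbank_lines <- function(lines) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("not a GenBank file: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- if (length(locus) >= 2L) locus[2] else "unnamed"
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"

  feat_start <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) stop("GenBank record has no ORIGIN sequence block")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L

  entries <- list()
  if (length(feat_start) > 0L) {
    ft <- lines[(feat_start[1] + 1L):(origin_i[1] - 1L)]
    entries <- collect_feature_entries(ft, key_pattern = "^ {1,9}(\\S+) +(\\S.*)$",
                                       cont_pattern = "^ {10,}(\\S.*)$")
  }
  seq_lines <- lines[(origin_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record has an empty sequence")
  new_genome(id, sequence, topology, features_from_table(entries))
}

parse_embl_lines <- function(lines) {
  id_i <- grep("^ID ", lines)
  if (length(id_i) == 0L) stop("not an EMBL file: no ID line")
  id_parts <- strsplit(trimws(sub("^ID +", "", lines[id_i[1]])), " *; *")[[1]]
  id <- id_parts[1]
  topology <- if (any(tolower(id_parts) == "circular")) "circular" else "linear"

  ft_lines <- sub("^FT", "  ", lines[grepl("^FT ", lines)])
  entries <- collect_feature_entries(ft_lines,
                                     key_pattern = "^ {1,9}(\\S+) +(\\S.*)$",
                                     cont_pattern = "^ {10,}(\\S.*)$")
  sq_i <- grep("^SQ", lines)
  if (length(sq_i) == 0L) stop("EMBL record has no SQ sequence block")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[1] else length(lines) + 1L
  seq_lines <- lines[(sq_i[1] + 1L):(end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("EMBL record has an empty sequence")
  new_genome(id, sequence, topology, features_from_table(entries))
}

# Groups raw feature-table lines into entries of (key, location, qualifiers),
# joining wrapped location and qualifier continuation lines.
collect_feature_entries <- function(ft, key_pattern, cont_pattern) {
  entries <- list()
  cur <- NULL
  for (ln in ft) {
    if (!grepl("\\S", ln)) next
    km <- regmatches(ln, regexec(key_pattern, ln))[[1]]
    if (length(km) == 3L && !startsWith(trimws(ln), "/")) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      cur <- list(key = km[2], loc = km[3], quals = character())
    } else if (!is.null(cur)) {
      cm <- regmatches(ln, regexec(cont_pattern, ln))[[1]]
      if (length(cm) != 2L) next
      txt <- cm[2]
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals) == 0L) {
        cur$loc <- paste0(cur$loc, txt)      # wrapped location
      } else {
        i <- length(cur$quals)               # wrapped qualifier text
        cur$quals[i] <- paste(cur$quals[i], txt)
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  entries
}

## ---- GenBank writing ------------------------------------------------------

#' Write a genome as a GenBank flat file
#'
#' Emits the subset of the GenBank grammar that [parse_genome()] reads back
#' bit-exactly: LOCUS with length and topology, a feature table with CDS
#' entries and `locus_tag`/`gene`/`product` qualifiers, and an ORIGIN
#' block. The LOCUS date is fixed so identical genomes yield byte-identical
#' files.
#'
#' @param genome A [new_genome()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- genome_length(genome)
  out <- c(sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-1980",
                   genome$id, n, genome$topology),
           sprintf("DEFINITION  synthetic construct %s.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])   # back to 1-based
    if (f$strand[i] == -1L) loc <- sprintf("complement(%s)", loc)
    key <- if (f$kind[i] == "CDS") "CDS" else "misc_feature"
    out <- c(out, sprintf("     %-16s%s", key, loc),
             sprintf("                     /locus_tag=\"%s\"", f$locus_tag[i]))
    if (!is.na(f$gene_name[i])) {
      out <- c(out, sprintf("                     /gene=\"%s\"", f$gene_name[i]))
    }
    if (!is.na(f$product[i])) {
      out <- c(out, sprintf("                     /product=\"%s\"", f$product[i]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ---- target lists ---------------------------------------------------------

#' Read a target-gene list
#'
#' Plain text, one identifier (locus_tag or gene name) per line; `#` starts
#' a comment. Duplicates are removed with a warning.
#'
#' @param path Path to the list file.
#' @return Character vector of identifiers, classed `target_list`.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) stop("cannot read target list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  ids <- lines[nzchar(lines)]
  if (length(ids) == 0L) stop("target list ", path, " contains no identifiers")
  if (anyDuplicated(ids)) {
    warning("duplicate identifiers removed from target list: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            call. = FALSE)
    ids <- unique(ids)
  }
  structure(ids, class = "target_list")
}

#' Select design targets from a genome
#'
#' With no target list, returns every CDS feature in genomic order. With a
#' list, returns the matching CDS features in list order, matching
#' `locus_tag` first and then `gene_name`; an identifier matching no
#' feature, or a gene name matching several, is an error naming every
#' offending identifier.
#'
#' @param genome A [new_genome()] object.
#' @param targets Optional character vector / [read_target_list()] result.
#' @return `data.frame` of selected CDS features.
#' @export
select_targets <- function(genome, targets = NULL) {
  cds <- cds_features(genome)
  if (is.null(targets)) {
    return(cds[order(cds$start), , drop = FALSE])
  }
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("empty target list")
  unresolved <- character()
  ambiguous <- character()
  rows <- integer()
  for (t in targets) {
    i <- which(cds$locus_tag == t)
    if (length(i) == 0L) i <- which(!is.na(cds$gene_name) & cds$gene_name == t)
    if (length(i) == 0L) unresolved <- c(unresolved, t)
    else if (length(i) > 1L) ambiguous <- c(ambiguous, t)
    else rows <- c(rows, i)
  }
  if (length(unresolved) > 0L || length(ambiguous) > 0L) {
    msg <- character()
    if (length(unresolved) > 0L) {
      msg <- c(msg, paste0("unresolved identifier(s): ",
                           paste(unresolved, collapse = ", ")))
    }
    if (length(ambiguous) > 0L) {
      msg <- c(msg, paste0("ambiguous gene name(s): ",
                           paste(ambiguous, collapse = ", ")))
    }
    stop(paste(msg, collapse = "; "))
  }
  out <- cds[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}
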