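#' Read a BED file
#'
#' BED coordinates are 0-based, half-open on disk; they are converted to
#' the package's 1-based, closed convention on read (`start + 1`, `end`
#' unchanged).  `track`/`browser`/comment lines are skipped.  Column 4,
#' when present, is the feature name (the identifier); column 6 the
#' strand.
#'
#' @param path BED file path (3, 4 or 6+ columns, tab-separated).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` in internal coordinates.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed BED line ", i, ": fewer than 3 columns")
    s0 <- suppressWarnings(as.numeric(f[2L]))
    e0 <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s0) || is.na(e0))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (s0 < 0) stop("malformed BED line ", i, ": negative start")
    if (e0 <= s0) stop("malformed BED line ", i, ": end must exceed start")
    data.frame(chrom = f[1L], start = s0 + 1, end = e0,
               name = if (length(f) >= 4L) f[4L] else NA_character_,
               strand = if (length(f) >= 6L && f[6L] %in% c("+", "-"))
                 f[6L] else "*",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out
}

#' Write intervals as a BED file / UCSC custom track
#'
#' Converts internal 1-based closed coordinates back to BED's 0-based
#' half-open convention (`start - 1`, `end` unchanged).  With a
#' `track_name`, a UCSC custom-track header line is emitted so the file
#' can be loaded directly in the genome browser.
#'
#' @param tab Data frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `strand`.
#' @param path Output path.
#' @param track_name,description Optional UCSC track line attributes.
#' @return The path, invisibly.
#' @export
write_bed <- function(tab, path, track_name = NULL, description = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track name="%s" description="%s"', track_name,
                       if (is.null(description)) track_name else description),
               con)
  if (nrow(tab) > 0L) {
    name <- if ("name" %in% names(tab)) as.character(tab$name)
            else sprintf("%s:%g-%g", tab$chrom, tab$start, tab$end)
    has_strand <- "strand" %in% names(tab) && any(tab$strand %in% c("+", "-"))
    lines <- if (has_strand) {
      strand <- ifelse(tab$strand %in% c("+", "-"), tab$strand, "+")
      sprintf("%s\t%d\t%d\t%s\t0\t%s", tab$chrom, as.integer(tab$start - 1),
              as.integer(tab$end), name, strand)
    } else {
      sprintf("%s\t%d\t%d\t%s", tab$chrom, as.integer(tab$start - 1),
              as.integer(tab$end), name)
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_bed
#' @param report A `conversion_report`; one BED record is written per hit,
#'   named by the target identifier.
#' @export
write_track <- function(report, path, track_name = "conversion",
                        description = NULL) {
  stopifnot(inherits(report, "conversion_report"))
  h <- report$hits
  tab <- data.frame(chrom = h$target_chrom, start = h$target_start,
                    end = h$target_end, name = h$target_id,
                    stringsAsFactors = FALSE)
  write_bed(tab, path, track_name = track_name, description = description)
}

#' Read / write FASTA
#'
#' Thin wrappers over `Biostrings` returning plain named character
#' vectors for convenience.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs Named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read an identifier list
#'
#' One identifier per line; surrounding whitespace is trimmed, empty and
#' `#`-comment lines are dropped, input order is preserved.
#'
#' @param path File path.
#' @return Character vector.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read exon-union records from GFF3
#'
#' Parses a GFF3 file (1-based closed coordinates, passed through
#' unchanged), keeps `feature`-type rows and groups them by their
#' `Parent` attribute into one `exon_union` [id_record()] per parent.
#' An exon naming several parents contributes to each of them.
#'
#' @param path GFF3 file path.
#' @param namespace Namespace for the resulting records.
#' @param feature Feature type to collect (default `"exon"`).
#' @return List of [id_record()]s.
#' @export
read_gff3_exons <- function(path, namespace, feature = "exon") {
  g <- rtracklayer::readGFF(path)
  g <- g[g$type == feature, , drop = FALSE]
  if (nrow(g) == 0L) return(list())
  parents <- g$Parent
  rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    pv <- unlist(parents[i])
    if (length(pv) == 0L)
      stop("exon without a Parent attribute in ", path)
    data.frame(parent = pv, chrom = as.character(g$seqid[i]),
               start = g$start[i], end = g$end[i],
               strand = as.character(g$strand[i]),
               stringsAsFactors = FALSE)
  }))
  lapply(unique(rows$parent), function(p) {
    iv <- rows[rows$parent == p, c("chrom", "start", "end", "strand")]
    id_record(p, namespace, iv, mode = "exon_union")
  })
}

#' Write / read a conversion table
#'
#' The hit table of a `conversion_report` as TSV with fixed column order
#' `query_id`, `query_namespace`, `query_locus`, `target_namespace`,
#' `target_id`, `target_locus`, `overlap_bases`, `gap_bases`, where a
#' locus is formatted `chrom:start-end` in 1-based closed coordinates.
#'
#' @param report A `conversion_report`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_conversion_tsv <- function(report, path) {
  stopifnot(inherits(report, "conversion_report"))
  h <- report$hits
  out <- data.frame(query_id = h$query_id,
                    query_namespace = h$query_namespace,
                    query_locus = sprintf("%s:%g-%g", h$query_chrom,
                                          h$query_start, h$query_end),
                    target_namespace = h$target_namespace,
                    target_id = h$target_id,
                    target_locus = sprintf("%s:%g-%g", h$target_chrom,
                                           h$target_start, h$target_end),
                    overlap_bases = h$overlap_bases,
                    gap_bases = h$gap_bases, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conversion_tsv
#' @export
write_unconverted_tsv <- function(report, path) {
  stopifnot(inherits(report, "conversion_report"))
  utils::write.table(report$unconverted, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_conversion_tsv
#' @export
read_conversion_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(query_id = "character",
                                   target_id = "character"))
}
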