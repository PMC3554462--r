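empty_hits <- function() {
  data.frame(query_id = character(0), query_namespace = character(0),
             query_chrom = character(0), query_start = numeric(0),
             query_end = numeric(0), target_namespace = character(0),
             target_id = character(0), target_chrom = character(0),
             target_start = numeric(0), target_end = numeric(0),
             overlap_bases = numeric(0), gap_bases = numeric(0),
             stringsAsFactors = FALSE)
}

conversion_report <- function(hits, unconverted) {
  structure(list(hits = hits, unconverted = unconverted),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("conversion_report: %d hit(s) for %d converted quer%s; %d unconverted\n",
              nrow(x$hits), length(unique(x$hits$query_id)),
              if (length(unique(x$hits$query_id)) == 1L) "y" else "ies",
              nrow(x$unconverted)))
  invisible(x)
}

unconverted_row <- function(query_id, reason) {
  data.frame(query_id = query_id, reason = reason, stringsAsFactors = FALSE)
}

# Query every target namespace with one interval; returns hit rows.
convert_one_interval <- function(reg, query_id, query_ns, query, target_ns, p) {
  out <- lapply(target_ns, function(ns) {
    rows <- query_namespace(reg, ns, query, p)
    if (nrow(rows) == 0L) return(NULL)
    data.frame(query_id = query_id, query_namespace = query_ns,
               query_chrom = query$chrom, query_start = query$start,
               query_end = query$end, target_namespace = ns,
               target_id = rows$subject_id, target_chrom = rows$chrom,
               target_start = rows$start, target_end = rows$end,
               overlap_bases = rows$overlap_bases, gap_bases = rows$gap_bases,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) empty_hits() else out
}

#' Convert a list of identifiers to target namespaces
#'
#' Two-step absolute conversion: each query id is resolved to its genomic
#' intervals (step 1), then every target namespace's interval trees are
#' queried for identifiers whose intervals qualify under `p` (step 2).
#' With `source_ns = "auto"` the source namespace(s) are determined by
#' [lookup_identifier_types()]; an id found in several namespaces is
#' converted from all of them, with hits tagged by `query_namespace`.
#'
#' Every input id lands either in `hits` or in `unconverted` (reason
#' `no_coordinates` when it resolves to no interval, `no_overlap` when its
#' intervals hit nothing in any target namespace).
#'
#' @param reg An [registry()].
#' @param ids Character vector of query identifiers.
#' @param source_ns `"auto"` or a namespace name.
#' @param target_ns Character vector of target namespaces (must exist).
#' @param p An [overlap_params()].
#' @return A `conversion_report`: list with data frames `hits` and
#'   `unconverted`.
#' @export
convert_ids <- function(reg, ids, source_ns = "auto", target_ns,
                        p = overlap_params()) {
  stopifnot(inherits(reg, "id_registry"), inherits(p, "overlap_params"))
  check_target_ns(reg, target_ns)
  ids <- as.character(ids)
  hits <- list(); unconv <- list()
  for (id in ids) {
    nss <- if (identical(source_ns, "auto")) {
      lookup_identifier_types(reg, id)[[1L]]
    } else {
      if (is.null(reg$records[[source_ns]][[id]])) character(0) else source_ns
    }
    if (length(nss) == 0L) {
      unconv[[id]] <- unconverted_row(id, "no_coordinates")
      next
    }
    idhits <- list()
    for (ns in nss) {
      rec <- get_record(reg, id, ns)
      qivs <- if (rec$mode == "span") rec$intervals else record_span(rec)
      for (i in seq_len(nrow(qivs))) {
        q <- genomic_interval(qivs$chrom[i], qivs$start[i], qivs$end[i])
        idhits[[length(idhits) + 1L]] <-
          convert_one_interval(reg, id, ns, q, target_ns, p)
      }
    }
    idhits <- do.call(rbind, idhits)
    idhits <- unique(idhits)
    if (nrow(idhits) == 0L) {
      unconv[[id]] <- unconverted_row(id, "no_overlap")
    } else {
      hits[[id]] <- idhits
    }
  }
  finish_report(hits, unconv)
}

check_target_ns <- function(reg, target_ns) {
  stopifnot(is.character(target_ns), length(target_ns) >= 1L)
  for (ns in target_ns)
    if (is.null(reg$records[[ns]]))
      stop("unknown target namespace '", ns, "'")
}

finish_report <- function(hits, unconv) {
  h <- do.call(rbind, unname(hits))
  if (is.null(h)) h <- empty_hits()
  rownames(h) <- NULL
  u <- do.call(rbind, unname(unconv))
  if (is.null(u)) u <- unconverted_row(character(0), character(0))
  rownames(u) <- NULL
  conversion_report(h, u)
}

#' Convert genomic intervals to target namespaces
#'
#' Step 2 of absolute conversion alone: query intervals are matched
#' directly against the target namespaces' interval trees.
#'
#' @param reg An [registry()].
#' @param intervals A data frame with columns `chrom`, `start`, `end`
#'   (optional `name` used as query id), or a list of `genomic_interval`s.
#' @param target_ns Character vector of target namespaces.
#' @param p An [overlap_params()].
#' @return A `conversion_report`.
#' @export
convert_intervals <- function(reg, intervals, target_ns, p = overlap_params()) {
  stopifnot(inherits(reg, "id_registry"), inherits(p, "overlap_params"))
  check_target_ns(reg, target_ns)
  if (is.data.frame(intervals)) {
    df <- intervals
    if (!"name" %in% names(df))
      df$name <- sprintf("%s:%g-%g", df$chrom, df$start, df$end)
  } else {
    if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
    df <- do.call(rbind, lapply(intervals, function(g) {
      g <- as_interval(g)
      data.frame(chrom = g$chrom, start = g$start, end = g$end,
                 name = sprintf("%s:%g-%g", g$chrom, g$start, g$end),
                 stringsAsFactors = FALSE)
    }))
  }
  hits <- list(); unconv <- list()
  for (i in seq_len(nrow(df))) {
    q <- genomic_interval(df$chrom[i], df$start[i], df$end[i])
    qid <- as.character(df$name[i])
    rows <- convert_one_interval(reg, qid, NA_character_, q, target_ns, p)
    if (nrow(rows) == 0L) {
      unconv[[length(unconv) + 1L]] <- unconverted_row(qid, "no_overlap")
    } else {
      hits[[length(hits) + 1L]] <- rows
    }
  }
  finish_report(hits, unconv)
}

#' Map a short sequence to a genome with bounded mismatches
#'
#' Ungapped alignment of a read (and its reverse complement) against
#' every chromosome, reporting genomic intervals of placements with at
#' most `max_mismatch` mismatching bases.  Minus-strand placements are
#' reported in forward-strand coordinates with `strand = "-"`.  `N` in a
#' read never matches a genome base, so each `N` costs one mismatch.
#'
#' Report modes: `"all"` keeps every placement; `"all_best"` (default)
#' keeps all placements with the smallest observed mismatch count;
#' `"k"` keeps up to `k` placements in canonical order (chrom, start,
#' `+` before `-`); `"k_best"` keeps up to `k` of the best stratum.
#' If `suppress_more_than >= 0` and the read's total number of valid
#' placements exceeds that value, the read is suppressed: an empty result
#' is returned with attribute `suppressed = TRUE` (repeat masking).  The
#' comparison is strictly-greater-than: a read with exactly
#' `suppress_more_than` placements is still reported.
#'
#' @param genome A named `DNAStringSet`, a named character vector of
#'   chromosome sequences, or a FASTA path.
#' @param read Sequence string over `A/C/G/T/N` (case-insensitive).
#' @param max_mismatch Integer 0..3 (0 default).
#' @param report_mode `"all_best"`, `"all"`, `"k"`, `"k_best"`.
#' @param k Placement cap for the `"k"` modes.
#' @param suppress_more_than Multimap cutoff; `-1` (default) disables it.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `mismatches`, attribute `suppressed` (logical) and `total_placements`.
#' @export
map_sequence <- function(genome, read, max_mismatch = 0,
                         report_mode = c("all_best", "all", "k", "k_best"),
                         k = 1, suppress_more_than = -1) {
  report_mode <- match.arg(report_mode)
  genome <- as_genome(genome)
  read <- toupper(read)
  if (!grepl("^[ACGTN]+$", read))
    stop("read contains characters outside A/C/G/T/N")
  if (!max_mismatch %in% 0:3) stop("'max_mismatch' must be between 0 and 3")
  fwd <- Biostrings::DNAString(read)
  rev <- Biostrings::reverseComplement(fwd)
  hits <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    if (length(fwd) > length(subj)) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fwd else rev
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m)
      nmm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                         with.indels = FALSE, fixed = TRUE)
      hits[[length(hits) + 1L]] <-
        data.frame(chrom = chrom, start = st, end = Biostrings::end(m),
                   strand = strand, mismatches = as.integer(nmm),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  # canonical order: chromosome, start, '+' before '-'
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  total <- nrow(out)
  if (suppress_more_than >= 0 && total > suppress_more_than) {
    out <- out[0L, , drop = FALSE]
    attr(out, "suppressed") <- TRUE
    attr(out, "total_placements") <- total
    return(out)
  }
  if (total > 0L) {
    out <- switch(report_mode,
      all = out,
      all_best = out[out$mismatches == min(out$mismatches), , drop = FALSE],
      k = utils::head(out, k),
      k_best = utils::head(out[out$mismatches == min(out$mismatches), ,
                               drop = FALSE], k))
    rownames(out) <- NULL
  }
  attr(out, "suppressed") <- FALSE
  attr(out, "total_placements") <- total
  out
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("'genome' must be a DNAStringSet, a named character vector, or a FASTA path")
}

as_reads <- function(reads) {
  if (inherits(reads, "DNAStringSet"))
    return(stats::setNames(as.character(reads), names(reads)))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    ss <- Biostrings::readDNAStringSet(reads)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  if (is.character(reads) && !is.null(names(reads))) return(reads)
  stop("'reads' must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Convert sequences to target identifiers
#'
#' Maps each read to the genome with [map_sequence()], then converts the
#' resulting intervals with [convert_intervals()].  Suppressed multimap
#' reads are reported as `unconverted` with reason `suppressed_multimap`;
#' unmappable reads with `no_coordinates`.
#'
#' @inheritParams map_sequence
#' @inheritParams convert_intervals
#' @param reads Named character vector, `DNAStringSet`, or FASTA path.
#' @return A `conversion_report`.
#' @export
convert_sequences <- function(reg, genome, reads, target_ns,
                              p = overlap_params(), max_mismatch = 0,
                              report_mode = "all_best", k = 1,
                              suppress_more_than = -1) {
  stopifnot(inherits(reg, "id_registry"))
  check_target_ns(reg, target_ns)
  genome <- as_genome(genome)
  reads <- as_reads(reads)
  hits <- list(); unconv <- list()
  for (nm in names(reads)) {
    m <- map_sequence(genome, reads[[nm]], max_mismatch = max_mismatch,
                      report_mode = report_mode, k = k,
                      suppress_more_than = suppress_more_than)
    if (isTRUE(attr(m, "suppressed"))) {
      unconv[[length(unconv) + 1L]] <- unconverted_row(nm, "suppressed_multimap")
      next
    }
    if (nrow(m) == 0L) {
      unconv[[length(unconv) + 1L]] <- unconverted_row(nm, "no_coordinates")
      next
    }
    m$name <- nm
    rep1 <- convert_intervals(reg, m, target_ns, p)
    if (nrow(rep1$hits) == 0L) {
      unconv[[length(unconv) + 1L]] <- unconverted_row(nm, "no_overlap")
    } else {
      hits[[length(hits) + 1L]] <- unique(rep1$hits)
    }
  }
  finish_report(hits, unconv)
}

#' Fragment a sequence into overlapping windows
#'
#' Cuts a sequence into `window`-base fragments starting every `step`
#' bases (so consecutive fragments overlap by `window - step`), naming
#' each fragment by appending `_1`, `_2`, ... to the sequence name in
#' order of appearance.  Trailing stretches shorter than a full window
#' are dropped.
#'
#' @param name Sequence name.
#' @param seq Sequence string.
#' @param window Fragment length (default 50).
#' @param step Offset between fragment starts (default 25).
#' @return Data frame with columns `name` and `seq`; zero rows when the
#'   sequence is shorter than one window.
#' @examples
#' fragment_sequence("g", strrep("ACGT", 25))  # 3 fragments of 100 bases
#' @export
fragment_sequence <- function(name, seq, window = 50, step = 25) {
  stopifnot(window >= 1, step >= 1, step <= window)
  len <- nchar(seq)
  starts <- seq(1, len, by = step)
  starts <- starts[starts + window - 1 <= len]
  if (length(starts) == 0L)
    return(data.frame(name = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  data.frame(name = paste0(name, "_", seq_along(starts)),
             seq = substring(seq, starts, starts + window - 1),
             stringsAsFactors = FALSE)
}

#' Keep alignments near the maximal score
#'
#' Retains alignments whose score is at least `(1 - fraction)` times the
#' maximal observed score (default: within 5\% of the maximum).
#'
#' @param alignments Data frame with a `score` column, or a numeric
#'   vector of scores.
#' @param fraction Fraction below the maximum to tolerate, in `[0, 1]`.
#' @return The qualifying subset, same shape as the input.
#' @examples
#' filter_best_fraction(c(100, 96, 94))  # keeps 100 and 96
#' @export
filter_best_fraction <- function(alignments, fraction = 0.05) {
  stopifnot(fraction >= 0, fraction <= 1)
  scores <- if (is.data.frame(alignments)) alignments$score else alignments
  if (length(scores) == 0L) return(alignments)
  if (any(scores < 0)) stop("alignment scores must be >= 0")
  keep <- scores >= (1 - fraction) * max(scores)
  if (is.data.frame(alignments)) alignments[keep, , drop = FALSE] else scores[keep]
}
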