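#' Genomic interval
#'
#' A located span on a named chromosome in 1-based, fully closed
#' coordinates: both `start` and `end` are included in the span, so an
#' interval of width 1 has `start == end`.  BED input (0-based, half-open)
#' is converted to this convention at the I/O boundary by [read_bed()];
#' GFF3 coordinates pass through unchanged.
#'
#' @param chrom Chromosome (or any reference sequence) name.
#' @param start,end Integer positions, `1 <= start <= end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unspecified).
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 100, 149)
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) || !nzchar(chrom))
    stop("'chrom' must be a single non-empty string")
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("'start' and 'end' must be single numbers")
  if (start < 1) stop("'start' must be >= 1 (coordinates are 1-based)")
  if (end < start) stop("'end' must be >= 'start'")
  if (start != floor(start) || end != floor(end))
    stop("'start' and 'end' must be whole numbers")
  strand <- match.arg(strand, c("+", "-", "*"))
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d%s> width %d\n", x$chrom, x$start, x$end,
              if (x$strand == "*") "" else paste0("(", x$strand, ")"),
              interval_width(x)))
  invisible(x)
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_width <- function(x) x$end - x$start + 1

as_interval <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x)))
    return(genomic_interval(x$chrom, x$start, x$end,
                            if (is.null(x$strand)) "*" else x$strand))
  stop("cannot interpret object as a genomic interval")
}

check_same_chrom <- function(a, b) {
  if (a$chrom != b$chrom)
    stop(sprintf("intervals on different chromosomes ('%s' vs '%s') are not comparable",
                 a$chrom, b$chrom))
}

#' Signed overlap width of two intervals
#'
#' Width of the intersection of two closed intervals on the same
#' chromosome.  Positive values count shared bases; 0 means the intervals
#' are adjacent (no shared base, no base between them); negative values
#' have magnitude equal to the number of bases strictly between the spans.
#'
#' @param a,b `genomic_interval` objects on the same chromosome.
#' @return Integer, `min(a$end, b$end) - max(a$start, b$start) + 1`.
#' @examples
#' overlap_width(genomic_interval("c", 1, 10), genomic_interval("c", 5, 9))  # 5
#' overlap_width(genomic_interval("c", 1, 5), genomic_interval("c", 8, 9))   # -2
#' @export
overlap_width <- function(a, b) {
  a <- as_interval(a); b <- as_interval(b)
  check_same_chrom(a, b)
  min(a$end, b$end) - max(a$start, b$start) + 1
}

#' Gap between two intervals
#'
#' Number of bases strictly separating two intervals on the same
#' chromosome; 0 when they overlap or are adjacent.
#'
#' @inheritParams overlap_width
#' @return Non-negative integer.
#' @export
gap <- function(a, b) {
  max(0, -overlap_width(a, b))
}

#' Overlap query parameters
#'
#' The contract for an overlap query.  `type` selects the positional rule:
#' `"any"` accepts any overlap, `"start"`/`"end"` additionally require the
#' query's start/end to match the subject's (within `maxgap`), `"equal"`
#' requires both ends to match, and `"within"` requires the query to lie
#' wholly inside the subject.  `maxgap` is the largest tolerated
#' separation (for `"any"`) or coordinate slack (for the other types);
#' `minoverlap` is the smallest number of shared bases that counts as an
#' overlap; `select` reduces the hit list to all, the first, the last, or
#' one arbitrary (deterministically chosen) qualifying subject.
#'
#' The combined rule implemented by [qualifies()] is: for `type = "any"`,
#' a pair qualifies iff `overlap_width >= minoverlap` or
#' (`maxgap > 0` and `gap <= maxgap`); for `"start"`,
#' `|q$start - s$start| <= maxgap` and `overlap_width >= minoverlap`
#' (`"end"` symmetric on ends, `"equal"` both); for `"within"`,
#' `q$start >= s$start - maxgap`, `q$end <= s$end + maxgap` and
#' `overlap_width >= minoverlap`.
#'
#' @param type One of `"any"`, `"start"`, `"end"`, `"equal"`, `"within"`.
#' @param maxgap Integer `>= 0`; default 0.
#' @param minoverlap Integer `>= 1`; default 1.
#' @param select One of `"all"`, `"first"`, `"last"`, `"arbitrary"`.
#' @return An object of class `overlap_params`.
#' @export
overlap_params <- function(type = c("any", "start", "end", "equal", "within"),
                           maxgap = 0, minoverlap = 1,
                           select = c("all", "first", "last", "arbitrary")) {
  type <- match.arg(type)
  select <- match.arg(select)
  maxgap <- as.numeric(maxgap); minoverlap <- as.numeric(minoverlap)
  if (length(maxgap) != 1L || is.na(maxgap) || maxgap < 0 || maxgap != floor(maxgap))
    stop("'maxgap' must be a single integer >= 0")
  if (length(minoverlap) != 1L || is.na(minoverlap) || minoverlap < 1 ||
      minoverlap != floor(minoverlap))
    stop("'minoverlap' must be a single integer >= 1")
  structure(list(type = type, maxgap = maxgap, minoverlap = minoverlap,
                 select = select),
            class = "overlap_params")
}

#' @export
print.overlap_params <- function(x, ...) {
  cat(sprintf("overlap_params(type=%s, maxgap=%d, minoverlap=%d, select=%s)\n",
              x$type, x$maxgap, x$minoverlap, x$select))
  invisible(x)
}

# Vectorized predicate core: scalar query against subject coordinate
# vectors.  All user-facing entry points funnel through here so the
# overlap semantics live in exactly one place.
qualifies_core <- function(qs, qe, ss, se, type, maxgap, minoverlap) {
  ow <- pmin(qe, se) - pmax(qs, ss) + 1
  switch(type,
    any = ow >= minoverlap | (maxgap > 0 & pmax(0, -ow) <= maxgap),
    start = abs(qs - ss) <= maxgap & ow >= minoverlap,
    end = abs(qe - se) <= maxgap & ow >= minoverlap,
    equal = abs(qs - ss) <= maxgap & abs(qe - se) <= maxgap & ow >= minoverlap,
    within = qs >= ss - maxgap & qe <= se + maxgap & ow >= minoverlap,
    stop("unknown overlap type: ", type))
}

#' Does a query interval qualify as overlapping a subject?
#'
#' Applies the parameterized overlap rule described in [overlap_params()].
#' Strand is ignored unless `strict_strand = TRUE`, in which case both
#' intervals must carry the same specified strand.
#'
#' @param query,subject `genomic_interval` objects on the same chromosome.
#' @param p An [overlap_params()] object.
#' @param strict_strand Require equal strands (default `FALSE`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' p <- overlap_params("within")
#' qualifies(genomic_interval("c", 3, 7), genomic_interval("c", 2, 7), p)  # TRUE
#' @export
qualifies <- function(query, subject, p = overlap_params(),
                      strict_strand = FALSE) {
  query <- as_interval(query); subject <- as_interval(subject)
  check_same_chrom(query, subject)
  stopifnot(inherits(p, "overlap_params"))
  if (strict_strand && (query$strand == "*" || query$strand != subject$strand))
    return(FALSE)
  qualifies_core(query$start, query$end, subject$start, subject$end,
                 p$type, p$maxgap, p$minoverlap)
}

# Deterministic index choice for select = "arbitrary": a fixed hash of the
# query coordinates so repeated runs agree without touching R's RNG.
arbitrary_pick <- function(n, qs, qe) {
  if (n <= 1L) return(n)
  ((qs * 31 + qe * 17) %% n) + 1L
}

# Reduce canonical-row-ordered hits according to 'select'.
apply_select <- function(rows, select, qs, qe) {
  n <- nrow(rows)
  if (n == 0L || select == "all") return(rows)
  i <- switch(select,
              first = 1L,
              last = n,
              arbitrary = arbitrary_pick(n, qs, qe))
  rows[i, , drop = FALSE]
}
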