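# Payload strings stored in the trees encode (identifier, interval ordinal)
# with an unprintable separator so identifier order drives payload order.
PAYLOAD_SEP <- "\x1f"

encode_payload <- function(id, ordinal) paste(id, ordinal, sep = PAYLOAD_SEP)

decode_payload_ids <- function(payload) {
  vapply(strsplit(payload, PAYLOAD_SEP, fixed = TRUE), `[[`, "", 1L)
}

#' Identifier record
#'
#' Binds one identifier in a namespace to its genomic intervals.  In
#' `"span"` mode each interval is an independent placement of the
#' identifier (a multi-mapped probe has several).  In `"exon_union"` mode
#' the intervals are the exons of a single transcript-like feature: they
#' must share a chromosome and strand, and an intronic query does not
#' touch the record.
#'
#' @param id Identifier string.
#' @param namespace Identifier-type name (free-form: `"entrez"`,
#'   `"refseq"`, `"affy_probe"`, or any user-defined domain).
#' @param intervals Data frame with columns `chrom`, `start`, `end` and
#'   optionally `strand`; at least one row.
#' @param mode `"span"` or `"exon_union"`.
#' @return An object of class `id_record`.
#' @export
id_record <- function(id, namespace, intervals,
                      mode = c("span", "exon_union")) {
  mode <- match.arg(mode)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(namespace), length(namespace) == 1L, nzchar(namespace),
            is.data.frame(intervals), nrow(intervals) >= 1L,
            all(c("chrom", "start", "end") %in% names(intervals)))
  iv <- data.frame(chrom = as.character(intervals$chrom),
                   start = as.numeric(intervals$start),
                   end = as.numeric(intervals$end),
                   strand = if ("strand" %in% names(intervals))
                     as.character(intervals$strand) else "*",
                   stringsAsFactors = FALSE)
  if (any(iv$start < 1 | iv$end < iv$start))
    stop("invalid interval coordinates for id '", id, "'")
  if (mode == "exon_union") {
    if (length(unique(iv$chrom)) != 1L || length(unique(iv$strand)) != 1L)
      stop("exon_union record '", id,
           "' must have all intervals on one chromosome and strand")
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  }
  rownames(iv) <- NULL
  structure(list(id = id, namespace = namespace, intervals = iv, mode = mode),
            class = "id_record")
}

record_span <- function(rec) {
  iv <- rec$intervals
  data.frame(chrom = iv$chrom[1L], start = min(iv$start), end = max(iv$end),
             strand = iv$strand[1L], stringsAsFactors = FALSE)
}

#' Multi-namespace identifier registry
#'
#' Stores identifier records per namespace, maintains one interval tree
#' per (namespace, chromosome), and an exact-string index from identifier
#' to the namespaces containing it (the batch "lookup" store).
#'
#' @return An object of class `id_registry` (environment, modified in place).
#' @seealso [register()], [lookup_identifier_types()], [intervals_for_id()]
#' @export
registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$records <- new.env(parent = emptyenv())   # ns -> env(id -> id_record)
  reg$trees <- new.env(parent = emptyenv())     # "ns\x1fchrom" -> interval_tree
  reg$id_index <- new.env(parent = emptyenv())  # id -> character(namespaces)
  class(reg) <- "id_registry"
  reg
}

#' @export
print.id_registry <- function(x, ...) {
  ns <- registry_namespaces(x)
  cat(sprintf("id_registry with %d namespace(s)\n", length(ns)))
  for (n in ns)
    cat(sprintf("  %s: %d identifier(s)\n", n, length(ls(x$records[[n]]))))
  invisible(x)
}

#' @rdname registry
#' @param reg An `id_registry`.
#' @export
registry_namespaces <- function(reg) sort(ls(reg$records))

tree_key <- function(ns, chrom) paste(ns, chrom, sep = PAYLOAD_SEP)

registry_tree <- function(reg, ns, chrom, create = FALSE) {
  k <- tree_key(ns, chrom)
  t <- reg$trees[[k]]
  if (is.null(t) && create) {
    t <- interval_tree(chrom)
    reg$trees[[k]] <- t
  }
  t
}

#' Register an identifier record
#'
#' Inserts the record's intervals into the appropriate per-chromosome
#' trees (each exon separately in `exon_union` mode) and indexes the
#' identifier for type lookup.  Registering the same (namespace, id)
#' twice is an error.
#'
#' @param reg An [registry()].
#' @param rec An [id_record()].
#' @return The registry, invisibly.
#' @export
register <- function(reg, rec) {
  stopifnot(inherits(reg, "id_registry"), inherits(rec, "id_record"))
  ns <- rec$namespace
  if (is.null(reg$records[[ns]]))
    reg$records[[ns]] <- new.env(parent = emptyenv())
  if (!is.null(reg$records[[ns]][[rec$id]]))
    stop("duplicate registration of id '", rec$id, "' in namespace '", ns, "'")
  reg$records[[ns]][[rec$id]] <- rec
  iv <- rec$intervals
  for (i in seq_len(nrow(iv))) {
    t <- registry_tree(reg, ns, iv$chrom[i], create = TRUE)
    it_insert(t, start = iv$start[i], end = iv$end[i],
              payload = encode_payload(rec$id, i))
  }
  reg$id_index[[rec$id]] <- sort(unique(c(reg$id_index[[rec$id]], ns)))
  invisible(reg)
}

#' Register a table of named intervals
#'
#' Convenience bulk form of [register()]: rows sharing a `name` become one
#' record (placements in `"span"` mode, exons in `"exon_union"` mode).
#'
#' @param reg An [registry()].
#' @param tab Data frame with columns `chrom`, `start`, `end`, `name` and
#'   optionally `strand`.
#' @param namespace Namespace to register into.
#' @param mode Record representation mode.
#' @return The registry, invisibly.
#' @export
register_table <- function(reg, tab, namespace, mode = "span") {
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(tab)))
  for (id in unique(as.character(tab$name))) {
    rows <- tab[tab$name == id, , drop = FALSE]
    register(reg, id_record(id, namespace, rows, mode = mode))
  }
  invisible(reg)
}

#' Classify a mixed list of identifiers by namespace
#'
#' @param reg An [registry()].
#' @param ids Character vector of identifiers.
#' @return A named list, in input order, mapping each id to the (possibly
#'   empty) character vector of namespaces containing it.
#' @export
lookup_identifier_types <- function(reg, ids) {
  stopifnot(inherits(reg, "id_registry"))
  out <- lapply(as.character(ids), function(id) {
    v <- reg$id_index[[id]]
    if (is.null(v)) character(0) else v
  })
  names(out) <- as.character(ids)
  out
}

#' Intervals registered for an identifier
#'
#' @param reg An [registry()].
#' @param id Identifier string.
#' @param namespace Namespace the id is registered in.
#' @return The record's interval data frame.
#' @export
intervals_for_id <- function(reg, id, namespace) {
  rec <- get_record(reg, id, namespace)
  rec$intervals
}

get_record <- function(reg, id, namespace) {
  stopifnot(inherits(reg, "id_registry"))
  nsenv <- reg$records[[namespace]]
  if (is.null(nsenv))
    stop("not found: namespace '", namespace, "' is not registered")
  rec <- nsenv[[id]]
  if (is.null(rec))
    stop("not found: id '", id, "' is not registered in namespace '",
         namespace, "'")
  rec
}

# Query one namespace with a scalar query interval.  Candidate intervals
# come from the (namespace, chromosome) tree; candidates are grouped by
# identifier and the record-mode-aware rule is applied:
#   span:        each placement judged by qualifies(); the qualifying
#                placement with the widest overlap represents the id.
#   exon_union:  minoverlap is met by the SUM of per-exon intersection
#                widths; positional conditions (start/end/equal/within)
#                are judged against the record span; for type "any" with
#                maxgap > 0 the smallest per-exon gap may qualify instead.
# Returns one row per qualifying id in canonical (chrom, span start,
# span end, id) order, already reduced by p$select.
query_namespace <- function(reg, ns, query, p) {
  query <- as_interval(query)
  if (is.null(reg$records[[ns]]))
    stop("unknown target namespace '", ns, "'")
  empty <- data.frame(subject_id = character(0), subject_namespace = character(0),
                      chrom = character(0), start = numeric(0), end = numeric(0),
                      overlap_bases = numeric(0), gap_bases = numeric(0),
                      stringsAsFactors = FALSE)
  t <- registry_tree(reg, ns, query$chrom)
  if (is.null(t)) return(empty)
  cand <- tree_window(t, query$start - p$maxgap - 1, query$end + p$maxgap + 1)
  if (nrow(cand) == 0L) return(empty)
  ids <- unique(decode_payload_ids(cand$payload))
  rows <- lapply(ids, function(id) {
    rec <- get_record(reg, id, ns)
    iv <- rec$intervals
    onchrom <- iv$chrom == query$chrom
    iv <- iv[onchrom, , drop = FALSE]
    if (nrow(iv) == 0L) return(NULL)
    ow <- pmin(query$end, iv$end) - pmax(query$start, iv$start) + 1
    gp <- pmax(0, -ow)
    if (rec$mode == "span") {
      ok <- qualifies_core(query$start, query$end, iv$start, iv$end,
                           p$type, p$maxgap, p$minoverlap)
      if (!any(ok)) return(NULL)
      best <- which(ok)[order(-ow[ok], iv$start[ok], iv$end[ok])][1L]
      data.frame(subject_id = id, subject_namespace = ns,
                 chrom = iv$chrom[best], start = iv$start[best],
                 end = iv$end[best],
                 overlap_bases = max(0, ow[best]), gap_bases = gp[best],
                 stringsAsFactors = FALSE)
    } else {
      sp <- record_span(rec)
      sum_ov <- sum(pmax(0, ow))
      min_gap <- if (any(ow > 0)) 0 else min(gp)
      ok <- if (p$type == "any") {
        sum_ov >= p$minoverlap || (p$maxgap > 0 && min_gap <= p$maxgap)
      } else {
        pos_ok <- switch(p$type,
          start = abs(query$start - sp$start) <= p$maxgap,
          end = abs(query$end - sp$end) <= p$maxgap,
          equal = abs(query$start - sp$start) <= p$maxgap &&
                  abs(query$end - sp$end) <= p$maxgap,
          within = query$start >= sp$start - p$maxgap &&
                   query$end <= sp$end + p$maxgap)
        pos_ok && sum_ov >= p$minoverlap
      }
      if (!ok) return(NULL)
      data.frame(subject_id = id, subject_namespace = ns,
                 chrom = sp$chrom, start = sp$start, end = sp$end,
                 overlap_bases = sum_ov, gap_bases = min_gap,
                 stringsAsFactors = FALSE)
    }
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows) || nrow(rows) == 0L) return(empty)
  rows <- rows[order(rows$chrom, rows$start, rows$end, rows$subject_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows <- apply_select(rows, p$select, query$start, query$end)
  rownames(rows) <- NULL
  rows
}

#' Consistency walk over a registry
#'
#' Verifies that the multiset of intervals stored in every namespace's
#' trees equals the multiset implied by its records, and that the id
#' index covers every registered identifier.
#'
#' @param reg An [registry()].
#' @return `TRUE` invisibly; stops on the first inconsistency.
#' @export
registry_validate <- function(reg) {
  stopifnot(inherits(reg, "id_registry"))
  for (ns in registry_namespaces(reg)) {
    want <- list()
    for (id in ls(reg$records[[ns]])) {
      rec <- reg$records[[ns]][[id]]
      if (!ns %in% reg$id_index[[id]])
        stop("id index misses '", id, "' in namespace '", ns, "'")
      iv <- rec$intervals
      want[[id]] <- sprintf("%s:%g-%g:%s", iv$chrom, iv$start, iv$end,
                            encode_payload(id, seq_len(nrow(iv))))
    }
    want <- sort(unlist(want, use.names = FALSE))
    got <- character(0)
    for (k in ls(reg$trees)) {
      parts <- strsplit(k, PAYLOAD_SEP, fixed = TRUE)[[1L]]
      if (parts[1L] != ns) next
      tab <- tree_window(reg$trees[[k]], -Inf, Inf)
      got <- c(got, sprintf("%s:%g-%g:%s", parts[2L], tab$start, tab$end,
                            tab$payload))
    }
    if (!identical(sort(got), want))
      stop("tree/record interval multisets differ in namespace '", ns, "'")
  }
  invisible(TRUE)
}

#' Build a registry from a manifest file
#'
#' The manifest is a YAML list under key `namespaces`, each entry having
#' `name`, `file` (BED or GFF3, relative paths resolved against the
#' manifest), `format` (`"bed"` or `"gff3"`), and `mode` (`"span"` or
#' `"exon_union"`; GFF3 always yields `exon_union` records grouped by
#' their `Parent` attribute).
#'
#' @param path Manifest file path.
#' @return An [registry()].
#' @export
registry_from_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$namespaces)) stop("manifest has no 'namespaces' key")
  reg <- registry()
  base <- dirname(normalizePath(path))
  for (entry in man$namespaces) {
    f <- entry$file
    if (!file.exists(f)) f <- file.path(base, entry$file)
    fmt <- if (is.null(entry$format)) "bed" else entry$format
    mode <- if (is.null(entry$mode)) "span" else entry$mode
    if (fmt == "bed") {
      register_table(reg, read_bed(f), entry$name, mode = mode)
    } else if (fmt == "gff3") {
      for (rec in read_gff3_exons(f, namespace = entry$name))
        register(reg, rec)
    } else stop("unknown annotation format '", fmt, "' in manifest")
  }
  reg
}
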