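#' Augmented interval tree for one chromosome
#'
#' A dynamic set of (interval, payload) pairs stored in a red-black tree
#' keyed by `(start, end, payload)` and augmented with the maximum interval
#' end over every subtree, so insert and delete run in `O(log2 n)` and an
#' overlap query visits `O(log2 n + k)` nodes for `k` hits.  Duplicate
#' (interval, payload) pairs may be stored and are individually
#' retrievable and deletable.
#'
#' The tree lives in compiled code behind an external pointer; it is
#' rebuilt, not serialized, across sessions (see [write_tree_tsv()]).
#'
#' @param chrom Chromosome this tree indexes.
#' @return An object of class `interval_tree`.
#' @seealso [it_insert()], [it_delete()], [search_overlaps()], [it_validate()]
#' @export
interval_tree <- function(chrom) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  t <- new.env(parent = emptyenv())
  t$ptr <- .it_create()
  t$chrom <- chrom
  class(t) <- "interval_tree"
  t
}

#' @export
length.interval_tree <- function(x) .it_size(x$ptr)

#' @export
print.interval_tree <- function(x, ...) {
  cat(sprintf("interval_tree on '%s' with %d interval(s)\n",
              x$chrom, length(x)))
  invisible(x)
}

tree_check_chrom <- function(t, chrom) {
  if (!identical(chrom, t$chrom))
    stop(sprintf("interval on '%s' does not belong to the tree for '%s'",
                 chrom, t$chrom))
}

#' Insert intervals into an interval tree
#'
#' @param t An [interval_tree()].
#' @param iv A `genomic_interval` (or `start` may be a numeric vector used
#'   together with `end`/`payload` for bulk insertion).
#' @param payload Identifier reference stored with the interval.
#' @param start,end Numeric vectors for bulk insertion when `iv` is `NULL`.
#' @param chrom Chromosome of the bulk coordinates; must match the tree.
#' @return The tree, invisibly (it is modified in place).
#' @export
it_insert <- function(t, iv = NULL, payload = "", start = NULL, end = NULL,
                      chrom = t$chrom) {
  stopifnot(inherits(t, "interval_tree"))
  if (!is.null(iv)) {
    iv <- as_interval(iv)
    tree_check_chrom(t, iv$chrom)
    .it_insert(t$ptr, iv$start, iv$end, as.character(payload))
  } else {
    tree_check_chrom(t, chrom)
    stopifnot(length(start) == length(end))
    payload <- rep_len(as.character(payload), length(start))
    if (any(start < 1 | end < start)) stop("invalid interval coordinates")
    .it_insert(t$ptr, as.numeric(start), as.numeric(end), payload)
  }
  invisible(t)
}

#' Delete a stored (interval, payload) pair
#'
#' Removes one occurrence of the exact pair; an absent pair is an error.
#'
#' @inheritParams it_insert
#' @return The tree, invisibly.
#' @export
it_delete <- function(t, iv, payload = "") {
  stopifnot(inherits(t, "interval_tree"))
  iv <- as_interval(iv)
  tree_check_chrom(t, iv$chrom)
  ok <- .it_erase(t$ptr, iv$start, iv$end, as.character(payload))
  if (!ok)
    stop(sprintf("not found: [%d,%d] payload '%s' is not stored in the tree",
                 iv$start, iv$end, payload))
  invisible(t)
}

# Raw window query: every stored interval intersecting
# [lo - 0, hi + 0] (slack already folded into lo/hi by the caller),
# in canonical (start, end, payload) order, plus the visited-node count.
tree_window <- function(t, lo, hi) {
  r <- .it_window(t$ptr, lo, hi)
  out <- data.frame(start = r$start, end = r$end, payload = r$payload,
                    stringsAsFactors = FALSE)
  attr(out, "visited") <- r$visited
  out
}

#' Overlap search in an interval tree
#'
#' Returns the stored (interval, payload) pairs that [qualifies()] accepts
#' for the query under `p`, in canonical `(start, end, payload)` order,
#' reduced according to `p$select`.  The number of tree nodes examined is
#' attached as attribute `"visited"`.
#'
#' @param t An [interval_tree()].
#' @param query A `genomic_interval` on the tree's chromosome.
#' @param p An [overlap_params()].
#' @return A data frame with columns `start`, `end`, `payload`.
#' @export
search_overlaps <- function(t, query, p = overlap_params()) {
  stopifnot(inherits(t, "interval_tree"), inherits(p, "overlap_params"))
  query <- as_interval(query)
  tree_check_chrom(t, query$chrom)
  # gap g in closed coordinates means a coordinate distance of g + 1, so
  # the candidate window carries one extra base of slack beyond maxgap
  cand <- tree_window(t, query$start - p$maxgap - 1, query$end + p$maxgap + 1)
  keep <- qualifies_core(query$start, query$end, cand$start, cand$end,
                         p$type, p$maxgap, p$minoverlap)
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- apply_select(out, p$select, query$start, query$end)
  rownames(out) <- NULL
  attr(out, "visited") <- attr(cand, "visited")
  out
}

#' Flat snapshot of tree structure
#'
#' Exposes every node with its coordinates, payload, color, children and
#' subtree max-end, for structural validation and serialization.
#'
#' @param t An [interval_tree()].
#' @return A list with a node data frame (`nodes`) and the root node id.
#' @export
it_dump <- function(t) {
  stopifnot(inherits(t, "interval_tree"))
  d <- .it_dump(t$ptr)
  nodes <- data.frame(id = d$id, start = d$start, end = d$end,
                      maxend = d$maxend, left = d$left, right = d$right,
                      parent = d$parent, red = d$red == 1L,
                      payload = d$payload, stringsAsFactors = FALSE)
  list(nodes = nodes, root = d$root)
}

#' Validate red-black and augmentation invariants
#'
#' Walks a structural snapshot of the tree and checks binary-search-tree
#' order on `(start, end, payload)`, the max-end augmentation, the
#' red-black coloring rules (black root, no red node with a red child,
#' equal black height on every root-to-nil path) and the height bound
#' `height <= 2 * log2(n + 1)`.
#'
#' @param t An [interval_tree()].
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
it_validate <- function(t) {
  d <- it_dump(t)
  nodes <- d$nodes
  n <- nrow(nodes)
  if (n != length(t)) stop("size mismatch: dump has ", n, " nodes, size is ", length(t))
  if (n == 0L) return(invisible(TRUE))
  pos <- integer(max(nodes$id))
  pos[nodes$id] <- seq_len(n)
  root <- d$root
  if (nodes$red[pos[root]]) stop("root is red")

  key <- function(i) list(nodes$start[i], nodes$end[i], nodes$payload[i])
  key_le <- function(a, b) {
    if (a[[1]] != b[[1]]) return(a[[1]] < b[[1]])
    if (a[[2]] != b[[2]]) return(a[[2]] < b[[2]])
    TRUE  # equal payloads allowed on the right spine; <= is enough
  }
  # recursive walk returning list(black_height, min_key, max_key, maxend, height)
  walk <- function(id) {
    if (id == 0L) return(list(bh = 1L, maxend = -Inf, height = 0L,
                              lo = NULL, hi = NULL))
    i <- pos[id]
    L <- walk(nodes$left[i]); R <- walk(nodes$right[i])
    if (nodes$red[i]) {
      for (ch in c(nodes$left[i], nodes$right[i]))
        if (ch != 0L && nodes$red[pos[ch]]) stop("red node ", id, " has red child")
    }
    if (L$bh != R$bh) stop("black-height mismatch at node ", id)
    k <- key(i)
    if (!is.null(L$hi) && !key_le(L$hi, k)) stop("BST order violated left of node ", id)
    if (!is.null(R$lo) && !key_le(k, R$lo)) stop("BST order violated right of node ", id)
    me <- max(nodes$end[i], L$maxend, R$maxend)
    if (me != nodes$maxend[i])
      stop("maxend stale at node ", id, ": stored ", nodes$maxend[i],
           " recomputed ", me)
    list(bh = L$bh + (!nodes$red[i]),
         maxend = me, height = 1L + max(L$height, R$height),
         lo = if (is.null(L$lo)) k else L$lo,
         hi = if (is.null(R$hi)) k else R$hi)
  }
  res <- walk(root)
  if (res$height > 2 * log2(n + 1))
    stop("height ", res$height, " exceeds red-black bound for n = ", n)
  invisible(TRUE)
}

#' Serialize / rebuild an interval tree
#'
#' A built tree is written as a flat, canonically sorted interval table
#' (TSV with columns `chrom`, `start`, `end`, `payload`); reloading
#' rebuilds the tree by insertion.
#'
#' @param t An [interval_tree()].
#' @param path File path.
#' @return `write_tree_tsv`: the path, invisibly.  `read_tree_tsv`: a new
#'   [interval_tree()].
#' @export
write_tree_tsv <- function(t, path) {
  stopifnot(inherits(t, "interval_tree"))
  tab <- tree_window(t, -Inf, Inf)
  out <- data.frame(chrom = rep.int(t$chrom, nrow(tab)),
                    start = tab$start, end = tab$end, payload = tab$payload,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_tsv
#' @export
read_tree_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "numeric", "numeric",
                                          "character"))
  if (nrow(tab) == 0L) stop("empty tree table: ", path)
  chrom <- unique(tab$chrom)
  if (length(chrom) != 1L) stop("a tree table must cover exactly one chromosome")
  t <- interval_tree(chrom)
  it_insert(t, start = tab$start, end = tab$end, payload = tab$payload)
  t
}
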