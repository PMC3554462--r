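#' Classify one conversion against its truth set
#'
#' Given the authoritative target set `Z` for a query and a converter's
#' predicted set `Y`, returns one of four labels:
#' \describe{
#'   \item{TP}{`Z` non-empty and `Z` is a subset of `Y` (the conversion
#'     recovered every annotated target).}
#'   \item{FP}{`Z` non-empty, `Y` non-empty, but `Z` is not a subset of
#'     `Y` (an incorrect conversion); or `Z` empty while `Y` is not (the
#'     converter invents targets the authority does not annotate).}
#'   \item{FN}{`Z` non-empty but `Y` empty (a missed conversion).}
#'   \item{TN}{both empty (correct absence of conversion).}
#' }
#' The four labels partition all `(Z, Y)` pairs.
#'
#' @param truth Character vector `Z` (may be empty).
#' @param predicted Character vector `Y` (may be empty).
#' @return One of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
classify_conversion <- function(truth, predicted) {
  Z <- unique(as.character(truth)); Y <- unique(as.character(predicted))
  if (length(Z) == 0L) {
    if (length(Y) == 0L) "TN" else "FP"
  } else {
    if (length(Y) == 0L) "FN"
    else if (all(Z %in% Y)) "TP"
    else "FP"
  }
}

#' Confusion counts
#'
#' @param TP,FP,FN,TN Non-negative integer tallies.
#' @return An object of class `confusion_counts`; `total_mapped` is
#'   `TP + FP`, the number of queries with a non-empty predicted set.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  v <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(v < 0) || any(v != floor(v))) stop("counts must be non-negative integers")
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 total_mapped = TP + FP),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts: TP=%d FP=%d FN=%d TN=%d (mapped %d of %d)\n",
              x$TP, x$FP, x$FN, x$TN, x$total_mapped,
              x$TP + x$FP + x$FN + x$TN))
  invisible(x)
}

#' Round half away from zero
#'
#' Fixed-precision reporting rounds halves up (2.145 -> 2.15), matching
#' conventional table formatting rather than R's round-half-to-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percent accuracy of a conversion
#'
#' `100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c A [confusion_counts()].
#' @param digits Decimal places for reporting (`NULL` for full precision).
#' @return Accuracy in percent.
#' @export
conversion_accuracy <- function(c, digits = 2) {
  stopifnot(inherits(c, "confusion_counts"))
  denom <- c$TP + c$TN + c$FP + c$FN
  if (denom == 0) stop("accuracy undefined: no evaluated queries")
  acc <- 100 * (c$TP + c$TN) / denom
  if (is.null(digits)) acc else round_half_up(acc, digits)
}

#' Derived accuracy metrics
#'
#' Sensitivity (`TPR = 100*TP/(TP+FN)`), false positive rate
#' (`FPR = 100*FP/(FP+TN)`), accuracy, false discovery rate
#' (`FDR = 100*FP/(TP+FP)`) and `F1 = 100*2*TP/(2*TP+FP+FN)`.  A metric
#' whose denominator is zero is reported as `NA` and named in the
#' `"undefined"` attribute rather than silently zeroed.
#'
#' @inheritParams conversion_accuracy
#' @return Named numeric vector `TPR`, `FPR`, `ACC`, `FDR`, `F1`.
#' @export
conversion_metrics <- function(c, digits = 2) {
  stopifnot(inherits(c, "confusion_counts"))
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  m <- c(TPR = safe(c$TP, c$TP + c$FN),
         FPR = safe(c$FP, c$FP + c$TN),
         ACC = safe(c$TP + c$TN, c$TP + c$TN + c$FP + c$FN),
         FDR = safe(c$FP, c$TP + c$FP),
         F1  = safe(2 * c$TP, 2 * c$TP + c$FP + c$FN))
  if (!is.null(digits)) m <- round_half_up(m, digits)
  attr(m, "undefined") <- names(m)[is.na(m)]
  m
}

#' Score a conversion report against a truth mapping
#'
#' For every id in `evaluated_ids`, the predicted set `Y` is the set of
#' target ids the report assigns to it and the truth set `Z` comes from
#' `truth`; each query is classified with [classify_conversion()] and the
#' tallies and derived metrics are returned.  An optional `id_filter`
#' (e.g. [filter_refseq_curated()]) is applied to both sets before
#' classification so that identifier classes outside the comparison are
#' ignored on both sides.
#'
#' @param report A `conversion_report` (or a data frame of hits with
#'   columns `query_id` and `target_id`).
#' @param truth A named list mapping query id to a character vector of
#'   truth target ids (possibly empty), e.g. from [read_truth_tsv()].
#' @param evaluated_ids Ids to score; defaults to all truth keys.
#' @param id_filter Optional function reducing a character vector of
#'   target ids to the evaluable subset.
#' @return List with elements `counts` ([confusion_counts()]), `metrics`
#'   (from [conversion_metrics()]) and `labels` (named character).
#' @export
evaluate_conversion <- function(report, truth, evaluated_ids = names(truth),
                                id_filter = NULL) {
  hits <- if (inherits(report, "conversion_report")) report$hits else report
  stopifnot(all(c("query_id", "target_id") %in% names(hits)))
  if (!all(evaluated_ids %in% names(truth)))
    stop("evaluated_ids must all be present as truth keys")
  labels <- vapply(evaluated_ids, function(id) {
    Z <- truth[[id]]
    Y <- hits$target_id[hits$query_id == id]
    if (!is.null(id_filter)) {
      Z <- id_filter(Z)
      Y <- id_filter(Y)
    }
    classify_conversion(Z, Y)
  }, "")
  names(labels) <- evaluated_ids
  cc <- confusion_counts(TP = sum(labels == "TP"), FP = sum(labels == "FP"),
                         FN = sum(labels == "FN"), TN = sum(labels == "TN"))
  list(counts = cc, metrics = conversion_metrics(cc), labels = labels)
}

#' Keep curated mRNA/RNA RefSeq identifiers
#'
#' Identifier-class filter for Entrez-to-RefSeq comparisons: keeps only
#' curated mRNA (`NM_`) and non-coding RNA (`NR_`) accessions and drops
#' everything else, in particular the computationally predicted `X*`
#' classes (`XM_`, `XR_`, `XP_`).
#'
#' @param ids Character vector of identifiers.
#' @return The curated subset.
#' @export
filter_refseq_curated <- function(ids) {
  ids <- as.character(ids)
  ids[startsWith(ids, "NM_") | startsWith(ids, "NR_")]
}

#' Read / write a truth mapping
#'
#' Two-column TSV (`query_id`, `target_id`; one row per pair, repeated
#' query ids for multi-target annotations; a query id with an empty
#' target field records an id the authority does not annotate).
#'
#' @param path File path.
#' @return A named list of character vectors.
#' @export
read_truth_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = character(0))
  stopifnot(all(c("query_id", "target_id") %in% names(tab)))
  out <- lapply(split(tab$target_id, factor(tab$query_id,
                                            levels = unique(tab$query_id))),
                function(v) v[nzchar(v)])
  out
}

#' @rdname read_truth_tsv
#' @param truth A named list of character vectors.
#' @export
write_truth_tsv <- function(truth, path) {
  rows <- lapply(names(truth), function(id) {
    v <- truth[[id]]
    data.frame(query_id = id,
               target_id = if (length(v) == 0L) "" else v,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Published conversion-accuracy benchmark counts
#'
#' The printed contingency tables of two published benchmark conversions
#' (1,000 Entrez gene ids to official gene symbols, and 1,000 Entrez gene
#' ids to curated RefSeq ids, each across ten conversion tools), shipped
#' as plain-text data.  The `TP/FP/FN/TN` columns are inputs for
#' [conversion_metrics()]; the printed metric columns allow verifying the
#' reconstructed formulas cell by cell.
#'
#' @param table `"entrez_symbol"`, `"entrez_refseq"`, or `"all"`.
#' @return Data frame with columns `table`, `tool`, `total_mapped`, `TP`,
#'   `FP`, `FN`, `TN`, `TPR`, `FPR`, `ACC`, `FDR`, `F1`.
#' @export
benchmark_counts <- function(table = c("all", "entrez_symbol", "entrez_refseq")) {
  table <- match.arg(table)
  path <- system.file("extdata", "conversion_benchmarks.tsv",
                      package = "intervalid", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (table != "all") tab <- tab[tab$table == table, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Metrics table for a set of confusion counts
#'
#' Recomputes the derived metrics for each row of counts, mirroring the
#' benchmark table layout (tool, total mapped, counts, then TPR / FPR /
#' ACC / FDR / F1 to two decimals).
#'
#' @param counts Data frame with columns `tool`, `TP`, `FP`, `FN`, `TN`.
#' @return Data frame with recomputed `total_mapped` and metric columns.
#' @export
metrics_table <- function(counts) {
  stopifnot(all(c("tool", "TP", "FP", "FN", "TN") %in% names(counts)))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    cc <- confusion_counts(counts$TP[i], counts$FP[i], counts$FN[i],
                           counts$TN[i])
    m <- conversion_metrics(cc)
    data.frame(tool = counts$tool[i], total_mapped = cc$total_mapped,
               TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
               TPR = m[["TPR"]], FPR = m[["FPR"]], ACC = m[["ACC"]],
               FDR = m[["FDR"]], F1 = m[["F1"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
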