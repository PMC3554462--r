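#' Tree-vs-linear query cost scaling
#'
#' Builds, for each database size `n`, an interval tree over `n`
#' uniformly placed fixed-width intervals and runs point queries,
#' recording the number of tree nodes examined per query (a
#' deterministic, hardware-independent cost measure) next to the `n`
#' comparisons a linear scan of the same database must spend.  On a
#' balanced augmented tree the visited count grows with `log2(n)` times
#' the hit count, while the linear cost grows with `n`.
#'
#' @param sizes Database sizes.
#' @param n_queries Point queries per size.
#' @param iv_width Width of each stored interval.
#' @param density Stored intervals per unit of axis length (fixes the
#'   expected number of hits per query independent of `n`).
#' @param seed RNG seed.
#' @return Data frame with one row per size: `n`, `mean_visited`,
#'   `mean_hits`, `linear_cost` (= `n`).
#' @export
bench_scaling <- function(sizes = c(1e3, 1e4, 1e5), n_queries = 200,
                          iv_width = 10, density = 0.01, seed = 1) {
  rows <- lapply(sizes, function(n) {
    axis_len <- ceiling(n / density)
    with_seed(seed + n, {
      starts <- sample.int(axis_len - iv_width + 1L, n, replace = TRUE)
      t <- interval_tree("bench")
      it_insert(t, start = starts, end = starts + iv_width - 1,
                payload = as.character(seq_len(n)), chrom = "bench")
      qpos <- sample.int(axis_len, n_queries, replace = TRUE)
      visited <- numeric(n_queries); hits <- numeric(n_queries)
      for (i in seq_len(n_queries)) {
        r <- search_overlaps(t, genomic_interval("bench", qpos[i], qpos[i]))
        visited[i] <- attr(r, "visited")
        hits[i] <- nrow(r)
      }
      data.frame(n = n, mean_visited = mean(visited),
                 mean_hits = mean(hits), linear_cost = n)
    })
  })
  do.call(rbind, rows)
}
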