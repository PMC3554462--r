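# Independent oracles and small generators shared across tests.

# Set-based overlap oracle: shared bases counted by explicit set
# intersection; disjoint pairs get minus the number of bases strictly
# between the spans.  Independent of the closed-form implementation.
oracle_overlap_width <- function(a1, a2, b1, b2) {
  shared <- length(intersect(seq(a1, a2), seq(b1, b2)))
  if (shared > 0) return(shared)
  -max(0L, max(a1, b1) - min(a2, b2) - 1L)
}

# Brute-force linear scan: apply the pairwise predicate to every stored
# interval.  The prescribed correctness oracle for tree search.
oracle_scan <- function(qs, qe, starts, ends, payloads, p) {
  keep <- intervalid:::qualifies_core(qs, qe, starts, ends,
                                      p$type, p$maxgap, p$minoverlap)
  ord <- order(starts[keep], ends[keep], payloads[keep])
  data.frame(start = starts[keep][ord], end = ends[keep][ord],
             payload = payloads[keep][ord], stringsAsFactors = FALSE)
}

rand_intervals <- function(n, axis = 1000, max_width = 50) {
  s <- sample.int(axis, n, replace = TRUE)
  data.frame(start = s, end = s + sample(0:max_width, n, replace = TRUE),
             payload = sprintf("iv%05d", seq_len(n)),
             stringsAsFactors = FALSE)
}

rand_params <- function(select = "all") {
  overlap_params(sample(c("any", "start", "end", "equal", "within"), 1),
                 maxgap = sample(0:3, 1), minoverlap = sample(1:3, 1),
                 select = select)
}

build_tree <- function(df, chrom = "c") {
  t <- interval_tree(chrom)
  it_insert(t, start = df$start, end = df$end, payload = df$payload,
            chrom = chrom)
  t
}

# Exhaustive ungapped mapper oracle: slide the read (and its reverse
# complement) over every offset of every chromosome counting mismatching
# characters directly; N in the read matches nothing.
revcomp_chr <- function(x) rev(chartr("ACGTN", "TGCAN", x))

oracle_hamming_map <- function(genome_chars, read, max_mismatch) {
  r_fwd <- strsplit(toupper(read), "")[[1]]
  hits <- list()
  for (chrom in names(genome_chars)) {
    g <- genome_chars[[chrom]]
    L <- length(r_fwd); N <- length(g)
    if (L > N) next
    for (strand in c("+", "-")) {
      r <- if (strand == "+") r_fwd else revcomp_chr(r_fwd)
      mm <- integer(N - L + 1L)
      for (j in seq_len(L))
        mm <- mm + (g[j:(N - L + j)] != r[j])
      o <- which(mm <= max_mismatch)
      if (length(o))
        hits[[length(hits) + 1L]] <-
          data.frame(chrom = chrom, start = o, end = o + L - 1L,
                     strand = strand, mismatches = mm[o],
                     stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(sprintf("%s:%d-%d:%s:%d", df$chrom, as.integer(df$start),
               as.integer(df$end), df$strand, as.integer(df$mismatches)))
}
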