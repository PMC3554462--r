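# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome
#'
#' Independent draws over A/C/G/T with the requested GC fraction;
#' deterministic (byte-identical) for a given seed.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome (recycled).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed RNG seed fixing all randomness.
#' @return A named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
synthetic_genome <- function(n_chroms = 2, chrom_length = 10000, gc = 0.5,
                             seed = 1) {
  if (n_chroms < 1) stop("'n_chroms' must be >= 1")
  if (any(chrom_length < 1)) stop("'chrom_length' must be >= 1")
  stopifnot(gc >= 0, gc <= 1)
  lens <- rep_len(chrom_length, n_chroms)
  seqs <- with_seed(seed, {
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, "")
  })
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  Biostrings::DNAStringSet(seqs)
}

#' Generate layered synthetic annotations with known truth
#'
#' Emulates the granularity ladder of real annotation namespaces: a
#' coarse transcript-like layer of features placed uniformly on the
#' genome, and a fine probe-like layer in which each feature is placed
#' inside a randomly chosen transcript with probability `p_in` (and
#' uniformly at random otherwise).  The returned truth mapping links
#' every probe to every transcript that wholly contains it, computed with
#' the package's own containment predicate, so 1-1, n-1 and (when
#' transcripts overlap) n-m relations all arise.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param n_transcripts,n_probes Layer sizes.
#' @param transcript_len,probe_len Length ranges `c(min, max)`; probe
#'   lengths must not exceed transcript lengths when nesting is requested.
#' @param p_in Probability that a probe is sampled inside a transcript.
#' @param seed RNG seed.
#' @return List with data frames `transcripts` and `probes` (columns
#'   `chrom`, `start`, `end`, `name`) and `truth`, a named list mapping
#'   each probe id to the character vector of containing transcript ids.
#' @export
synthetic_layers <- function(chrom_lengths, n_transcripts = 30,
                             n_probes = 120, transcript_len = c(500, 2000),
                             probe_len = c(25, 60), p_in = 0.9, seed = 1) {
  stopifnot(!is.null(names(chrom_lengths)), n_transcripts >= 1, n_probes >= 0)
  if (p_in > 0 && max(probe_len) > min(transcript_len))
    stop("probe lengths must not exceed transcript lengths when nesting")
  with_seed(seed, {
    chroms <- names(chrom_lengths)
    pick_chrom <- function() sample(chroms, 1L, prob = chrom_lengths)
    place <- function(len_range, n, prefix) {
      rows <- lapply(seq_len(n), function(i) {
        ch <- pick_chrom()
        L <- min(sample(len_range[1]:len_range[2], 1L), chrom_lengths[[ch]])
        s <- sample.int(chrom_lengths[[ch]] - L + 1L, 1L)
        data.frame(chrom = ch, start = s, end = s + L - 1L,
                   name = sprintf("%s%04d", prefix, i),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }
    tx <- place(transcript_len, n_transcripts, "TX")
    pr <- lapply(seq_len(n_probes), function(i) {
      L <- sample(probe_len[1]:probe_len[2], 1L)
      if (stats::runif(1) < p_in) {
        j <- sample.int(n_transcripts, 1L)
        s <- tx$start[j] + sample.int(tx$end[j] - tx$start[j] + 1L - L + 1L, 1L) - 1L
        data.frame(chrom = tx$chrom[j], start = s, end = s + L - 1L,
                   name = sprintf("PR%04d", i), stringsAsFactors = FALSE)
      } else {
        ch <- pick_chrom()
        s <- sample.int(chrom_lengths[[ch]] - L + 1L, 1L)
        data.frame(chrom = ch, start = s, end = s + L - 1L,
                   name = sprintf("PR%04d", i), stringsAsFactors = FALSE)
      }
    })
    pr <- do.call(rbind, c(pr, list(
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0), stringsAsFactors = FALSE))))
    truth <- lapply(seq_len(nrow(pr)), function(i) {
      same <- tx$chrom == pr$chrom[i]
      ok <- qualifies_core(pr$start[i], pr$end[i], tx$start[same],
                           tx$end[same], "within", 0, 1)
      tx$name[same][ok]
    })
    names(truth) <- pr$name
    list(transcripts = tx, probes = pr, truth = truth)
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Genome FASTA, one BED per annotation namespace, the truth TSV, and a
#' registry manifest ready for [registry_from_manifest()].
#'
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_chroms,chrom_length,gc Genome parameters, see
#'   [synthetic_genome()].
#' @param ... Passed to [synthetic_layers()].
#' @return Invisibly, a named list of the paths written.
#' @export
write_synthetic_dataset <- function(dir, seed = 1, n_chroms = 2,
                                    chrom_length = 10000, gc = 0.5, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- synthetic_genome(n_chroms, chrom_length, gc, seed = seed)
  layers <- synthetic_layers(stats::setNames(Biostrings::width(genome),
                                             names(genome)),
                             seed = seed + 1, ...)
  paths <- list(genome = file.path(dir, "genome.fa"),
                transcripts = file.path(dir, "transcripts.bed"),
                probes = file.path(dir, "probes.bed"),
                truth = file.path(dir, "truth.tsv"),
                manifest = file.path(dir, "manifest.yaml"))
  write_fasta(genome, paths$genome)
  write_bed(layers$transcripts, paths$transcripts)
  write_bed(layers$probes, paths$probes)
  write_truth_tsv(layers$truth, paths$truth)
  yaml::write_yaml(list(namespaces = list(
    list(name = "transcript", file = "transcripts.bed", format = "bed",
         mode = "span"),
    list(name = "probe", file = "probes.bed", format = "bed",
         mode = "span"))), paths$manifest)
  invisible(paths)
}

# ---- reference fixtures -------------------------------------------------

# The three published outcome statements for the 10-base worked example:
# hit sets of queries q1..q4 against subjects s1..s4 under three
# parameter settings.  These statements, not any printed coordinates,
# define the fixture; solve_overlap_axis() recovers coordinates from them.
axis_expectations <- function() {
  list(
    list(p = overlap_params("any", 0, 1),
         hits = list(q1 = "s1", q2 = c("s1", "s2", "s3", "s4"),
                     q3 = c("s1", "s2", "s3", "s4"),
                     q4 = c("s2", "s3", "s4"))),
    list(p = overlap_params("within", 0, 1),
         hits = list(q1 = "s1", q2 = "s2", q3 = character(0),
                     q4 = c("s2", "s3"))),
    list(p = overlap_params("end", 1, 1),
         hits = list(q1 = character(0), q2 = "s2", q3 = c("s3", "s4"),
                     q4 = "s2")))
}

#' Recover the worked overlap example by constraint search
#'
#' The worked example used throughout the documentation places four
#' subject intervals (`s1`..`s4`) and four query intervals (`q1`..`q4`)
#' on a 10-base reference and states, for three parameter settings, the
#' complete hit set of every query.  The coordinates themselves are not
#' given, so this function enumerates every closed interval on the axis
#' and searches, with the package's own [qualifies()] predicate, for the
#' lexicographically first assignment satisfying all three statements
#' simultaneously.  Failure to find any assignment would falsify the
#' overlap semantics, so this doubles as a consistency check.
#'
#' @param axis_len Axis length (default 10).
#' @return List with data frames `subjects` and `queries` (columns
#'   `name`, `chrom`, `start`, `end`).
#' @seealso [overlap_axis_fixture()] for the frozen result.
#' @export
solve_overlap_axis <- function(axis_len = 10) {
  ivs <- do.call(rbind, lapply(seq_len(axis_len), function(s)
    data.frame(start = s, end = s:axis_len)))
  S <- ivs$start; E <- ivs$end
  n <- nrow(ivs)
  exps <- axis_expectations()
  # predicate matrix M[x, j]: query interval x vs subject interval j
  pred <- function(p) vapply(seq_len(n), function(j)
    qualifies_core(S, E, S[j], E[j], p$type, p$maxgap, p$minoverlap),
    logical(n))
  M <- lapply(exps, function(e) pred(e$p))
  qnames <- paste0("q", 1:4)
  # C[[q]][[slot]][x, s]: interval x is consistent, as query q, with
  # interval s sitting in subject slot `slot`, across all three settings
  C <- lapply(qnames, function(q) {
    lapply(1:4, function(slot) {
      want <- vapply(exps, function(e)
        paste0("s", slot) %in% e$hits[[q]], NA)
      ok <- matrix(TRUE, n, n)
      for (k in seq_along(M)) ok <- ok & (M[[k]] == want[k])
      ok
    })
  })
  names(C) <- qnames
  for (a in seq_len(n)) {
    va <- lapply(qnames, function(q) C[[q]][[1]][, a])
    if (!all(vapply(va, any, NA))) next
    for (b in seq_len(n)) {
      vab <- lapply(seq_along(qnames), function(i) va[[i]] & C[[qnames[i]]][[2]][, b])
      if (!all(vapply(vab, any, NA))) next
      for (cc in seq_len(n)) {
        vabc <- lapply(seq_along(qnames), function(i)
          vab[[i]] & C[[qnames[i]]][[3]][, cc])
        if (!all(vapply(vabc, any, NA))) next
        for (d in seq_len(n)) {
          cand <- lapply(seq_along(qnames), function(i)
            which(vabc[[i]] & C[[qnames[i]]][[4]][, d]))
          if (!all(vapply(cand, length, 0L) > 0L)) next
          subj <- c(a, b, cc, d)
          qsel <- vapply(cand, `[[`, 0L, 1L)
          return(list(
            subjects = data.frame(name = paste0("s", 1:4), chrom = "axis",
                                  start = S[subj], end = E[subj],
                                  stringsAsFactors = FALSE),
            queries = data.frame(name = qnames, chrom = "axis",
                                 start = S[qsel], end = E[qsel],
                                 stringsAsFactors = FALSE)))
        }
      }
    }
  }
  stop("no interval assignment satisfies all outcome statements: ",
       "the overlap semantics must be revisited")
}

#' Canonical worked-example fixture
#'
#' The frozen result of [solve_overlap_axis()]: the lexicographically
#' first coordinates on the 10-base axis satisfying all three published
#' outcome statements (see [axis_expectations] in the package sources).
#'
#' @return List with data frames `subjects` and `queries`.
#' @examples
#' fx <- overlap_axis_fixture()
#' t <- interval_tree("axis")
#' for (i in 1:4) it_insert(t, start = fx$subjects$start[i],
#'                          end = fx$subjects$end[i],
#'                          payload = fx$subjects$name[i], chrom = "axis")
#' search_overlaps(t, genomic_interval("axis", 1, 1))  # q1 hits s1 only
#' @export
overlap_axis_fixture <- function() {
  list(
    subjects = data.frame(name = paste0("s", 1:4), chrom = "axis",
                          start = c(1L, 2L, 3L, 5L), end = c(3L, 5L, 7L, 7L),
                          stringsAsFactors = FALSE),
    queries = data.frame(name = paste0("q", 1:4), chrom = "axis",
                         start = c(1L, 2L, 1L, 4L), end = c(1L, 5L, 7L, 5L),
                         stringsAsFactors = FALSE))
}

#' Probe-to-transcript demonstration registry
#'
#' A small registry reproducing the canonical two-step conversion
#' picture: probe A overlaps exons of transcripts 2 and 3 but lies
#' outside every exon of transcript 1, so converting the probe to the
#' transcript namespace yields exactly transcripts 2 and 3.  The same
#' three transcripts are also registered under `transcript_span` in span
#' mode, so a query falling entirely inside an intron hits the span
#' representation but not the exon-union one.
#'
#' @return An [registry()] with namespaces `probe`, `transcript`
#'   (exon-union) and `transcript_span` (span).
#' @export
toy_probe_registry <- function() {
  reg <- registry()
  register(reg, id_record("probe_A", "probe",
                          data.frame(chrom = "chr1", start = 150, end = 165)))
  exons <- list(
    transcript_1 = data.frame(chrom = "chr1", start = c(10, 80),
                              end = c(40, 100)),
    transcript_2 = data.frame(chrom = "chr1", start = c(120, 200),
                              end = c(160, 240)),
    transcript_3 = data.frame(chrom = "chr1", start = c(150, 260),
                              end = c(190, 300)))
  for (id in names(exons)) {
    ex <- exons[[id]]
    register(reg, id_record(id, "transcript", ex, mode = "exon_union"))
    register(reg, id_record(id, "transcript_span",
                            data.frame(chrom = ex$chrom[1],
                                       start = min(ex$start),
                                       end = max(ex$end)),
                            mode = "span"))
  }
  reg
}
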