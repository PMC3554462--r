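test_that("the probe-to-transcript demonstration converts to exactly two transcripts", {
  reg <- toy_probe_registry()
  rep <- convert_ids(reg, "probe_A", "probe", "transcript")
  expect_setequal(rep$hits$target_id, c("transcript_2", "transcript_3"))
  expect_false("transcript_1" %in% rep$hits$target_id)
  expect_equal(nrow(rep$unconverted), 0)
  # empty query list gives an empty report
  rep0 <- convert_ids(reg, character(0), "probe", "transcript")
  expect_equal(nrow(rep0$hits), 0)
  expect_equal(nrow(rep0$unconverted), 0)
})

test_that("every query id lands exactly once in hits or unconverted", {
  reg <- toy_probe_registry()
  ids <- c("probe_A", "ghost1", "ghost2")
  rep <- convert_ids(reg, ids, "auto", "transcript")
  expect_setequal(c(unique(rep$hits$query_id), rep$unconverted$query_id), ids)
  expect_equal(length(unique(rep$hits$query_id)) + nrow(rep$unconverted),
               length(ids))
  expect_equal(rep$unconverted$reason, rep("no_coordinates", 2))
  expect_error(convert_ids(reg, "probe_A", "probe", "nonexistent"),
               "unknown target namespace")
})

test_that("converting a namespace onto itself recovers each identifier", {
  lay <- synthetic_layers(c(chr1 = 8000, chr2 = 8000), seed = 31,
                          n_transcripts = 15, n_probes = 0)
  reg <- registry()
  register_table(reg, lay$transcripts, "transcript")
  rep <- convert_ids(reg, lay$transcripts$name, "transcript", "transcript",
                     overlap_params("equal"))
  for (id in lay$transcripts$name)
    expect_true(id %in% rep$hits$target_id[rep$hits$query_id == id])
})

test_that("interval queries match a direct per-record predicate scan", {
  set.seed(77)
  lay <- synthetic_layers(c(chr1 = 4000), seed = 32, n_transcripts = 25,
                          n_probes = 0, transcript_len = c(100, 400))
  reg <- registry()
  register_table(reg, lay$transcripts, "transcript")
  for (k in 1:100) {
    qs <- sample.int(4000, 1); qe <- min(4000, qs + sample(0:300, 1))
    p <- rand_params()
    rep <- convert_intervals(reg, data.frame(chrom = "chr1", start = qs,
                                             end = qe, name = "q"),
                             "transcript", p)
    keep <- intervalid:::qualifies_core(qs, qe, lay$transcripts$start,
                                        lay$transcripts$end,
                                        p$type, p$maxgap, p$minoverlap)
    expect_setequal(rep$hits$target_id, lay$transcripts$name[keep])
    if (!any(keep)) expect_equal(rep$unconverted$reason, "no_overlap")
  }
})

test_that("upstream promoter windows reach features placed before a gene", {
  reg <- registry()
  gene_start <- 2000
  register(reg, id_record("TF_site", "tfbs",
                          data.frame(chrom = "chr1", start = gene_start - 220,
                                     end = gene_start - 180)))
  promoter <- data.frame(chrom = "chr1", start = gene_start - 500,
                         end = gene_start - 1, name = "promoter")
  rep <- convert_intervals(reg, promoter, "tfbs")
  expect_equal(rep$hits$target_id, "TF_site")
  # an interval on a chromosome absent from the registry is unconverted
  rep2 <- convert_intervals(reg, data.frame(chrom = "chrZ", start = 1,
                                            end = 100, name = "off"), "tfbs")
  expect_equal(rep2$unconverted$reason, "no_overlap")
})

test_that("conversion hit fields keep overlap and gap mutually exclusive", {
  reg <- toy_probe_registry()
  rep <- convert_ids(reg, "probe_A", "probe", c("transcript", "transcript_span"),
                     overlap_params("any", maxgap = 50))
  expect_true(all(rep$hits$overlap_bases >= 0))
  expect_true(all(rep$hits$gap_bases >= 0))
  expect_false(any(rep$hits$overlap_bases > 0 & rep$hits$gap_bases > 0))
})

test_that("sequence conversion composes mapping with interval conversion", {
  genome <- synthetic_genome(1, 3000, seed = 40)
  gseq <- as.character(genome[[1]])
  reg <- registry()
  register(reg, id_record("gene1", "gene",
                          data.frame(chrom = "chr1", start = 500, end = 800)))
  reads <- c(in_gene = substr(gseq, 600, 649),
             off_gene = substr(gseq, 2000, 2049),
             unmappable = strrep("N", 50))
  rep <- convert_sequences(reg, genome, reads, "gene")
  expect_equal(unique(rep$hits$query_id), "in_gene")
  expect_equal(rep$hits$target_id, "gene1")
  expect_setequal(rep$unconverted$query_id, c("off_gene", "unmappable"))
  expect_equal(rep$unconverted$reason[rep$unconverted$query_id == "off_gene"],
               "no_overlap")
  expect_equal(rep$unconverted$reason[rep$unconverted$query_id == "unmappable"],
               "no_coordinates")
})

test_that("fragmentation emits full windows with ordered numeric suffixes", {
  fr <- fragment_sequence("g", strrep("A", 100), window = 50, step = 25)
  expect_equal(nrow(fr), 3)
  expect_equal(fr$name, c("g_1", "g_2", "g_3"))
  expect_equal(nchar(fr$seq), rep(50, 3))
  # offsets 1, 26, 51: consecutive fragments share window - step bases
  expect_equal(substr(fr$seq[1], 26, 50), substr(fr$seq[2], 1, 25))
  expect_equal(nrow(fragment_sequence("g", strrep("A", 50))), 1)
  expect_equal(nrow(fragment_sequence("g", strrep("A", 49))), 0)
  seq <- paste(sample(c("A", "C", "G", "T"), 130, TRUE), collapse = "")
  fr2 <- fragment_sequence("x", seq)
  # length 130 fits full windows at offsets 1, 26, 51, 76 only
  expect_equal(fr2$seq, substring(seq, c(1, 26, 51, 76), c(50, 75, 100, 125)))
})

test_that("alignment score filtering keeps the near-maximal stratum", {
  expect_equal(filter_best_fraction(c(100, 96, 94)), c(100, 96))
  expect_equal(filter_best_fraction(42), 42)
  expect_equal(filter_best_fraction(rep(7, 5)), rep(7, 5))
  expect_equal(length(filter_best_fraction(numeric(0))), 0)
  df <- data.frame(id = c("a", "b", "c"), score = c(200, 189, 191))
  expect_equal(filter_best_fraction(df)$id, c("a", "c"))
  expect_error(filter_best_fraction(c(-1, 5)), ">= 0")
})
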