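# A shared-locus fixture in the spirit of the BRCA2 alias family: one
# gene locus carrying identifiers in three namespaces.
brca2_like_registry <- function() {
  reg <- registry()
  locus <- data.frame(chrom = "chr13", start = 32315474, end = 32400266)
  register(reg, id_record("675", "entrez", locus))
  register(reg, id_record("ENSG00000139618", "ensembl_gene", locus))
  register(reg, id_record("NM_000059", "refseq", locus))
  reg
}

test_that("aliases registered in separate namespaces resolve to one span", {
  reg <- brca2_like_registry()
  iv1 <- intervals_for_id(reg, "675", "entrez")
  iv2 <- intervals_for_id(reg, "ENSG00000139618", "ensembl_gene")
  iv3 <- intervals_for_id(reg, "NM_000059", "refseq")
  expect_equal(iv1[, c("start", "end")], iv2[, c("start", "end")])
  expect_equal(iv1[, c("start", "end")], iv3[, c("start", "end")])
  # converting any alias to the other namespaces recovers the others
  rep <- convert_ids(reg, "675", "auto", c("ensembl_gene", "refseq"))
  expect_setequal(rep$hits$target_id, c("ENSG00000139618", "NM_000059"))
})

test_that("identifier type lookup classifies mixed lists in input order", {
  reg <- brca2_like_registry()
  got <- lookup_identifier_types(reg, c("675", "NM_000059", "bogus"))
  expect_equal(names(got), c("675", "NM_000059", "bogus"))
  expect_equal(got[["675"]], "entrez")
  expect_equal(got[["NM_000059"]], "refseq")
  expect_equal(got[["bogus"]], character(0))
  expect_equal(lookup_identifier_types(reg, character(0)),
               structure(list(), names = character(0)))
  # an id present in two namespaces reports both
  register(reg, id_record("675", "legacy",
                          data.frame(chrom = "chr13", start = 1, end = 10)))
  expect_setequal(lookup_identifier_types(reg, "675")[[1]],
                  c("entrez", "legacy"))
})

test_that("registration round-trips and keeps trees consistent with records", {
  reg <- registry()
  iv <- data.frame(chrom = c("chr1", "chr2", "chr1"),
                   start = c(100, 50, 900), end = c(160, 80, 980))
  register(reg, id_record("est1", "est", iv))  # multi-placement EST
  got <- intervals_for_id(reg, "est1", "est")
  expect_equal(got[, c("chrom", "start", "end")],
               iv[, c("chrom", "start", "end")])
  expect_error(intervals_for_id(reg, "nope", "est"), "not found")
  expect_error(intervals_for_id(reg, "est1", "nope"), "not found")
  expect_error(register(reg, id_record("est1", "est", iv)), "duplicate")
  expect_true(registry_validate(reg))
})

test_that("exon-union records insert one tree node per exon", {
  reg <- registry()
  ex <- data.frame(chrom = "chr1", start = c(10, 100, 200),
                   end = c(40, 150, 260))
  register(reg, id_record("tx1", "transcript", ex, mode = "exon_union"))
  t <- intervalid:::registry_tree(reg, "transcript", "chr1")
  expect_equal(length(t), 3)
  expect_true(registry_validate(reg))
})

test_that("intronic queries separate exon-union from span representations", {
  reg <- toy_probe_registry()
  intron_q <- data.frame(chrom = "chr1", start = 201, end = 250, name = "iq")
  # transcript_3 has exons [150,190] and [260,300]: [201,250] is intronic
  rep_union <- convert_intervals(reg, intron_q, "transcript")
  rep_span <- convert_intervals(reg, intron_q, "transcript_span")
  expect_false("transcript_3" %in%
                 rep_union$hits$target_id[rep_union$hits$target_namespace == "transcript"])
  expect_true("transcript_3" %in% rep_span$hits$target_id)
})

test_that("exon-union minoverlap counts summed per-exon intersection", {
  reg <- registry()
  ex <- data.frame(chrom = "chr1", start = c(100, 200), end = c(110, 210))
  register(reg, id_record("tx", "transcript", ex, mode = "exon_union"))
  # query overlapping 4 bases of exon 1 and 4 of exon 2: sum 8
  q <- data.frame(chrom = "chr1", start = 107, end = 203, name = "q")
  hit8 <- convert_intervals(reg, q, "transcript",
                            overlap_params(minoverlap = 8))
  hit9 <- convert_intervals(reg, q, "transcript",
                            overlap_params(minoverlap = 9))
  expect_equal(hit8$hits$target_id, "tx")
  expect_equal(hit8$hits$overlap_bases, 8)
  expect_equal(nrow(hit9$hits), 0)
})

test_that("a registry builds from a manifest and matches in-memory layers", {
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(dir, seed = 5, n_chroms = 2,
                                   chrom_length = 5000, n_transcripts = 10,
                                   n_probes = 30)
  reg <- registry_from_manifest(paths$manifest)
  expect_setequal(registry_namespaces(reg), c("probe", "transcript"))
  expect_true(registry_validate(reg))
  lay <- synthetic_layers(c(chr1 = 5000, chr2 = 5000), seed = 6,
                          n_transcripts = 10, n_probes = 30)
  reg2 <- registry()
  register_table(reg2, lay$transcripts, "transcript")
  expect_equal(intervals_for_id(reg2, lay$transcripts$name[1], "transcript")$start,
               lay$transcripts$start[1])
})
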