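gi <- function(s, e, chrom = "c") genomic_interval(chrom, s, e)

test_that("overlap width and gap follow closed-coordinate set semantics", {
  expect_equal(overlap_width(gi(1, 10), gi(5, 9)), 5)
  expect_equal(overlap_width(gi(1, 5), gi(6, 9)), 0)
  expect_equal(overlap_width(gi(1, 5), gi(8, 9)), -2)
  expect_equal(gap(gi(1, 5), gi(6, 9)), 0)
  expect_equal(gap(gi(1, 5), gi(8, 9)), 2)
  expect_equal(gap(gi(1, 10), gi(5, 9)), 0)
  expect_error(overlap_width(gi(1, 5), genomic_interval("other", 1, 5)),
               "different chromosomes")
  # every interval pair on a 10-base toy genome vs the set oracle
  ivs <- expand.grid(s = 1:10, e = 1:10)
  ivs <- ivs[ivs$s <= ivs$e, ]
  for (i in seq_len(nrow(ivs))) {
    w <- overlap_width(gi(ivs$s[i], ivs$e[i]), gi(ivs$s[1], ivs$e[1]))
    expect_equal(w, oracle_overlap_width(ivs$s[i], ivs$e[i],
                                             ivs$s[1], ivs$e[1]))
  }
  set.seed(11)
  for (k in 1:200) {
    a <- sort(sample(1:10, 2, replace = TRUE))
    b <- sort(sample(1:10, 2, replace = TRUE))
    expect_equal(overlap_width(gi(a[1], a[2]), gi(b[1], b[2])),
                     oracle_overlap_width(a[1], a[2], b[1], b[2]))
  }
})

test_that("interval construction rejects invalid coordinates", {
  expect_error(genomic_interval("c", 0, 5), "1-based")
  expect_error(genomic_interval("c", 6, 5), "'end' must be")
  expect_equal(interval_width(gi(3, 3)), 1)
})

test_that("default-parameter qualification is exactly sharing a base", {
  p <- overlap_params()
  ivs <- expand.grid(s = 1:12, e = 1:12)
  ivs <- ivs[ivs$s <= ivs$e, ]
  for (i in seq_len(nrow(ivs))) {
    q <- gi(ivs$s[i], ivs$e[i])
    got <- vapply(seq_len(nrow(ivs)), function(j)
      qualifies(q, gi(ivs$s[j], ivs$e[j]), p), NA)
    want <- vapply(seq_len(nrow(ivs)), function(j)
      overlap_width(q, gi(ivs$s[j], ivs$e[j])) >= 1, NA)
    expect_identical(got, want)
  }
})

test_that("type-specific positional rules behave as documented", {
  expect_true(qualifies(gi(3, 7), gi(3, 9), overlap_params("start")))
  expect_false(qualifies(gi(4, 7), gi(3, 9), overlap_params("start")))
  expect_true(qualifies(gi(3, 7), gi(2, 7), overlap_params("within")))
  expect_false(qualifies(gi(2, 7), gi(3, 7), overlap_params("within")))
  expect_true(qualifies(gi(3, 7), gi(9, 12), overlap_params("any", maxgap = 1)))
  expect_false(qualifies(gi(3, 7), gi(9, 12), overlap_params("any")))
  # equal with maxgap 0 is exact coordinate identity
  set.seed(3)
  p <- overlap_params("equal")
  for (k in 1:100) {
    a <- sort(sample(1:15, 2, replace = TRUE))
    b <- sort(sample(1:15, 2, replace = TRUE))
    expect_identical(qualifies(gi(a[1], a[2]), gi(b[1], b[2]), p),
                     a[1] == b[1] && a[2] == b[2])
  }
})

test_that("qualification is symmetric for any/equal but not within", {
  set.seed(5)
  for (k in 1:200) {
    a <- sort(sample(1:30, 2, replace = TRUE))
    b <- sort(sample(1:30, 2, replace = TRUE))
    for (ty in c("any", "equal")) {
      p <- overlap_params(ty, maxgap = sample(0:2, 1))
      expect_identical(qualifies(gi(a[1], a[2]), gi(b[1], b[2]), p),
                       qualifies(gi(b[1], b[2]), gi(a[1], a[2]), p))
    }
  }
  p <- overlap_params("within")
  expect_true(qualifies(gi(4, 6), gi(2, 9), p))
  expect_false(qualifies(gi(2, 9), gi(4, 6), p))
})

test_that("relaxing maxgap or minoverlap never loses a qualifying pair", {
  set.seed(8)
  for (k in 1:300) {
    a <- sort(sample(1:40, 2, replace = TRUE))
    b <- sort(sample(1:40, 2, replace = TRUE))
    ty <- sample(c("any", "start", "end", "equal", "within"), 1)
    mg <- sample(0:3, 1); mo <- sample(1:4, 1)
    base <- qualifies(gi(a[1], a[2]), gi(b[1], b[2]),
                      overlap_params(ty, mg, mo))
    if (base) {
      expect_true(qualifies(gi(a[1], a[2]), gi(b[1], b[2]),
                            overlap_params(ty, mg + 1, mo)))
      expect_true(qualifies(gi(a[1], a[2]), gi(b[1], b[2]),
                            overlap_params(ty, mg, max(1, mo - 1))))
    }
  }
})

test_that("strand is ignored unless strict matching is requested", {
  a <- genomic_interval("c", 1, 10, "+")
  b <- genomic_interval("c", 5, 12, "-")
  expect_true(qualifies(a, b))
  expect_false(qualifies(a, b, strict_strand = TRUE))
  expect_true(qualifies(a, genomic_interval("c", 5, 12, "+"),
                        strict_strand = TRUE))
})

test_that("predicate matches IRanges findOverlaps where contracts coincide", {
  skip_if_not_installed("IRanges")
  set.seed(21)
  n <- 80
  qs <- sample(1:80, n, TRUE); qe <- qs + sample(0:15, n, TRUE)
  ss <- sample(1:80, n, TRUE); se <- ss + sample(0:15, n, TRUE)
  q <- IRanges::IRanges(qs, qe); s <- IRanges::IRanges(ss, se)
  # shared-contract combos: every type at maxgap 0 (any minoverlap), and
  # coordinate slack on start/end/equal; 'any'/'within' with maxgap follow
  # a different contract in IRanges and are covered by the scan oracle
  combos <- rbind(expand.grid(type = c("any", "start", "end", "equal", "within"),
                              maxgap = 0, minoverlap = 1:3,
                              stringsAsFactors = FALSE),
                  expand.grid(type = c("start", "end", "equal"),
                              maxgap = 1:2, minoverlap = 1,
                              stringsAsFactors = FALSE))
  for (i in seq_len(nrow(combos))) {
    ty <- combos$type[i]; mg <- combos$maxgap[i]; mo <- combos$minoverlap[i]
    h <- IRanges::findOverlaps(q, s, minoverlap = mo, type = ty,
                               maxgap = if (mg == 0 && ty == "any") -1L else mg)
    ir <- matrix(FALSE, n, n)
    ir[cbind(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))] <- TRUE
    mine <- vapply(seq_len(n), function(j)
      intervalid:::qualifies_core(qs, qe, ss[j], se[j], ty, mg, mo),
      logical(n))
    expect_identical(unname(mine), unname(ir),
                     label = sprintf("type=%s maxgap=%d minoverlap=%d", ty, mg, mo))
  }
})
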