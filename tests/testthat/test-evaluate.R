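test_that("conversion classification covers all set configurations", {
  expect_equal(classify_conversion("A", c("A", "B")), "TP")
  expect_equal(classify_conversion(character(0), "A"), "FP")
  expect_equal(classify_conversion(c("A", "B"), "A"), "FP")
  expect_equal(classify_conversion("A", character(0)), "FN")
  expect_equal(classify_conversion(character(0), character(0)), "TN")
  # exhaustive and exclusive over random small sets
  set.seed(61)
  universe <- LETTERS[1:5]
  for (k in 1:300) {
    Z <- sample(universe, sample(0:3, 1))
    Y <- sample(universe, sample(0:3, 1))
    lab <- classify_conversion(Z, Y)
    expect_true(lab %in% c("TP", "FP", "FN", "TN"))
    manual <- if (length(Z) == 0 && length(Y) == 0) "TN"
      else if (length(Z) == 0) "FP"
      else if (length(Y) == 0) "FN"
      else if (all(Z %in% Y)) "TP" else "FP"
    expect_equal(lab, manual)
  }
})

test_that("accuracy matches the published formula on printed counts", {
  expect_equal(conversion_accuracy(confusion_counts(866, 19, 109, 6)), 87.20)
  expect_equal(conversion_accuracy(confusion_counts(790, 63, 146, 1)), 79.10)
  expect_equal(conversion_accuracy(confusion_counts(0, 0, 0, 1)), 100.0)
  expect_error(conversion_accuracy(confusion_counts(0, 0, 0, 0)), "undefined")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("derived metrics reproduce published rows to two decimals", {
  m1 <- conversion_metrics(confusion_counts(866, 19, 109, 6))
  expect_equal(unname(m1[c("TPR", "FPR", "FDR", "F1")]),
               c(88.82, 76.00, 2.15, 93.12))
  m2 <- conversion_metrics(confusion_counts(362, 224, 20, 394))
  expect_equal(unname(m2[c("TPR", "FPR", "FDR", "F1")]),
               c(94.76, 36.25, 38.23, 74.79))
  m3 <- conversion_metrics(confusion_counts(335, 216, 49, 400))
  expect_equal(unname(m3[c("TPR", "FPR", "FDR", "F1")]),
               c(87.24, 35.06, 39.20, 71.66))
  # undefined denominators are flagged, not zeroed
  m4 <- conversion_metrics(confusion_counts(0, 0, 0, 5))
  expect_true(is.na(m4[["TPR"]]))
  expect_true("TPR" %in% attr(m4, "undefined"))
})

test_that("half-up rounding matches fixed-precision table formatting", {
  expect_equal(round_half_up(98.4375, 2), 98.44)
  expect_equal(round_half_up(2.145, 2), 2.15)
  expect_equal(round_half_up(-2.145, 2), -2.15)
  expect_equal(round_half_up(87.2, 2), 87.2)
})

test_that("every metric cell of the shipped benchmark tables recomputes", {
  b <- benchmark_counts()
  expect_equal(nrow(b), 20)
  expect_true(all(b$TP + b$FP + b$FN + b$TN == 1000))
  rec <- metrics_table(b)
  for (col in c("TPR", "FPR", "ACC", "FDR", "F1"))
    expect_equal(rec[[col]], b[[col]], label = col)
  # total mapped is TP + FP by definition; one printed row is internally
  # inconsistent with its own counts and is excluded from the comparison
  expect_equal(rec$total_mapped, b$TP + b$FP)
  consistent <- b$total_mapped == b$TP + b$FP
  expect_equal(sum(consistent), 19)
  expect_equal(rec$total_mapped[consistent], b$total_mapped[consistent])
})

test_that("adding a true positive never decreases accuracy", {
  set.seed(62)
  for (k in 1:100) {
    v <- sample(0:50, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    a0 <- conversion_accuracy(confusion_counts(v[1], v[2], v[3], v[4]),
                              digits = NULL)
    a1 <- conversion_accuracy(confusion_counts(v[1] + 1, v[2], v[3], v[4]),
                              digits = NULL)
    expect_gte(a1, a0)
    expect_true(a0 >= 0 && a0 <= 100)
  }
})

test_that("report evaluation equals a direct per-id recount", {
  set.seed(63)
  ids <- sprintf("q%03d", 1:60)
  targets <- sprintf("t%02d", 1:15)
  truth <- lapply(ids, function(i) sample(targets, sample(0:2, 1)))
  names(truth) <- ids
  hits <- do.call(rbind, lapply(ids, function(i) {
    y <- sample(targets, sample(0:3, 1))
    if (length(y) == 0) return(NULL)
    data.frame(query_id = i, target_id = y, stringsAsFactors = FALSE)
  }))
  ev <- evaluate_conversion(hits, truth)
  recount <- table(factor(vapply(ids, function(i)
    classify_conversion(truth[[i]], hits$target_id[hits$query_id == i]), ""),
    levels = c("TP", "FP", "FN", "TN")))
  expect_equal(ev$counts$TP, unname(recount["TP"]))
  expect_equal(ev$counts$FP, unname(recount["FP"]))
  expect_equal(ev$counts$FN, unname(recount["FN"]))
  expect_equal(ev$counts$TN, unname(recount["TN"]))
  expect_equal(ev$counts$TP + ev$counts$FP + ev$counts$FN + ev$counts$TN,
               length(ids))
  expect_error(evaluate_conversion(hits, truth, evaluated_ids = "missing"),
               "truth keys")
})

test_that("the curated-RefSeq filter drops predicted accessions on both sides", {
  expect_equal(filter_refseq_curated(c("NM_000059", "XM_123", "NR_002", "NP_9")),
               c("NM_000059", "NR_002"))
  truth <- list(q1 = c("NM_1", "XM_2"))
  hits <- data.frame(query_id = "q1", target_id = c("NM_1", "XR_7"),
                     stringsAsFactors = FALSE)
  ev <- evaluate_conversion(hits, truth, id_filter = filter_refseq_curated)
  expect_equal(unname(ev$labels["q1"]), "TP")  # XM_/XR_ ignored on both sides
})
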