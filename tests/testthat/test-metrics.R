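# Confusion matrices, accuracy, F1 family, and the accuracy variants.

test_that("confusion counts and normalization are correct", {
  cm <- confusion(c("R", "Y"), c("R", "Y"))
  expect_identical(unname(diag(cm$counts)), c(1L, 1L))
  expect_identical(sum(cm$counts), 2L)
  set.seed(1)
  truths <- sample(c("A", "B", "C"), 50, replace = TRUE)
  preds <- sample(c("A", "B", "C"), 50, replace = TRUE)
  cm2 <- confusion(truths, preds)
  expect_identical(sum(cm2$counts), 50L)  # sample conservation
  rs <- rowSums(cm2$normalized)
  expect_equal(unname(rs), rep(1, 3), tolerance = 1e-9)
  expect_error(confusion(truths, preds, labels = c("A", "B")),
               "unknown truth label")
  expect_error(confusion(c("A"), c("Z"), labels = c("A", "B")),
               "unknown predicted label")
})

test_that("binary confusion matrices carry TP/FN/FP/TN in the table cells", {
  truths <- rep(c("pos", "neg"), c(4, 6))
  preds <- c("pos", "pos", "pos", "neg",  # TP = 3, FN = 1
             "pos", "neg", "neg", "neg", "neg", "neg")  # FP = 1, TN = 5
  cm <- confusion(truths, preds, labels = c("pos", "neg"))
  expect_identical(unname(cm$counts["pos", "pos"]), 3L)
  expect_identical(unname(cm$counts["pos", "neg"]), 1L)
  expect_identical(unname(cm$counts["neg", "pos"]), 1L)
  expect_identical(unname(cm$counts["neg", "neg"]), 5L)
  expect_equal(accuracy(cm), 0.8)  # (TP + TN) / all = 8/10
})

test_that("accuracy is the trace over the total", {
  cm <- confusion(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(accuracy(cm), 1)
  cm_wrong <- confusion(c("A", "A", "B"), c("B", "B", "A"))
  expect_equal(accuracy(cm_wrong), 0)
  expect_error(accuracy(confusion(character(0), character(0),
                                  labels = c("A", "B"))),
               "empty")
})

test_that("per-class F1 matches the hand-computed example", {
  cm <- confusion(c("R", "R", "Y", "Y"), c("R", "Y", "Y", "Y"))
  f1 <- f1_per_class(cm)
  expect_equal(unname(f1["R"]), 2 * (0.5 * 1) / 1.5, tolerance = 1e-12)
  expect_equal(unname(f1["Y"]), 0.8, tolerance = 1e-12)
  expect_equal(macro_f1(cm), (2 / 3 + 0.8) / 2, tolerance = 1e-12)
})

test_that("degenerate classes follow the documented conventions", {
  # class never true and never predicted: dropped from the macro mean
  cm <- confusion(c("A", "B"), c("A", "B"), labels = c("A", "B", "C"))
  expect_true(is.na(f1_per_class(cm)["C"]))
  expect_equal(macro_f1(cm), 1)
  # class with true instances but no predictions: F1 = 0
  cm2 <- confusion(c("A", "B"), c("A", "A"), labels = c("A", "B"))
  expect_identical(unname(f1_per_class(cm2)["B"]), 0)
  # perfect classifier
  expect_equal(macro_f1(confusion(letters[1:4], letters[1:4])), 1)
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(99)
  labels <- c("A", "B", "C", "D")
  for (i in 1:100) {
    truths <- factor(sample(labels, 40, replace = TRUE), levels = labels)
    # ensure every class occurs so per-class rates are defined
    truths[1:4] <- labels
    preds <- factor(sample(labels, 40, replace = TRUE), levels = labels)
    cm <- confusion(as.character(truths), as.character(preds),
                    labels = labels)
    ref <- caret::confusionMatrix(preds, truths, mode = "prec_recall")
    expect_equal(accuracy(cm), unname(ref$overall["Accuracy"]),
                 tolerance = 1e-12)
    ref_f1 <- ref$byClass[, "F1"]
    ref_f1[is.na(ref_f1)] <- 0  # classes never predicted
    expect_equal(unname(f1_per_class(cm)), unname(ref_f1),
                 tolerance = 1e-12)
    expect_equal(macro_f1(cm), mean(ref_f1), tolerance = 1e-12)
  }
})

test_that("include/without-inconsistent accuracies behave as documented", {
  truths <- paste0("L", c(1:8, 1, 2))
  preds <- c(paste0("L", 1:8), "L9", INCONSISTENT)  # 8 right, 1 wrong, 1 inc.
  acc <- accuracy_with_without_inconsistent(truths, preds)
  expect_equal(unname(acc["include"]), 0.8)
  expect_equal(unname(acc["without"]), 8 / 9)
  # no inconsistent cases: both equal plain accuracy
  acc2 <- accuracy_with_without_inconsistent(c("A", "B"), c("A", "A"))
  expect_equal(unname(acc2["include"]), unname(acc2["without"]))
  expect_error(
    accuracy_with_without_inconsistent("A", INCONSISTENT),
    "all predictions are inconsistent"
  )
})

test_that("include-accuracy never exceeds without-accuracy", {
  set.seed(2024)
  labels <- c("A", "B", "C")
  for (i in 1:500) {
    truths <- sample(labels, 20, replace = TRUE)
    preds <- sample(c(labels, INCONSISTENT), 20, replace = TRUE)
    if (all(preds == INCONSISTENT)) next
    acc <- accuracy_with_without_inconsistent(truths, preds)
    expect_lte(acc["include"], acc["without"])
    expect_true(all(acc >= 0 & acc <= 1))
  }
})

test_that("set-membership accuracy generalizes plain accuracy monotonically", {
  preds <- c("White", "Purple", "Red")
  singles <- list("White", "Red", "Red")
  expect_equal(set_membership_accuracy(preds, singles), 2 / 3)
  # prediction contained in an enlarged set counts as correct
  expect_equal(
    set_membership_accuracy("White", list(c("White", "Purple"))), 1)
  # enlarging sets never decreases the rate
  set.seed(31)
  labels <- c("A", "B", "C", "D")
  for (i in 1:50) {
    preds <- sample(labels, 15, replace = TRUE)
    sets <- replicate(15, sample(labels, sample(1:2, 1)), simplify = FALSE)
    bigger <- lapply(sets, function(s) unique(c(s, sample(labels, 1))))
    expect_gte(set_membership_accuracy(preds, bigger),
               set_membership_accuracy(preds, sets))
  }
  expect_error(set_membership_accuracy("A", list(character(0))), "non-empty")
})

test_that("inconsistent predictions appear as a predicted-only column", {
  cm <- confusion(c("A", "B", "A"), c("A", INCONSISTENT, INCONSISTENT),
                  labels = c("A", "B"))
  expect_identical(colnames(cm$counts), c("A", "B", INCONSISTENT))
  expect_identical(rownames(cm$counts), c("A", "B"))
  expect_identical(sum(cm$counts[, INCONSISTENT]), 2L)
})

test_that("confusion matrices export to CSV", {
  cm <- confusion(c("A", "B"), c("A", "B"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, f)
  back <- utils::read.csv(f, row.names = 1)
  expect_identical(unname(as.matrix(back)), unname(unclass(cm$counts)))
})
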