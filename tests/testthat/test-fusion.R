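# Fusion strategies: argmax, one-vs-rest merge, max probability, and the
# MLTC / MLCR ensembles.

# independent truth-table oracle for the one-vs-rest merge
ovr_oracle <- function(decisions, labels) {
  pos <- which(decisions == 1)
  if (length(pos) == 1) labels[pos]
  else if (length(pos) > 1) INCONSISTENT
  else labels[length(labels)]
}

test_that("multi-class argmax picks the max and breaks ties by order", {
  expect_identical(
    predict_multiclass(c(Red = 0.1, Yellow = 0.7, Green = 0.2)), "Yellow")
  expect_identical(
    predict_multiclass(c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)), "A")
  expect_error(predict_multiclass(c(A = 0.3, B = 0.2)), "sum to 1")
  expect_error(predict_multiclass(numeric(0)), "")
})

test_that("one-vs-rest merge implements the three outcomes", {
  labs <- c("R", "Y", "G", "P")
  r1 <- merge_one_vs_rest(c(0, 1, 0), labs)
  expect_identical(r1$label, "Y")
  expect_identical(r1$provenance, "single_positive")
  r2 <- merge_one_vs_rest(c(1, 1, 0), labs)
  expect_identical(r2$label, INCONSISTENT)
  expect_identical(r2$provenance, "contradiction")
  r3 <- merge_one_vs_rest(c(0, 0, 0), labs)
  expect_identical(r3$label, "P")
  expect_identical(r3$provenance, "domain_closure")
  expect_error(merge_one_vs_rest(c(0, 1), labs), "decisions")
})

test_that("one-vs-rest merge matches the truth-table oracle exhaustively", {
  for (m in c(4, 5, 8, 10, 11)) {
    labels <- paste0("L", seq_len(m))
    grids <- rep(list(0:1), m - 1)
    tab <- as.matrix(do.call(expand.grid, grids))
    for (i in seq_len(nrow(tab))) {
      expect_identical(merge_one_vs_rest(tab[i, ], labels)$label,
                       ovr_oracle(tab[i, ], labels))
    }
  }
})

test_that("inconsistency appears iff two or more bits are set", {
  labels <- paste0("L", 1:5)
  grids <- rep(list(0:1), 4)
  tab <- as.matrix(do.call(expand.grid, grids))
  for (i in seq_len(nrow(tab))) {
    res <- merge_one_vs_rest(tab[i, ], labels)
    expect_identical(res$label == INCONSISTENT, sum(tab[i, ]) >= 2)
  }
})

test_that("max-probability merge equals brute-force argmax and is always consistent", {
  expect_identical(
    merge_max_probability(c(R = 0.2, Y = 0.9, G = 0.1, P = 0.3)), "Y")
  expect_identical(
    merge_max_probability(c(R = 0.5, Y = 0.5, G = 0.5, P = 0.5)), "R")
  expect_error(merge_max_probability(c(R = 0.2, Y = 0.9), labels = c("R", "Y", "G")),
               "missing probability")
  set.seed(123)
  labels <- c("R", "Y", "G", "P")
  for (i in 1:1000) {
    p <- stats::setNames(runif(4), labels)
    got <- merge_max_probability(p)
    # brute-force linear scan
    best <- labels[1]
    for (lb in labels) if (p[lb] > p[best]) best <- lb
    expect_identical(got, best)
    expect_false(got == INCONSISTENT)
  }
})

test_that("TPR tables are the normalized confusion diagonal", {
  t_perfect <- compute_tpr_table(c("R", "Y"), c("R", "Y"))
  expect_equal(unname(t_perfect$tpr), c(1, 1))
  t_hand <- compute_tpr_table(c("R", "Y", "Y", "Y"), c("R", "R", "Y", "Y"))
  expect_equal(t_hand$tpr, c(R = 0.5, Y = 1.0))
  # constant classifier: 1 for its class, 0 elsewhere
  t_const <- compute_tpr_table(rep("R", 4), c("R", "R", "Y", "Y"))
  expect_equal(t_const$tpr, c(R = 1, Y = 0))
  expect_error(compute_tpr_table(c("R", "R"), c("R", "R"),
                                 labels = c("R", "Y")),
               "absent from truths")
  # agrees with the row-normalized confusion diagonal
  set.seed(5)
  truths <- sample(c("A", "B", "C"), 60, replace = TRUE)
  preds <- sample(c("A", "B", "C"), 60, replace = TRUE)
  tab <- compute_tpr_table(preds, truths, labels = c("A", "B", "C"))
  cm <- confusion(truths, preds, labels = c("A", "B", "C"))
  expect_equal(unname(tab$tpr),
               unname(cm$normalized[cbind(c("A", "B", "C"),
                                          c("A", "B", "C"))]))
})

ex1_t1 <- tpr_table(c(red = 0.38, white = 0.70), "C1")
ex1_t2 <- tpr_table(c(red = 0.58, white = 0.59), "C2")

test_that("MLTC picks the higher-TPR label on disagreement", {
  expect_identical(ensemble_mltc("red", "white", ex1_t1, ex1_t2), "white")
  expect_identical(ensemble_mltc("Green", "Green", ex1_t1, ex1_t2), "Green")
  t_eq1 <- tpr_table(c(a = 0.5, b = 0.5), "C1")
  t_eq2 <- tpr_table(c(a = 0.5, b = 0.5), "C2")
  expect_identical(ensemble_mltc("a", "b", t_eq1, t_eq2), "a")
  expect_error(ensemble_mltc("red", "blue", ex1_t1, ex1_t2), "no TPR entry")
})

test_that("MLCR reproduces the worked red/white example", {
  r <- mlcr_ratios("red", "white", ex1_t1, ex1_t2)
  expect_equal(round(unname(r["white"]), 2), 0.84)  # 0.59 / 0.70
  expect_equal(round(unname(r["red"]), 2), 0.66)    # 0.38 / 0.58
  expect_identical(ensemble_mlcr("red", "white", ex1_t1, ex1_t2), "red")
  # MLTC and MLCR provably diverge on this input
  expect_false(identical(ensemble_mlcr("red", "white", ex1_t1, ex1_t2),
                         ensemble_mltc("red", "white", ex1_t1, ex1_t2)))
})

test_that("MLCR reduces to MLTC on identical TPR tables", {
  t1 <- tpr_table(c(a = 0.6, b = 0.8), "C1")
  t2 <- tpr_table(c(a = 0.6, b = 0.8), "C2")
  expect_identical(ensemble_mlcr("a", "b", t1, t2),
                   ensemble_mltc("a", "b", t1, t2))
  expect_identical(ensemble_mlcr("b", "a", t1, t2), "b")
})

test_that("ensembles are idempotent and symmetric", {
  set.seed(77)
  labels <- c("p", "q", "r")
  for (i in 1:50) {
    t1 <- tpr_table(stats::setNames(runif(3, 0.05, 1), labels), "C1")
    t2 <- tpr_table(stats::setNames(runif(3, 0.05, 1), labels), "C2")
    l1 <- sample(labels, 1)
    l2 <- sample(labels, 1)
    expect_identical(ensemble_mltc(l1, l1, t1, t2), l1)
    expect_identical(ensemble_mlcr(l2, l2, t1, t2), l2)
    # swapping the two classifiers swaps nothing but the argument roles
    expect_identical(ensemble_mltc(l1, l2, t1, t2),
                     ensemble_mltc(l2, l1, t2, t1))
    expect_identical(ensemble_mlcr(l1, l2, t1, t2),
                     ensemble_mlcr(l2, l1, t2, t1))
  }
})

test_that("MLCR falls back to MLTC on a zero TPR denominator", {
  t1 <- tpr_table(c(a = 0.5, b = 0), "C1")
  t2 <- tpr_table(c(a = 0.4, b = 0.7), "C2")
  expect_warning(got <- ensemble_mlcr("a", "b", t1, t2), "falling back")
  expect_identical(got, ensemble_mltc("a", "b", t1, t2))
})

test_that("probability matrices and TPR tables round-trip through disk", {
  P <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, byrow = TRUE,
              dimnames = list(NULL, c("Red", "Yellow")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_prob_csv(P, f)
  expect_equal(read_prob_csv(f), P, ignore_attr = TRUE)
  g <- withr::local_tempfile(fileext = ".json")
  write_tpr_json(ex1_t1, g)
  back <- read_tpr_json(g)
  expect_equal(back$tpr, ex1_t1$tpr)
  expect_identical(back$classifier_id, "C1")
})
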