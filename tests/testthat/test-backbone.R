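# Classifier construction, freezing, oversampling and training behavior.

test_that("classifier head has the documented layer structure", {
  m <- build_classifier("tinycnn", c("A", "B", "C", "D"), seed = 1)
  ops <- vapply(m$layers, `[[`, character(1), "type")
  head_ops <- ops[(m$n_backbone + 1):length(ops)]
  expect_identical(head_ops, c("flatten", "dense", "relu", "dropout", "dense"))
  dense_idx <- which(ops == "dense")
  expect_identical(nrow(m$layers[[dense_idx[1]]]$W), 512L)
  expect_identical(nrow(m$layers[[dense_idx[2]]]$W), 4L)
  expect_identical(m$layers[[which(ops == "dropout")]]$p, 0.5)
})

test_that("unknown backbones are rejected, registered ones accepted", {
  expect_error(build_classifier("resnet900", c("A", "B")), "unknown backbone")
  expect_true(all(c("tinycnn", "smallcnn") %in% list_backbones()))
})

test_that("freeze schemes mark the right backbone layers", {
  m <- build_classifier("tinycnn", c("A", "B"),
                        freeze = freeze_scheme("first_layer_only"), seed = 1)
  expect_identical(m$frozen_layers, 1L)
  # tinycnn backbone has 6 layers; half -> bottom 3 (covers first conv)
  m2 <- build_classifier("tinycnn", c("A", "B"),
                         freeze = freeze_scheme("fraction_bottom", 1 / 2),
                         seed = 1)
  expect_identical(m2$frozen_layers, 1:3)
  expect_false(m2$layers[[1]]$trainable)
  expect_true(m2$layers[[4]]$trainable)
  m3 <- build_classifier("smallcnn", c("A", "B"),
                         freeze = freeze_scheme("fraction_bottom", 1 / 4),
                         input_size = 32, seed = 1)
  expect_identical(m3$frozen_layers, 1:2)  # floor(9/4)
  expect_error(freeze_scheme("fraction_bottom"), "fraction")
  expect_error(freeze_scheme("none", 0.5), "only meaningful")
})

test_that("frozen layer parameters are bit-identical after training", {
  ds <- quick_dataset(n_per_class = 12, seed = 3)
  tr <- ds$manifest$split == "train"
  m <- build_classifier("tinycnn", sch1cf$primaries,
                        freeze = freeze_scheme("fraction_bottom", 1 / 2),
                        input_size = 32, seed = 2)
  W_before <- m$layers[[1]]$W
  b_before <- m$layers[[1]]$b
  W4_before <- m$layers[[4]]$W
  fit <- train_classifier(m, ds$images[tr], ds$manifest$cf_primary[tr],
                          config = quick_train_config(epochs = 2))
  expect_identical(fit$layers[[1]]$W, W_before)
  expect_identical(fit$layers[[1]]$b, b_before)
  expect_false(identical(fit$layers[[4]]$W, W4_before))
})

test_that("replication oversampling balances to the majority class", {
  recs <- data.frame(id = 1:4, lab = c("A", "A", "A", "B"))
  out <- oversample_by_replication(recs, label_field = "lab")
  expect_identical(unname(table(out$lab)["A"]), unname(table(out$lab)["B"]))
  expect_identical(sum(out$lab == "A"), 3L)
  # already balanced input passes through unchanged
  bal <- data.frame(id = 1:4, lab = c("A", "A", "B", "B"))
  expect_identical(oversample_by_replication(bal, label_field = "lab")$id,
                   bal$id)
  # counts {A:5, B:2, C:1} -> 3 classes x 5
  recs3 <- data.frame(id = 1:8, lab = rep(c("A", "B", "C"), c(5, 2, 1)))
  out3 <- oversample_by_replication(recs3, label_field = "lab")
  expect_identical(nrow(out3), 15L)
  # multiset of distinct records preserved
  expect_setequal(unique(out3$id), recs3$id)
  expect_error(
    oversample_by_replication(recs3, labels = factor(recs3$lab,
                                                     levels = c("A", "B", "C", "D"))),
    "empty class"
  )
})

test_that("oversampling is cyclic and deterministic", {
  recs <- list(list(lab = "A", v = 1), list(lab = "A", v = 2),
               list(lab = "A", v = 3), list(lab = "B", v = 4))
  o1 <- oversample_by_replication(recs, label_field = "lab")
  o2 <- oversample_by_replication(recs, label_field = "lab")
  expect_identical(attr(o1, "indices"), attr(o2, "indices"))
  expect_identical(sum(attr(o1, "indices") == 4), 3L)
})

test_that("zero training epochs leave the model unchanged", {
  ds <- quick_dataset(n_per_class = 12, seed = 3)
  tr <- ds$manifest$split == "train"
  m <- build_classifier("tinycnn", sch1cf$primaries, input_size = 32,
                        seed = 2)
  fit <- train_classifier(m, ds$images[tr], ds$manifest$cf_primary[tr],
                          config = quick_train_config(epochs = 0))
  expect_identical(fit$layers, m$layers)
  expect_identical(nrow(fit$history), 0L)
})

test_that("labels outside the model's vocabulary are rejected", {
  ds <- quick_dataset(n_per_class = 12, seed = 3)
  tr <- ds$manifest$split == "train"
  m <- build_classifier("tinycnn", c("Red", "Yellow"), input_size = 32,
                        seed = 2)
  expect_error(
    train_classifier(m, ds$images[tr], ds$manifest$cf_primary[tr],
                     config = quick_train_config(epochs = 1)),
    "outside the model's label space"
  )
})

test_that("multi-class probabilities sum to one, binary ones lie in [0,1]", {
  ds <- quick_dataset(n_per_class = 12, seed = 5)
  m <- build_classifier("tinycnn", sch1cf$primaries, input_size = 32,
                        seed = 4)
  P <- predict_proba(m, ds$images[1:10])
  expect_identical(dim(P), c(10L, 4L))
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
  mb <- build_classifier("tinycnn", "Red", activation = "sigmoid",
                         input_size = 32, seed = 4)
  p <- predict_proba(mb, ds$images[1:10])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("a zeroed network yields the uniform distribution", {
  m <- build_classifier("tinycnn", sch1cf$primaries, input_size = 32,
                        seed = 1)
  for (s in seq_along(m$layers)) {
    if (!is.null(m$layers[[s]]$W)) {
      m$layers[[s]]$W[] <- 0
      m$layers[[s]]$b[] <- 0
    }
  }
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(unname(predict_proba(m, img)[1, ]), rep(0.25, 4))
})

test_that("short training beats chance on a 4-class problem", {
  ds <- quick_dataset(n_per_class = 30, seed = 6)
  tr <- ds$manifest$split == "train"
  va <- ds$manifest$split == "validation"
  y <- ds$manifest$cf_primary
  fit <- color_classifier(ds$images[tr], y[tr], labels = sch1cf$primaries,
                          validation = list(images = ds$images[va],
                                            y = y[va]),
                          config = quick_train_config(epochs = 4))
  expect_gt(fit$history$val_acc[4], 0.25)
  expect_identical(nrow(fit$history), 4L)
  expect_true(all(c("epoch", "loss", "acc", "val_loss", "val_acc") %in%
                    names(fit$history)))
})

test_that("training is reproducible under a fixed seed", {
  ds <- quick_dataset(n_per_class = 12, seed = 8)
  tr <- ds$manifest$split == "train"
  y <- ds$manifest$cf_primary
  f1 <- color_classifier(ds$images[tr], y[tr], labels = sch1cf$primaries,
                         config = quick_train_config(epochs = 2, seed = 21))
  f2 <- color_classifier(ds$images[tr], y[tr], labels = sch1cf$primaries,
                         config = quick_train_config(epochs = 2, seed = 21))
  expect_identical(f1$layers, f2$layers)
  expect_identical(f1$history, f2$history)
})
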