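# Classifier construction and training: transfer-learning style backbones
# with a fresh head (flatten -> dense(512, ReLU) -> dropout(0.5) ->
# dense(num_classes)), layer freezing, replication oversampling, data
# augmentation and Adam training.

.backbones <- new.env(parent = emptyenv())

#' Register a CNN backbone
#'
#' Backbones are feature extractors the classifier head is trained on.
#' The package ships two small from-scratch backbones suitable for
#' CPU-scale experiments (`tinycnn`, `smallcnn`); externally supplied
#' feature extractors (e.g. a pretrained network exported layer by layer)
#' can be attached by registering a spec function.
#'
#' @param name backbone name used in [build_classifier()].
#' @param spec_fun function of no arguments returning a list of layer specs
#'   (see the package internals for the spec format).
#' @param input_size default square input size in pixels.
#' @export
register_backbone <- function(name, spec_fun, input_size) {
  assign(name, list(spec_fun = spec_fun, input_size = input_size),
         envir = .backbones)
  invisible(name)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() sort(ls(envir = .backbones))

default_backbones <- function() {
  register_backbone("tinycnn", function() {
    list(list(op = "conv", filters = 8, k = 3), list(op = "relu"),
         list(op = "pool"),
         list(op = "conv", filters = 16, k = 3), list(op = "relu"),
         list(op = "pool"))
  }, input_size = 32)
  register_backbone("smallcnn", function() {
    list(list(op = "conv", filters = 8, k = 3), list(op = "relu"),
         list(op = "pool"),
         list(op = "conv", filters = 16, k = 3), list(op = "relu"),
         list(op = "pool"),
         list(op = "conv", filters = 32, k = 3), list(op = "relu"),
         list(op = "pool"))
  }, input_size = 64)
}

#' Layer-freezing scheme
#'
#' Controls which backbone layers stay fixed during training:
#' `fraction_bottom` freezes the given fraction (3/4, 1/2 or 1/4 in the
#' standard experiments) of the bottom layers, `first_layer_only` freezes
#' only the first layer, `none` trains everything and `all` freezes the
#' whole backbone (head layers always train).
#'
#' @param mode one of `"none"`, `"fraction_bottom"`, `"first_layer_only"`,
#'   `"all"`.
#' @param fraction fraction of bottom layers to freeze; required (and only
#'   meaningful) for `fraction_bottom`.
#' @export
freeze_scheme <- function(mode = c("none", "fraction_bottom",
                                   "first_layer_only", "all"),
                          fraction = NULL) {
  mode <- match.arg(mode)
  if (mode == "fraction_bottom") {
    if (is.null(fraction) || fraction <= 0 || fraction >= 1) {
      stop("fraction_bottom requires a fraction in (0, 1)")
    }
  } else if (!is.null(fraction)) {
    stop("fraction is only meaningful for mode 'fraction_bottom'")
  }
  structure(list(mode = mode, fraction = fraction), class = "freeze_scheme")
}

#' Training hyper-parameters
#'
#' Defaults follow the study's transfer-learning setup: Adam with initial
#' learning rate 5e-5, 100 epochs, batch size 64, 224 x 224 inputs,
#' class-weighted cross entropy, and rotation/shrink/flip/zoom augmentation
#' on the training split only. Desk-scale runs on the from-scratch
#' `tinycnn` override `epochs`, `initial_lr` and `input_size`.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param initial_lr initial learning rate.
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size.
#' @param input_size square image input size in pixels; `NULL` uses the
#'   backbone's default.
#' @param augmentation character vector drawn from
#'   `c("rotation", "shrink", "flip", "zoom")`; empty disables augmentation.
#' @param rotation_range maximum absolute rotation in degrees.
#' @param zoom_range multiplicative zoom/shrink range.
#' @param balance `"oversample"` replicates minority classes up to the
#'   majority size; `"class_weight"` uses inverse-frequency loss weights;
#'   `"none"` does neither.
#' @param seed integer governing weight init, shuffling, augmentation,
#'   replication order and dropout.
#' @export
train_config <- function(optimizer = "adam", initial_lr = 5e-5, epochs = 100,
                         batch_size = 64, input_size = 224,
                         augmentation = c("rotation", "shrink", "flip",
                                          "zoom"),
                         rotation_range = 30, zoom_range = c(0.8, 1.2),
                         balance = c("oversample", "class_weight", "none"),
                         seed = 42L) {
  stopifnot(identical(optimizer, "adam"))
  balance <- match.arg(balance)
  structure(
    list(optimizer = optimizer, initial_lr = initial_lr, epochs = epochs,
         batch_size = batch_size, input_size = input_size,
         augmentation = augmentation, rotation_range = rotation_range,
         zoom_range = zoom_range, balance = balance, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Build an untrained classifier
#'
#' Stacks a fresh classification head -- flatten, dense(512) with ReLU,
#' dropout(0.5), and a final dense layer -- on a registered backbone, and
#' applies a [freeze_scheme()] to the backbone layers. A multi-class head
#' (`activation = "softmax"`) has one output per label; a binary one-vs-rest
#' head (`activation = "sigmoid"`) has a single output unit.
#'
#' @param backbone name of a registered backbone (see [list_backbones()]).
#' @param labels character vector of class labels (multi-class), or a single
#'   label naming the positive class (binary head).
#' @param freeze a [freeze_scheme()].
#' @param dense_units hidden units in the head's dense layer.
#' @param dropout_p dropout probability in the head.
#' @param activation `"softmax"` (multi-class) or `"sigmoid"` (binary).
#' @param input_size square input size; `NULL` uses the backbone default.
#' @param seed optional integer seed for weight initialization.
#' @return an object of class `color_classifier`.
#' @export
build_classifier <- function(backbone = "tinycnn", labels,
                             freeze = freeze_scheme("none"),
                             dense_units = 512, dropout_p = 0.5,
                             activation = c("softmax", "sigmoid"),
                             input_size = NULL, seed = NULL) {
  activation <- match.arg(activation)
  if (!exists(backbone, envir = .backbones)) {
    stop("unknown backbone '", backbone, "'; registered: ",
         paste(list_backbones(), collapse = ", "))
  }
  reg <- get(backbone, envir = .backbones)
  if (is.null(input_size)) input_size <- reg$input_size
  if (!is.null(seed)) set.seed(seed)

  n_out <- if (activation == "sigmoid") 1L else length(labels)
  if (activation == "softmax" && n_out < 2) {
    stop("a softmax head needs at least two labels")
  }
  backbone_specs <- reg$spec_fun()
  head_specs <- list(
    list(op = "flatten"),
    list(op = "dense", units = dense_units), list(op = "relu"),
    list(op = "dropout", p = dropout_p),
    list(op = "dense", units = n_out)
  )
  net <- build_network(c(backbone_specs, head_specs),
                       c(input_size, input_size, 3L))
  n_backbone <- length(backbone_specs)
  model <- structure(
    list(backbone = backbone, layers = net$layers, n_backbone = n_backbone,
         labels = labels, activation = activation,
         input_dim = c(input_size, input_size, 3L),
         freeze = freeze, trained = FALSE, history = NULL),
    class = "color_classifier"
  )
  apply_freeze(model)
}

apply_freeze <- function(model) {
  fr <- model$freeze
  nb <- model$n_backbone
  frozen <- switch(fr$mode,
    none = integer(0),
    all = seq_len(nb),
    first_layer_only = 1L,
    fraction_bottom = seq_len(floor(fr$fraction * nb))
  )
  for (s in seq_along(model$layers)) {
    if (!is.null(model$layers[[s]]$W)) {
      model$layers[[s]]$trainable <- !(s %in% frozen)
    }
  }
  model$frozen_layers <- frozen
  model
}

frozen_parameter_layers <- function(model) {
  which(vapply(model$layers,
               function(l) !is.null(l$W) && !isTRUE(l$trainable),
               logical(1)))
}

#' Replication oversampling to the majority class
#'
#' Balances a dataset by cyclically replicating every minority class until
#' it has as many samples as the largest class. The multiset of distinct
#' records is preserved; only multiplicities change, and replication order
#' is deterministic (cyclic in the original record order).
#'
#' @param records a list of records or a data.frame (one record per row).
#' @param labels class label per record; alternatively give `label_field`
#'   naming a column/element to extract labels from.
#' @param label_field name of the label column (data.frame records) or list
#'   element (list records).
#' @return records of the same type, oversampled; the selected indices are
#'   attached as attribute `"indices"`.
#' @export
oversample_by_replication <- function(records, labels = NULL,
                                      label_field = NULL) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (is.null(labels)) {
    if (is.null(label_field)) stop("supply labels or label_field")
    labels <- if (is.data.frame(records)) {
      records[[label_field]]
    } else {
      vapply(records, function(r) as.character(r[[label_field]]), character(1))
    }
  }
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels length does not match records")
  counts <- table(labels)
  if (any(counts == 0)) {
    stop("empty class(es): ", paste(names(counts)[counts == 0], collapse = ", "))
  }
  target <- max(counts)
  idx <- unlist(lapply(levels(labels), function(lv) {
    i <- which(labels == lv)
    rep(i, length.out = target)
  }), use.names = FALSE)
  out <- if (is.data.frame(records)) records[idx, , drop = FALSE] else records[idx]
  attr(out, "indices") <- idx
  out
}

# ---- image plumbing ---------------------------------------------------

# Convert a list of (H x W x 3) arrays in [0,1] (or a 4D array) into the
# (H*W*3 x B) matrix layout of the network, resizing (nearest neighbor) to
# the model input size when needed.
images_to_matrix <- function(images, input_dim) {
  if (is.array(images) && length(dim(images)) == 4) {
    images <- lapply(seq_len(dim(images)[4]), function(b) images[, , , b])
  }
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  H <- input_dim[1]; W <- input_dim[2]
  cols <- vapply(images, function(img) {
    d <- dim(img)
    if (d[1] != H || d[2] != W) img <- resize_nearest(img, H, W)
    as.numeric(img)
  }, numeric(H * W * 3))
  matrix(cols, nrow = H * W * 3)
}

resize_nearest <- function(img, H, W) {
  d <- dim(img)
  ri <- pmin(d[1], pmax(1, round(seq(1, d[1], length.out = H))))
  ci <- pmin(d[2], pmax(1, round(seq(1, d[2], length.out = W))))
  img[ri, ci, , drop = FALSE]
}

# Random affine augmentation (rotation / zoom / shrink / horizontal flip)
# of one flattened image column; nearest-neighbor sampling, edge clamping.
augment_batch <- function(X, input_dim, config) {
  aug <- config$augmentation
  if (length(aug) == 0) return(X)
  H <- input_dim[1]; W <- input_dim[2]
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  grid <- expand.grid(r = seq_len(H), c = seq_len(W))
  dr <- grid$r - cr; dc <- grid$c - cc
  for (b in seq_len(ncol(X))) {
    ang <- if ("rotation" %in% aug) {
      stats::runif(1, -config$rotation_range, config$rotation_range) * pi / 180
    } else 0
    zoom <- if (any(c("zoom", "shrink") %in% aug)) {
      stats::runif(1, config$zoom_range[1], config$zoom_range[2])
    } else 1
    flip <- ("flip" %in% aug) && stats::runif(1) < 0.5
    if (ang == 0 && zoom == 1 && !flip) next
    sdc <- if (flip) -dc else dc
    src_r <- round(cr + (cos(ang) * dr - sin(ang) * sdc) / zoom)
    src_c <- round(cc + (sin(ang) * dr + cos(ang) * sdc) / zoom)
    src_r <- pmin(H, pmax(1, src_r))
    src_c <- pmin(W, pmax(1, src_c))
    lin <- src_r + H * (src_c - 1)
    lin3 <- c(lin, lin + H * W, lin + 2 * H * W)
    X[, b] <- X[lin3, b]
  }
  X
}

# ---- training ---------------------------------------------------------

#' Train a classifier
#'
#' Mini-batch Adam training with class-weighted cross entropy (multi-class
#' heads) or weighted binary cross entropy (binary heads). Augmentation is
#' applied to the training split only; frozen layers are never updated.
#'
#' @param model a `color_classifier` from [build_classifier()].
#' @param images training images: list of (H x W x 3) arrays in `[0, 1]`.
#' @param y training labels: class labels (multi-class) or 0/1 (binary head).
#' @param validation optional `list(images =, y =)` held-out split evaluated
#'   each epoch (never augmented).
#' @param config a [train_config()].
#' @return the trained model, with a `history` data.frame (epoch, loss, acc,
#'   val_loss, val_acc).
#' @export
train_classifier <- function(model, images, y, validation = NULL,
                             config = train_config()) {
  set.seed(config$seed)
  multi <- model$activation == "softmax"
  if (multi) {
    y <- as.character(y)
    bad <- setdiff(unique(y), model$labels)
    if (length(bad)) {
      stop("labels outside the model's label space: ",
           paste(bad, collapse = ", "))
    }
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("binary head labels must be 0/1")
  }
  if (!is.null(validation)) {
    if (multi) {
      bad <- setdiff(unique(as.character(validation$y)), model$labels)
      if (length(bad)) {
        stop("validation labels outside the model's label space: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  X <- images_to_matrix(images, model$input_dim)

  # class balancing
  cls <- if (multi) y else ifelse(y == 1, "pos", "neg")
  weights <- rep(1, length(y))
  if (config$balance == "oversample") {
    idx <- attr(oversample_by_replication(seq_along(y), labels = cls),
                "indices")
    X <- X[, idx, drop = FALSE]
    y <- y[idx]
    weights <- rep(1, length(y))
  } else if (config$balance == "class_weight") {
    counts <- table(cls)
    w_by_class <- max(counts) / counts
    weights <- as.numeric(w_by_class[cls])
  }

  n <- ncol(X)
  if (multi) {
    Y <- matrix(0, length(model$labels), n)
    Y[cbind(match(y, model$labels), seq_len(n))] <- 1
  }

  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  if (config$epochs < 1) {
    model$history <- hist
    return(model)
  }

  state <- adam_init(model$layers)
  t_step <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0; ep_w <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1, n)]
      Xb <- augment_batch(X[, bi, drop = FALSE], model$input_dim, config)
      fw <- nn_forward(model$layers, Xb, train = TRUE)
      wb <- weights[bi]
      if (multi) {
        P <- softmax_cols(fw$out)
        Yb <- Y[, bi, drop = FALSE]
        pt <- pmax(colSums(P * Yb), 1e-12)
        loss <- -sum(wb * log(pt)) / sum(wb)
        dZ <- sweep(P - Yb, 2, wb / sum(wb), "*")
        ep_correct <- ep_correct + sum(max.col(t(P)) == max.col(t(Yb)))
      } else {
        p <- sigmoid(fw$out)
        tb <- y[bi]
        pv <- pmin(pmax(ifelse(tb == 1, p, 1 - p), 1e-12), 1)
        loss <- -sum(wb * log(pv)) / sum(wb)
        dZ <- sweep(p - matrix(tb, 1), 2, wb / sum(wb), "*")
        ep_correct <- ep_correct + sum((p > 0.5) == (tb == 1))
      }
      ep_loss <- ep_loss + loss * sum(wb)
      ep_w <- ep_w + sum(wb)
      grads <- nn_backward(model$layers, fw$caches, dZ)
      t_step <- t_step + 1
      upd <- adam_step(model$layers, grads, state, t_step,
                       lr = config$initial_lr)
      model$layers <- upd$layers
      state <- upd$state
    }
    val <- c(NA_real_, NA_real_)
    if (!is.null(validation)) {
      val <- evaluate_loss(model, validation$images, validation$y)
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, loss = ep_loss / ep_w, acc = ep_correct / n,
      val_loss = val[1], val_acc = val[2]
    ))
  }
  model$trained <- TRUE
  model$history <- hist
  model
}

evaluate_loss <- function(model, images, y) {
  P <- predict_proba(model, images)
  if (model$activation == "softmax") {
    yi <- match(as.character(y), model$labels)
    pt <- pmax(P[cbind(seq_len(nrow(P)), yi)], 1e-12)
    c(-mean(log(pt)), mean(max.col(P, ties.method = "first") == yi))
  } else {
    y <- as.numeric(y)
    pv <- pmin(pmax(ifelse(y == 1, P, 1 - P), 1e-12), 1)
    c(-mean(log(pv)), mean((P > 0.5) == (y == 1)))
  }
}

#' Class probabilities from a classifier
#'
#' @param model a `color_classifier`.
#' @param images list of (H x W x 3) arrays (or a single array).
#' @param batch_size internal evaluation batch size.
#' @return multi-class heads: an N x m matrix of softmax probabilities with
#'   the labels as column names (rows sum to 1); binary heads: a numeric
#'   vector of probabilities.
#' @export
predict_proba <- function(model, images, batch_size = 256) {
  X <- images_to_matrix(images, model$input_dim)
  n <- ncol(X)
  outs <- lapply(seq(1, n, by = batch_size), function(start) {
    sub <- X[, start:min(start + batch_size - 1, n), drop = FALSE]
    nn_forward(model$layers, sub, train = FALSE)$out
  })
  Z <- do.call(cbind, outs)
  if (model$activation == "softmax") {
    P <- t(softmax_cols(Z))
    colnames(P) <- model$labels
    P
  } else {
    as.numeric(sigmoid(Z))
  }
}

# ---- S3 modelling interface ------------------------------------------

#' Fit a color-label image classifier
#'
#' One-shot fitting interface: builds a classifier head on the requested
#' backbone and trains it. This is the package's central model-fitting
#' function; [build_classifier()] and [train_classifier()] expose the two
#' stages separately.
#'
#' @inheritParams build_classifier
#' @inheritParams train_classifier
#' @param x training images: list of (H x W x 3) arrays in `[0, 1]`.
#' @param y labels (character/factor for multi-class; 0/1 for a binary head).
#' @param labels label space; defaults to the sorted unique values of `y`.
#' @return a trained `color_classifier`.
#' @examples
#' \donttest{
#' sch <- color_scheme(1, "CF")
#' ds <- generate_dataset(synth_config(n_per_class = 12, image_size = 32,
#'                                     seed = 7), sch)
#' tr <- ds$manifest$split == "train"
#' fit <- color_classifier(ds$images[tr], ds$manifest$cf_primary[tr],
#'                         config = train_config(initial_lr = 1e-3,
#'                                               epochs = 2, input_size = 32))
#' predict(fit, ds$images[!tr], type = "label")
#' }
#' @export
color_classifier <- function(x, y, backbone = "tinycnn", labels = NULL,
                             freeze = freeze_scheme("none"),
                             activation = c("softmax", "sigmoid"),
                             validation = NULL, config = train_config(),
                             dense_units = 512, dropout_p = 0.5) {
  activation <- match.arg(activation)
  if (is.null(labels)) {
    labels <- if (activation == "softmax") sort(unique(as.character(y))) else "positive"
  }
  set.seed(config$seed)
  model <- build_classifier(backbone, labels, freeze = freeze,
                            dense_units = dense_units, dropout_p = dropout_p,
                            activation = activation,
                            input_size = config$input_size)
  train_classifier(model, x, y, validation = validation, config = config)
}

#' @export
print.color_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$layers,
                      function(l) if (is.null(l$W)) 0L else length(l$W) + length(l$b),
                      integer(1)))
  cat(sprintf("Color classifier (%s backbone, %s head)\n",
              x$backbone, x$activation))
  cat(sprintf("  input %dx%dx%d, %d parameters, %d backbone layer(s) frozen\n",
              x$input_dim[1], x$input_dim[2], x$input_dim[3], n_par,
              length(x$frozen_layers)))
  if (x$activation == "softmax") {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  }
  cat(if (isTRUE(x$trained)) {
    sprintf("  trained for %d epoch(s)\n", nrow(x$history))
  } else "  untrained\n")
  invisible(x)
}

#' @export
summary.color_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$history) && nrow(object$history)) {
    h <- object$history
    cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
                h$loss[nrow(h)], h$acc[nrow(h)]))
    if (!is.na(h$val_acc[nrow(h)])) {
      cat(sprintf("  final validation loss %.4f, accuracy %.3f\n",
                  h$val_loss[nrow(h)], h$val_acc[nrow(h)]))
    }
  }
  invisible(object)
}

#' @export
predict.color_classifier <- function(object, newdata,
                                     type = c("prob", "label"), ...) {
  type <- match.arg(type)
  P <- predict_proba(object, newdata)
  if (type == "prob") return(P)
  if (object$activation == "softmax") {
    object$labels[max.col(P, ties.method = "first")]
  } else {
    as.integer(P > 0.5)
  }
}

#' @export
plot.color_classifier <- function(x, ...) {
  h <- x$history
  if (is.null(h) || !nrow(h)) stop("no training history to plot")
  graphics::plot(h$epoch, h$acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", ...)
  if (!all(is.na(h$val_acc))) {
    graphics::lines(h$epoch, h$val_acc, lty = 2)
    graphics::legend("bottomright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(h)
}

#' Write a training history as CSV
#'
#' @param model a trained `color_classifier`.
#' @param path output CSV path.
#' @export
write_history <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
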