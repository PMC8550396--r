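# Minimal feed-forward CNN engine.
#
# Activations travel between layers as matrices of shape (features x batch);
# image-shaped activations use the column-major (height, width, channel)
# linearization, so convolution and pooling work through precomputed index
# vectors (im2col) and BLAS matrix products. Training is plain mini-batch
# Adam with backpropagation. All randomness (weight init, dropout, shuffling)
# goes through R's RNG, so runs are reproducible under set.seed().

lin_index <- function(r, c, ch, H, W) r + H * (c - 1) + H * W * (ch - 1)

# im2col index vector for a valid k x k convolution over (H, W, C):
# length k*k*C * oh*ow, patch entries fast, output position (row-major in
# (oh, ow) column-major order) slow
conv_indices <- function(H, W, C, k) {
  oh <- H - k + 1
  ow <- W - k + 1
  patch <- expand.grid(dr = 0:(k - 1), dc = 0:(k - 1), ch = seq_len(C))
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow))
  idx <- outer(
    lin_index(patch$dr + 1, patch$dc + 1, patch$ch, H, W) - 1,
    lin_index(pos$i, pos$j, 1, H, W),
    "+"
  )
  list(idx = as.integer(idx), oh = oh, ow = ow, kk = nrow(patch))
}

pool_indices <- function(H, W, C) {
  oh <- H %/% 2
  ow <- W %/% 2
  pos <- expand.grid(i = seq_len(oh), j = seq_len(ow), ch = seq_len(C))
  base_r <- 2 * pos$i - 1
  base_c <- 2 * pos$j - 1
  list(
    idx = list(
      lin_index(base_r,     base_c,     pos$ch, H, W),
      lin_index(base_r + 1, base_c,     pos$ch, H, W),
      lin_index(base_r,     base_c + 1, pos$ch, H, W),
      lin_index(base_r + 1, base_c + 1, pos$ch, H, W)
    ),
    oh = oh, ow = ow
  )
}

he_init <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

# Instantiate a network from layer specs. Each spec is one of
#   list(op = "conv", filters, k), list(op = "relu"), list(op = "pool"),
#   list(op = "flatten"), list(op = "dense", units), list(op = "dropout", p)
# input_dim is c(H, W, C). Weights are drawn from the current RNG.
build_network <- function(specs, input_dim) {
  dim_cur <- input_dim
  flat <- FALSE
  layers <- vector("list", length(specs))
  for (s in seq_along(specs)) {
    spec <- specs[[s]]
    layer <- switch(spec$op,
      conv = {
        stopifnot(!flat)
        ci <- conv_indices(dim_cur[1], dim_cur[2], dim_cur[3], spec$k)
        l <- list(type = "conv", W = he_init(spec$filters, ci$kk),
                  b = numeric(spec$filters), idx = ci$idx, kk = ci$kk,
                  P = ci$oh * ci$ow, trainable = TRUE)
        dim_cur <- c(ci$oh, ci$ow, spec$filters)
        l
      },
      relu = list(type = "relu"),
      pool = {
        stopifnot(!flat)
        pi <- pool_indices(dim_cur[1], dim_cur[2], dim_cur[3])
        l <- list(type = "pool", idx = pi$idx,
                  n_in = prod(dim_cur), trainable = FALSE)
        dim_cur <- c(pi$oh, pi$ow, dim_cur[3])
        l
      },
      flatten = {
        flat <- TRUE
        list(type = "flatten")
      },
      dense = {
        nin <- prod(dim_cur)
        l <- list(type = "dense", W = he_init(spec$units, nin),
                  b = numeric(spec$units), trainable = TRUE)
        dim_cur <- spec$units
        l
      },
      dropout = list(type = "dropout", p = spec$p),
      stop("unknown layer op: ", spec$op)
    )
    layers[[s]] <- layer
  }
  list(layers = layers, out_dim = prod(dim_cur))
}

nn_forward <- function(layers, X, train = FALSE) {
  caches <- vector("list", length(layers))
  for (s in seq_along(layers)) {
    l <- layers[[s]]
    if (l$type == "conv") {
      B <- ncol(X)
      colsm <- matrix(X[l$idx, , drop = FALSE], l$kk, l$P * B)
      y <- l$W %*% colsm + l$b
      out <- matrix(aperm(array(y, c(nrow(l$W), l$P, B)), c(2, 1, 3)),
                    l$P * nrow(l$W), B)
      caches[[s]] <- list(cols = colsm, n_in = nrow(X))
      X <- out
    } else if (l$type == "relu") {
      mask <- X > 0
      X <- X * mask
      caches[[s]] <- mask
    } else if (l$type == "pool") {
      x1 <- X[l$idx[[1]], , drop = FALSE]
      x2 <- X[l$idx[[2]], , drop = FALSE]
      x3 <- X[l$idx[[3]], , drop = FALSE]
      x4 <- X[l$idx[[4]], , drop = FALSE]
      y <- pmax(x1, x2, x3, x4)
      if (train) {
        m1 <- x1 == y
        m2 <- (x2 == y) & !m1
        m3 <- (x3 == y) & !(m1 | m2)
        m4 <- (x4 == y) & !(m1 | m2 | m3)
        caches[[s]] <- list(masks = list(m1, m2, m3, m4))
      }
      X <- y
    } else if (l$type == "flatten") {
      # no-op: activations are already flat matrices
    } else if (l$type == "dense") {
      caches[[s]] <- X
      X <- l$W %*% X + l$b
    } else if (l$type == "dropout") {
      if (train) {
        mask <- matrix(stats::runif(length(X)) >= l$p, nrow(X), ncol(X))
        X <- X * mask / (1 - l$p)
        caches[[s]] <- mask
      }
    }
  }
  list(out = X, caches = caches)
}

# Backward pass from the gradient w.r.t. the network output (pre-activation
# of the final layer is handled by the caller through dZ). Returns gradients
# per layer (NULL for parameterless layers) and does not modify the layers.
nn_backward <- function(layers, caches, dZ) {
  grads <- vector("list", length(layers))
  dX <- dZ
  for (s in rev(seq_along(layers))) {
    l <- layers[[s]]
    if (l$type == "conv") {
      B <- ncol(dX)
      Fn <- nrow(l$W)
      dym <- matrix(aperm(array(dX, c(l$P, Fn, B)), c(2, 1, 3)),
                    Fn, l$P * B)
      cache <- caches[[s]]
      grads[[s]] <- list(
        dW = dym %*% t(cache$cols),
        db = rowSums(dym)
      )
      dcols <- crossprod(l$W, dym)
      dcols <- matrix(dcols, l$kk * l$P, B)
      dX <- rowsum(dcols, group = l$idx, reorder = TRUE)
      # rowsum drops rows never indexed; for valid conv every input unit is
      # covered, so rows are exactly 1..n_in in order
      if (nrow(dX) != cache$n_in) {
        full <- matrix(0, cache$n_in, B)
        full[as.integer(rownames(dX)), ] <- dX
        dX <- full
      }
    } else if (l$type == "relu") {
      dX <- dX * caches[[s]]
    } else if (l$type == "pool") {
      masks <- caches[[s]]$masks
      dprev <- matrix(0, l$n_in, ncol(dX))
      for (q in 1:4) {
        dprev[l$idx[[q]], ] <- dX * masks[[q]]
      }
      dX <- dprev
    } else if (l$type == "flatten") {
      # no-op
    } else if (l$type == "dense") {
      Xin <- caches[[s]]
      grads[[s]] <- list(dW = dX %*% t(Xin), db = rowSums(dX))
      dX <- crossprod(l$W, dX)
    } else if (l$type == "dropout") {
      if (!is.null(caches[[s]])) dX <- dX * caches[[s]] / (1 - l$p)
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    } else NULL
  })
}

adam_step <- function(layers, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (s in seq_along(layers)) {
    l <- layers[[s]]
    if (is.null(l$W) || !isTRUE(l$trainable) || is.null(grads[[s]])) next
    st <- state[[s]]
    g <- grads[[s]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * g$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$db
    st$vb <- beta2 * st$vb + (1 - beta2) * g$db^2
    mW_hat <- st$mW / (1 - beta1^t)
    vW_hat <- st$vW / (1 - beta2^t)
    mb_hat <- st$mb / (1 - beta1^t)
    vb_hat <- st$vb / (1 - beta2^t)
    l$W <- l$W - lr * mW_hat / (sqrt(vW_hat) + eps)
    l$b <- l$b - lr * mb_hat / (sqrt(vb_hat) + eps)
    layers[[s]] <- l
    state[[s]] <- st
  }
  list(layers = layers, state = state)
}

softmax_cols <- function(Z) {
  Z <- exp(sweep(Z, 2, apply(Z, 2, max)))
  sweep(Z, 2, colSums(Z), "/")
}

sigmoid <- function(z) 1 / (1 + exp(-z))
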