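# Residual convolutional backbone, implemented with im2col + BLAS matrix
# products. Image batches are 4-D arrays (H, W, C, N) with values in [0, 1].
# The network is small by design: two stride-2 convs, two identity-shortcut
# residual blocks (widths 16/32), global average pooling, then the head
# FC128 -> ReLU -> BatchNorm -> FC(m) -> softmax. The FC128 linear output is
# the feature layer tapped for the randomized-network members.

.conv_idx_cache <- new.env(parent = emptyenv())

# Patch-gather index matrix for im2col: rows = output positions (row-major
# over (Ho, Wo) in column-major array order), cols = k*k*C patch entries,
# values = linear indices into the padded (Hp, Wp, C) array.
conv_indices <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2 * pad; Wp <- W + 2 * pad
  Ho <- (Hp - k) %/% stride + 1
  Wo <- (Wp - k) %/% stride + 1
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  ti <- (oi - 1) * stride + 1
  tj <- (oj - 1) * stride + 1
  di <- rep(seq_len(k) - 1L, times = k * C)
  dj <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  dc <- rep(seq_len(C) - 1L, each = k * k)
  rows <- outer(ti, di, "+")
  cols <- outer(tj, dj, "+")
  idx <- rows + (cols - 1) * Hp +
    matrix(dc * (Hp * Wp), nrow = Ho * Wo, ncol = k * k * C, byrow = TRUE)
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              P = Ho * Wo, kkC = k * k * C)
  .conv_idx_cache[[key]] <- out
  out
}

# Batch-expanded gather indices, cached per (shape, N): row blocks per
# image, each offset into its image's slice of the padded batch array.
conv_indices_batch <- function(ci, C, N) {
  key <- paste("b", ci$Hp, ci$Wp, C, ci$P, ci$kkC, N, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  offs <- as.integer((seq_len(N) - 1) * (ci$Hp * ci$Wp * C))
  IDX <- ci$idx[rep(seq_len(ci$P), N), , drop = FALSE] +
    offs[rep(seq_len(N), each = ci$P)]
  .conv_idx_cache[[key]] <- IDX
  IDX
}

pad_batch <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# Forward convolution. W is (k*k*C_in) x C_out, b length C_out.
conv_forward <- function(x, W, b, stride = 1, pad = 1, keep_cache = TRUE) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  k <- as.integer(sqrt(nrow(W) / C))
  stopifnot(k * k * C == nrow(W))
  ci <- conv_indices(H, Wd, C, k, stride, pad)
  xp <- pad_batch(x, pad)
  IDX <- conv_indices_batch(ci, C, N)
  Xcol <- xp[IDX]
  dim(Xcol) <- c(ci$P * N, ci$kkC)
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = nrow(Y))
  out <- aperm(array(Y, c(ci$Ho, ci$Wo, N, ncol(W))), c(1, 2, 4, 3))
  cache <- if (keep_cache) {
    list(Xcol = Xcol, IDX = IDX, W = W, in_dim = d, ci = ci, pad = pad,
         Cout = ncol(W))
  } else NULL
  list(out = out, cache = cache)
}

# Backward convolution: gradients w.r.t. weights, bias and input.
conv_backward <- function(dY, cache, need_dx = TRUE) {
  ci <- cache$ci
  d <- cache$in_dim
  N <- d[4]
  dYmat <- aperm(dY, c(1, 2, 4, 3))
  dim(dYmat) <- c(ci$P * N, cache$Cout)
  dW <- crossprod(cache$Xcol, dYmat)
  db <- colSums(dYmat)
  dx <- NULL
  if (need_dx) {
    dXcol <- dYmat %*% t(cache$W)
    # col2im: within one patch-offset column the gather indices are
    # distinct (different output positions read different pixels), so
    # accumulation is collision-free column by column.
    dxp <- numeric(ci$Hp * ci$Wp * d[3] * N)
    for (j in seq_len(ci$kkC)) {
      jj <- cache$IDX[, j]
      dxp[jj] <- dxp[jj] + dXcol[, j]
    }
    dxp <- array(dxp, c(ci$Hp, ci$Wp, d[3], N))
    p <- cache$pad
    dx <- if (p > 0) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
          else dxp
  }
  list(dW = dW, db = db, dx = dx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Residual block: identity shortcut around an inner transform
#'
#' The residual-learning identity: the block output is
#' `inner_transform(X) + X`, so a zero inner transform leaves the input
#' unchanged and stacking such blocks can never degrade the identity map.
#'
#' @param X numeric array or matrix.
#' @param inner_transform a function whose output has the same shape as its
#'   input (the learned residual).
#' @return `inner_transform(X) + X`.
#' @examples
#' residual_block(matrix(1:4, 2), function(x) 0 * x)  # identity mapping
#' @export
residual_block <- function(X, inner_transform) {
  E <- inner_transform(X)
  if (!identical(dim(E), dim(X)) || length(E) != length(X)) {
    stop("residual_block: inner transform changed the shape (",
         paste(dim(E), collapse = "x"), " vs ",
         paste(dim(X), collapse = "x"), ")")
  }
  E + X
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build a feature-extraction backbone with the modified head
#'
#' Constructs the backbone with its classifier head replaced by
#' `FC128 -> ReLU -> BatchNorm -> FC(num_classes) -> softmax`; the FC128
#' linear output is the feature layer used downstream. `tiny_resnet` is a
#' compact residual network (two stride-2 convolutions, two
#' identity-shortcut residual blocks of widths 16 and 32, global average
#' pooling) trainable in seconds on a CPU. The `resnet50_pretrained` tag is
#' reserved for an ImageNet-pretrained backbone and raises an error when no
#' pretrained weight source is available.
#'
#' @param base backbone tag, `"tiny_resnet"` or `"resnet50_pretrained"`.
#' @param num_classes number of output classes (>= 2).
#' @param input_size square input side in pixels (>= 32; default 64).
#' @param seed seed for the weight initialization.
#' @return object of class `rernet_backbone`.
#' @export
build_extractor <- function(base = "tiny_resnet", num_classes = 3,
                            input_size = 64, seed = 1) {
  if (num_classes < 2) stop("build_extractor: num_classes must be >= 2")
  if (identical(base, "resnet50_pretrained")) {
    stop("build_extractor: pretrained ResNet50 weights are not bundled; ",
         "use base = \"tiny_resnet\"")
  }
  if (!identical(base, "tiny_resnet")) {
    stop("build_extractor: unknown backbone tag '", base, "'")
  }
  if (input_size < 32) stop("build_extractor: input_size must be >= 32")
  w1 <- 16L; w2 <- 32L; k <- 3L
  params <- with_seed(seed, list(
    conv1_W = he_init(k * k * 3, w1, k * k * 3),   conv1_b = numeric(w1),
    b1A_W   = he_init(k * k * w1, w1, k * k * w1), b1A_b = numeric(w1),
    b1B_W   = he_init(k * k * w1, w1, k * k * w1), b1B_b = numeric(w1),
    conv2_W = he_init(k * k * w1, w2, k * k * w1), conv2_b = numeric(w2),
    b2A_W   = he_init(k * k * w2, w2, k * k * w2), b2A_b = numeric(w2),
    b2B_W   = he_init(k * k * w2, w2, k * k * w2), b2B_b = numeric(w2),
    fc1_W   = he_init(w2, 128, w2),                fc1_b = numeric(128),
    bn_gamma = rep(1, 128), bn_beta = numeric(128),
    fc2_W   = he_init(128, num_classes, 128),      fc2_b = numeric(num_classes)
  ))
  structure(list(base = base, params = params,
                 input_mean = rep(0.5, 3),
                 bn_mean = numeric(128), bn_var = rep(1, 128),
                 bn_eps = 1e-5, bn_momentum = 0.1,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 feature_layer = "fc128", feature_dim = 128L,
                 seed = as.integer(seed)),
            class = "rernet_backbone")
}

#' @export
print.rernet_backbone <- function(x, ...) {
  cat(sprintf("<rernet_backbone %s: input %dx%dx3, %d classes, feature layer %s (128)>\n",
              x$base, x$input_size, x$input_size, x$num_classes,
              x$feature_layer))
  invisible(x)
}

# Full forward pass. mode "train" uses batch statistics in the head
# BatchNorm (and updates running stats when update_stats), "infer" uses the
# stored running statistics so outputs are batch-size independent.
backbone_forward <- function(model, x, mode = c("infer", "train"),
                             keep_cache = FALSE, update_stats = FALSE) {
  mode <- match.arg(mode)
  p <- model$params
  N <- dim(x)[4]
  kc <- keep_cache
  # per-channel input centering: zero padding is then neutral relative to
  # the typical background, avoiding spurious border edge responses
  for (ch in 1:3) x[, , ch, ] <- x[, , ch, ] - model$input_mean[ch]
  c1 <- conv_forward(x, p$conv1_W, p$conv1_b, stride = 2, pad = 1, kc)
  a1 <- relu(c1$out)
  # residual block 1
  bA <- conv_forward(a1, p$b1A_W, p$b1A_b, 1, 1, kc); u1 <- relu(bA$out)
  bB <- conv_forward(u1, p$b1B_W, p$b1B_b, 1, 1, kc)
  s1 <- bB$out + a1; a2 <- relu(s1)
  c2 <- conv_forward(a2, p$conv2_W, p$conv2_b, 2, 1, kc)
  a3 <- relu(c2$out)
  # residual block 2
  cA <- conv_forward(a3, p$b2A_W, p$b2A_b, 1, 1, kc); u2 <- relu(cA$out)
  cB <- conv_forward(u2, p$b2B_W, p$b2B_b, 1, 1, kc)
  s2 <- cB$out + a3; a4 <- relu(s2)
  # global average pool -> N x C
  d4 <- dim(a4)
  f <- t(matrix(colMeans(matrix(a4, d4[1] * d4[2], d4[3] * d4[4])),
                d4[3], d4[4]))
  feat <- sweep(f %*% p$fc1_W, 2, p$fc1_b, "+")  # FC128 feature layer
  r <- relu(feat)
  if (mode == "train") {
    mu <- colMeans(r)
    va <- colMeans(r^2) - mu^2
    if (update_stats) {
      mom <- model$bn_momentum
      model$bn_mean <- (1 - mom) * model$bn_mean + mom * mu
      model$bn_var <- (1 - mom) * model$bn_var + mom * va * N / max(N - 1, 1)
    }
  } else {
    mu <- model$bn_mean
    va <- model$bn_var
  }
  inv_sd <- 1 / sqrt(va + model$bn_eps)
  xhat <- sweep(sweep(r, 2, mu, "-"), 2, inv_sd, "*")
  bn <- sweep(sweep(xhat, 2, p$bn_gamma, "*"), 2, p$bn_beta, "+")
  logits <- sweep(bn %*% p$fc2_W, 2, p$fc2_b, "+")
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  res <- list(logits = logits, probs = probs, feat = feat, model = model)
  if (keep_cache) {
    res$cache <- list(c1 = c1$cache, a1 = a1, bA = bA$cache, u1 = u1,
                      bB = bB$cache, s1 = s1, a2 = a2, c2 = c2$cache,
                      a3 = a3, cA = cA$cache, u2 = u2, cB = cB$cache,
                      s2 = s2, a4 = a4, f = f, feat = feat, r = r,
                      xhat = xhat, mu = mu, inv_sd = inv_sd, N = N,
                      gap_hw = d4[1] * d4[2])
  }
  res
}

# Backward pass from softmax cross-entropy; returns gradient list with the
# same names as model$params.
backbone_backward <- function(model, fw, Y) {
  p <- model$params
  cc <- fw$cache
  N <- cc$N
  g <- list()
  dlogits <- (fw$probs - Y) / N
  bn_out <- sweep(sweep(cc$xhat, 2, p$bn_gamma, "*"), 2, p$bn_beta, "+")
  g$fc2_W <- crossprod(bn_out, dlogits)
  g$fc2_b <- colSums(dlogits)
  dbn <- dlogits %*% t(p$fc2_W)
  g$bn_gamma <- colSums(dbn * cc$xhat)
  g$bn_beta <- colSums(dbn)
  dxhat <- sweep(dbn, 2, p$bn_gamma, "*")
  # batch-norm backward (training statistics)
  K <- ncol(dxhat)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cc$xhat)
  dr <- sweep(N * dxhat -
                matrix(sum_dxhat, N, K, byrow = TRUE) -
                cc$xhat * matrix(sum_dxhat_xhat, N, K, byrow = TRUE),
              2, cc$inv_sd / N, "*")
  dfeat <- dr * (cc$feat > 0)
  g$fc1_W <- crossprod(cc$f, dfeat)
  g$fc1_b <- colSums(dfeat)
  df <- dfeat %*% t(p$fc1_W)  # N x C2
  # un-pool: every spatial position gets df/(H*W)
  d4 <- dim(cc$a4)
  da4 <- array(rep(t(df) / cc$gap_hw, each = cc$gap_hw), d4)
  ds2 <- da4 * (cc$s2 > 0)
  bcB <- conv_backward(ds2, cc$cB)
  g$b2B_W <- bcB$dW; g$b2B_b <- bcB$db
  du2 <- bcB$dx * (cc$u2 > 0)
  bcA <- conv_backward(du2, cc$cA)
  g$b2A_W <- bcA$dW; g$b2A_b <- bcA$db
  da3 <- bcA$dx + ds2                      # shortcut
  dz2 <- da3 * (cc$a3 > 0)
  bc2 <- conv_backward(dz2, cc$c2)
  g$conv2_W <- bc2$dW; g$conv2_b <- bc2$db
  ds1 <- bc2$dx * (cc$s1 > 0)
  bbB <- conv_backward(ds1, cc$bB)
  g$b1B_W <- bbB$dW; g$b1B_b <- bbB$db
  du1 <- bbB$dx * (cc$u1 > 0)
  bbA <- conv_backward(du1, cc$bA)
  g$b1A_W <- bbA$dW; g$b1A_b <- bbA$db
  da1 <- bbA$dx + ds1
  dz1 <- da1 * (cc$a1 > 0)
  bc1 <- conv_backward(dz1, cc$c1, need_dx = FALSE)
  g$conv1_W <- bc1$dW; g$conv1_b <- bc1$db
  g
}

cross_entropy <- function(probs, Y) {
  -mean(log(rowSums(probs * Y) + 1e-12))
}

#' Backbone training configuration
#'
#' Defaults mirror the published fine-tuning recipe: mini-batch size 10,
#' 2 epochs (short on purpose, to avoid overfitting a small dataset),
#' initial learning rate 1e-4. The optimizer is stochastic gradient descent
#' with momentum 0.9.
#'
#' @param mini_batch mini-batch size.
#' @param max_epoch number of passes over the data.
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient.
#' @param seed seed controlling the shuffle order.
#' @return a `train_config` list.
#' @export
train_config <- function(mini_batch = 10, max_epoch = 2,
                         learning_rate = 1e-4, momentum = 0.9, seed = 1) {
  stopifnot(mini_batch >= 1, max_epoch >= 0, learning_rate >= 0,
            momentum >= 0, momentum < 1)
  structure(list(mini_batch = as.integer(mini_batch),
                 max_epoch = as.integer(max_epoch),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Fine-tune the backbone on labeled images
#'
#' Minimizes softmax cross-entropy by mini-batch SGD with momentum for
#' exactly `cfg$max_epoch` passes (`max_epoch * ceiling(N / mini_batch)`
#' parameter updates). The shuffle order is seeded, so identical data,
#' config and seed give identical trained weights.
#'
#' @param model an `rernet_backbone`.
#' @param images 4-D array (H, W, 3, N), values in `[0, 1]`.
#' @param labels integer vector of 0-based class codes, length N.
#' @param cfg a [train_config()].
#' @return the trained `rernet_backbone`, with attribute `history` (list
#'   with per-update `loss` and `n_updates`).
#' @export
fine_tune <- function(model, images, labels, cfg = train_config()) {
  stopifnot(inherits(model, "rernet_backbone"))
  if (is.null(labels)) stop("fine_tune: labels are required")
  labels <- as.integer(labels)
  N <- dim(images)[4]
  stopifnot(length(labels) == N, N >= 1)
  Yall <- one_hot_encode(labels, model$num_classes)
  # input normalization constants from the training data (per channel)
  model$input_mean <- vapply(1:3, function(ch) mean(images[, , ch, ]),
                             numeric(1))
  vel <- lapply(model$params, function(w) w * 0)
  losses <- numeric(0)
  n_updates <- 0L
  for (epoch in seq_len(cfg$max_epoch)) {
    ord <- with_seed(derive_seed(cfg$seed, 17, epoch), sample.int(N))
    starts <- seq(1, N, by = cfg$mini_batch)
    for (s in starts) {
      idx <- ord[s:min(s + cfg$mini_batch - 1, N)]
      xb <- images[, , , idx, drop = FALSE]
      yb <- Yall[idx, , drop = FALSE]
      fw <- backbone_forward(model, xb, mode = "train", keep_cache = TRUE,
                             update_stats = TRUE)
      model <- fw$model  # running BN stats updated
      grads <- backbone_backward(model, fw, yb)
      for (nm in names(model$params)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * grads[[nm]]
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
      losses <- c(losses, cross_entropy(fw$probs, yb))
      n_updates <- n_updates + 1L
    }
  }
  # Re-estimate the head BatchNorm statistics exactly over the training
  # set: the exponential running average lags the fast-moving feature
  # means of a short fine-tune, and the FC128 activations have small
  # within-batch variance, so stale statistics would distort inference.
  if (n_updates > 0) {
    r_all <- matrix(0, N, 128)
    for (s in seq(1, N, by = 64)) {
      idx <- s:min(s + 63, N)
      fw <- backbone_forward(model, images[, , , idx, drop = FALSE],
                             mode = "infer")
      r_all[idx, ] <- pmax(fw$feat, 0)
    }
    model$bn_mean <- colMeans(r_all)
    model$bn_var <- colMeans(sweep(r_all, 2, model$bn_mean, "-")^2) *
      N / max(N - 1, 1)
  }
  attr(model, "history") <- list(loss = losses, n_updates = n_updates)
  model
}

#' Extract feature-layer activations for a batch of images
#'
#' Runs the backbone in inference mode (BatchNorm uses stored running
#' statistics, so features do not depend on batch composition) and returns
#' the N x 128 matrix of FC128 feature-layer outputs.
#'
#' @param model an `rernet_backbone`.
#' @param images 4-D array (H, W, 3, N).
#' @param batch_size images per forward chunk.
#' @return N x 128 numeric feature matrix.
#' @export
extract_features <- function(model, images, batch_size = 64) {
  stopifnot(inherits(model, "rernet_backbone"))
  d <- dim(images)
  if (length(d) == 3) { dim(images) <- c(d, 1); d <- dim(images) }
  if (d[1] != model$input_size || d[2] != model$input_size || d[3] != 3) {
    stop("extract_features: expected ", model$input_size, "x",
         model$input_size, "x3 images, got ", paste(d[1:3], collapse = "x"))
  }
  N <- d[4]
  out <- matrix(0, N, model$feature_dim)
  for (s in seq(1, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, N)
    fw <- backbone_forward(model, images[, , , idx, drop = FALSE],
                           mode = "infer")
    out[idx, ] <- fw$feat
  }
  out
}

#' Classify images directly with the backbone head
#'
#' Softmax probabilities from the full modified head; used mainly for
#' monitoring the fine-tune, since final classification goes through the
#' randomized-network ensemble.
#'
#' @inheritParams extract_features
#' @return N x num_classes probability matrix.
#' @export
backbone_probs <- function(model, images, batch_size = 64) {
  d <- dim(images)
  if (length(d) == 3) dim(images) <- c(d, 1)
  N <- dim(images)[4]
  out <- matrix(0, N, model$num_classes)
  for (s in seq(1, N, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, N)
    out[idx, ] <- backbone_forward(model, images[, , , idx, drop = FALSE],
                                   mode = "infer")$probs
  }
  out
}
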