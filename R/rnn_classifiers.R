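#' One-hot encode integer class labels
#'
#' Builds the N x m binary target matrix with exactly one 1 per row. Labels
#' are 0-based codes matching one-hot column order (code 0 = first class).
#'
#' @param labels integer vector of class codes in `0 .. m-1`.
#' @param m number of classes (>= 2).
#' @return N x m binary matrix.
#' @examples
#' one_hot_encode(c(0, 1, 2), 3)  # identity
#' @export
one_hot_encode <- function(labels, m) {
  labels <- as.integer(labels)
  if (m < 2) stop("one_hot_encode: m must be >= 2")
  bad <- which(is.na(labels) | labels < 0 | labels >= m)
  if (length(bad)) {
    stop("one_hot_encode: label out of range {0,...,", m - 1,
         "} at index ", bad[1], " (value ", labels[bad[1]], ")")
  }
  H <- matrix(0, length(labels), m)
  H[cbind(seq_along(labels), labels + 1L)] <- 1
  H
}

activation_fun <- function(tag) {
  switch(tag,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = base::tanh,
    stop("unknown activation '", tag, "' (use \"sigmoid\" or \"tanh\")")
  )
}

#' Random hidden-layer specification
#'
#' Describes one random, frozen hidden layer: `v` nodes, a bounded monotone
#' activation (sigmoid by default), and input weights / biases drawn once
#' from uniform(-1, 1) under `seed` and never updated by fitting.
#'
#' @param v hidden-node count (the only tuned hyperparameter; default 400).
#' @param activation "sigmoid" (default) or "tanh".
#' @param seed integer seed for the weight draw.
#' @param weight_range length-2 numeric range of the uniform weight draw.
#' @return object of class `rnn_hidden_spec`.
#' @export
rnn_hidden_spec <- function(v = 400, activation = "sigmoid", seed = 1,
                            weight_range = c(-1, 1)) {
  stopifnot(length(v) == 1, v >= 1, length(weight_range) == 2,
            weight_range[1] < weight_range[2])
  activation_fun(activation)  # validate tag early
  structure(list(v = as.integer(v), activation = activation,
                 seed = as.integer(seed), weight_range = weight_range),
            class = "rnn_hidden_spec")
}

# Draw the frozen weights W (n_in x v) and biases c (length v) for a spec.
materialize_hidden <- function(spec, n_in) {
  lo <- spec$weight_range[1]
  hi <- spec$weight_range[2]
  with_seed(spec$seed, {
    W <- matrix(runif(n_in * spec$v, lo, hi), n_in, spec$v)
    b <- runif(spec$v, lo, hi)
    list(W = W, b = b, v = spec$v, n_in = n_in, activation = spec$activation)
  })
}

#' Hidden-layer activations
#'
#' Entry (i, j) is `g(b_j . x_i + c_j)` for materialized weights `b_j`
#' (columns of `hidden$W`) and biases `c_j` (`hidden$b`); deterministic
#' given the materialized layer.
#'
#' @param X numeric feature matrix, N x n.
#' @param hidden materialized hidden layer (from a fit, or
#'   [rnn_hidden_spec()] weights drawn internally by the fit functions).
#' @return N x v activation matrix.
#' @export
hidden_activations <- function(X, hidden) {
  X <- as.matrix(X)
  if (ncol(X) != hidden$n_in) {
    stop("hidden_activations: input width ", ncol(X),
         " does not match hidden layer input width ", hidden$n_in)
  }
  g <- activation_fun(hidden$activation)
  Z <- X %*% hidden$W
  Z <- sweep(Z, 2, hidden$b, "+")
  g(Z)
}

check_xy <- function(X, H) {
  X <- as.matrix(X)
  H <- as.matrix(H)
  if (nrow(X) != nrow(H)) stop("feature/target row-count mismatch")
  if (!all(is.finite(X))) stop("non-finite feature values")
  rs <- rowSums(H)
  if (any(abs(rs - 1) > 1e-8) || any(H != 0 & H != 1)) {
    stop("targets must be one-hot rows (exactly one 1 per row)")
  }
  list(X = X, H = H)
}

new_trained_rnn <- function(kind, hidden, d, e = NULL, n, m, extra = list()) {
  structure(c(list(kind = kind, hidden = hidden, d = d, e = e,
                   n = n, m = m), extra),
            class = "trained_rnn")
}

#' @export
print.trained_rnn <- function(x, ...) {
  cat(sprintf("<trained_rnn %s: n=%d, m=%d, %s>\n", x$kind, x$n, x$m,
              if (x$kind == "dRVFL") {
                sprintf("l=%d, v=%d per layer", length(x$hidden), x$hidden[[1]]$v)
              } else sprintf("v=%d", x$hidden$v)))
  invisible(x)
}

#' Fit an extreme learning machine
#'
#' Draws the hidden weights from the spec's seeded distribution, freezes
#' them, and solves the output weights in one pseudoinverse step
#' `d = M^+ H` where `M` is the hidden activation matrix. With `v` hidden
#' nodes the network can exactly interpolate `v` distinct observations.
#'
#' @param X N x n feature matrix.
#' @param H N x m one-hot target matrix (see [one_hot_encode()]).
#' @param spec an [rnn_hidden_spec()].
#' @param ridge optional ridge penalty passed to [pinv_solve()].
#' @return object of class `trained_rnn` with `kind = "ELM"`.
#' @export
fit_elm <- function(X, H, spec = rnn_hidden_spec(), ridge = 0) {
  xy <- check_xy(X, H)
  hid <- materialize_hidden(spec, ncol(xy$X))
  M <- hidden_activations(xy$X, hid)
  d <- pinv_solve(M, xy$H, ridge = ridge)
  new_trained_rnn("ELM", hid, d, NULL, ncol(xy$X), ncol(xy$H))
}

#' Fit a Schmidt neural network
#'
#' Identical to the extreme learning machine except for a learned output
#' bias: `(d, e)` are solved jointly by appending a constant-1 column to
#' the hidden activation matrix before the pseudoinverse solve, so the
#' last augmented row is the bias `e`.
#'
#' @inheritParams fit_elm
#' @return object of class `trained_rnn` with `kind = "SNN"` and bias `e`.
#' @export
fit_snn <- function(X, H, spec = rnn_hidden_spec(), ridge = 0) {
  xy <- check_xy(X, H)
  hid <- materialize_hidden(spec, ncol(xy$X))
  M <- hidden_activations(xy$X, hid)
  sol <- pinv_solve(cbind(M, 1), xy$H, ridge = ridge)
  v <- hid$v
  new_trained_rnn("SNN", hid, sol[seq_len(v), , drop = FALSE],
                  sol[v + 1, ], ncol(xy$X), ncol(xy$H))
}

#' Deep RVFL layer parameters
#'
#' `l` stacked random hidden layers; layer 1 consumes the raw input, each
#' deeper layer consumes the previous layer's activations. Each layer gets
#' an independent seeded weight draw (seeds derived from `seed`) unless
#' `share_deep_weights = TRUE`, in which case layers 2..l share a single
#' v-by-v draw.
#'
#' @param l number of hidden layers (default 3).
#' @param v hidden nodes per layer (default 400).
#' @param activation activation tag.
#' @param seed base seed; per-layer seeds are derived from it.
#' @param share_deep_weights logical; see description.
#' @return object of class `drvfl_params`.
#' @export
drvfl_params <- function(l = 3, v = 400, activation = "sigmoid", seed = 1,
                         share_deep_weights = FALSE) {
  stopifnot(l >= 1)
  specs <- lapply(seq_len(l), function(i) {
    rnn_hidden_spec(v = v, activation = activation,
                    seed = derive_seed(seed, 101, i))
  })
  structure(list(l = as.integer(l), specs = specs,
                 share_deep_weights = isTRUE(share_deep_weights)),
            class = "drvfl_params")
}

# Materialize all dRVFL layers and return activations plus frozen weights.
drvfl_forward <- function(X, layers) {
  acts <- vector("list", length(layers))
  inp <- X
  for (i in seq_along(layers)) {
    acts[[i]] <- hidden_activations(inp, layers[[i]])
    inp <- acts[[i]]
  }
  acts
}

#' Fit a deep random vector functional link network
#'
#' Stacks `l` random frozen hidden layers; the output layer consumes the
#' horizontal concatenation of the raw input and every layer's activations
#' (direct links), `T = [X | M^1 | ... | M^l]` of width `n + l v`, and its
#' weights are solved as `d = T^+ H`.
#'
#' @inheritParams fit_elm
#' @param params a [drvfl_params()].
#' @return object of class `trained_rnn` with `kind = "dRVFL"`; `hidden`
#'   is the list of materialized layers.
#' @export
fit_drvfl <- function(X, H, params = drvfl_params(), ridge = 0) {
  xy <- check_xy(X, H)
  n <- ncol(xy$X)
  layers <- vector("list", params$l)
  layers[[1]] <- materialize_hidden(params$specs[[1]], n)
  if (params$l >= 2) {
    shared <- if (params$share_deep_weights) {
      materialize_hidden(params$specs[[2]], layers[[1]]$v)
    } else NULL
    for (i in 2:params$l) {
      layers[[i]] <- if (params$share_deep_weights) shared
                     else materialize_hidden(params$specs[[i]], layers[[i - 1]]$v)
    }
  }
  acts <- drvfl_forward(xy$X, layers)
  Tmat <- do.call(cbind, c(list(xy$X), acts))
  d <- pinv_solve(Tmat, xy$H, ridge = ridge)
  new_trained_rnn("dRVFL", layers, d, NULL, n, ncol(xy$H),
                  extra = list(l = params$l))
}

#' Raw output scores of a trained randomized network
#'
#' Deterministic forward pass: `M d` (ELM), `M d + 1 e'` (SNN), or `T d`
#' (dRVFL) on the frozen hidden weights.
#'
#' @param model a `trained_rnn`.
#' @param X N x n feature matrix; width must match the model.
#' @return N x m numeric score matrix.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "trained_rnn"))
  X <- as.matrix(X)
  if (ncol(X) != model$n) {
    stop("predict_scores: feature width ", ncol(X),
         " does not match model input width ", model$n)
  }
  if (model$kind == "dRVFL") {
    acts <- drvfl_forward(X, model$hidden)
    S <- do.call(cbind, c(list(X), acts)) %*% model$d
  } else {
    M <- hidden_activations(X, model$hidden)
    S <- M %*% model$d
    if (model$kind == "SNN") S <- sweep(S, 2, model$e, "+")
  }
  S
}

#' Hard class labels of a trained randomized network
#'
#' Argmax over the m score columns; ties break toward the lowest class
#' index so predictions are deterministic.
#'
#' @inheritParams predict_scores
#' @return integer vector of 0-based class codes, length N.
#' @export
predict_labels <- function(model, X) {
  S <- predict_scores(model, X)
  max.col(S, ties.method = "first") - 1L
}
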