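test_that("one_hot_encode builds exact indicator rows", {
  expect_equal(one_hot_encode(0, 3), matrix(c(1, 0, 0), 1))
  expect_equal(one_hot_encode(c(0, 1, 2), 3), diag(3))
  expect_equal(one_hot_encode(c(2, 2), 4),
               matrix(c(0, 0, 1, 0, 0, 0, 1, 0), 2, 4, byrow = TRUE))
  expect_error(one_hot_encode(c(0, 3), 3), "index 2")
})

test_that("hidden_activations evaluates g(b.x + c) elementwise", {
  hid <- list(W = matrix(0, 2, 4), b = rep(0, 4), v = 4, n_in = 2,
              activation = "sigmoid")
  expect_equal(hidden_activations(matrix(rnorm(10), 5, 2), hid),
               matrix(0.5, 5, 4))
  # single node, argument exactly zero
  hid1 <- list(W = matrix(2, 1, 1), b = -2, v = 1, n_in = 1,
               activation = "sigmoid")
  expect_equal(hidden_activations(matrix(1, 1, 1), hid1),
               matrix(0.5, 1, 1))
  # seeded random weights vs direct per-element recomputation
  set.seed(3)
  X <- matrix(rnorm(12), 4, 3)
  hidr <- list(W = matrix(rnorm(15), 3, 5), b = rnorm(5), v = 5, n_in = 3,
               activation = "sigmoid")
  M <- hidden_activations(X, hidr)
  for (i in 1:4) for (j in 1:5) {
    expect_equal(M[i, j],
                 1 / (1 + exp(-(sum(hidr$W[, j] * X[i, ]) + hidr$b[j]))))
  }
  expect_error(hidden_activations(matrix(0, 2, 4), hidr), "width")
})

test_that("ELM exactly interpolates v distinct observations", {
  set.seed(21)
  for (v in c(5, 50)) {
    X <- matrix(rnorm(v * 4), v, 4)
    labs <- rep_len(0:2, v)
    H <- one_hot_encode(labs, 3)
    fit <- fit_elm(X, H, rnn_hidden_spec(v = v, seed = 13))
    expect_lt(max(abs(predict_scores(fit, X) - H)), 1e-6)
  }
  # single observation
  X1 <- matrix(rnorm(3), 1, 3)
  fit1 <- fit_elm(X1, one_hot_encode(1, 3), rnn_hidden_spec(v = 4, seed = 2))
  expect_equal(predict_scores(fit1, X1), one_hot_encode(1, 3),
               tolerance = 1e-8)
})

test_that("ELM training solution equals brute-force least squares on M", {
  ft <- small_features(10, dim = 4, seed = 31)
  H <- one_hot_encode(ft$labels, 3)
  spec <- rnn_hidden_spec(v = 2, seed = 5)
  fit <- fit_elm(ft$features, H, spec)
  M <- hidden_activations(ft$features, fit$hidden)
  expect_frobenius_close(fit$d, unname(qr_lstsq(M, H)), 1e-8)
})

test_that("SNN solves bias jointly and fits constants exactly", {
  set.seed(77)
  X <- matrix(rnorm(40), 10, 4)
  Hc <- matrix(rep(c(0, 1, 0), each = 10), 10, 3)  # constant targets
  fit <- fit_snn(X, Hc, rnn_hidden_spec(v = 3, seed = 1))
  expect_lt(max(abs(predict_scores(fit, X) - Hc)), 1e-8)
  expect_length(fit$e, 3)
  expect_null(fit_elm(X, Hc, rnn_hidden_spec(v = 3, seed = 1))$e)
  # N = v + 1 distinct samples: augmented width v+1 >= N -> interpolation
  v <- 5
  X2 <- matrix(rnorm((v + 1) * 3), v + 1, 3)
  H2 <- one_hot_encode(rep_len(0:2, v + 1), 3)
  fit2 <- fit_snn(X2, H2, rnn_hidden_spec(v = v, seed = 3))
  expect_lt(max(abs(predict_scores(fit2, X2) - H2)), 1e-6)
})

train_sse <- function(fit, X, H) sum((predict_scores(fit, X) - H)^2)

test_that("SNN train residual never exceeds ELM's with identical hidden weights", {
  for (s in 1:20) {
    ft <- small_features(8, dim = 6, sep = 2, seed = 100 + s)
    H <- one_hot_encode(ft$labels, 3)
    spec <- rnn_hidden_spec(v = 6, seed = 900 + s)
    snn <- fit_snn(ft$features, H, spec)
    elm <- fit_elm(ft$features, H, spec)
    # same frozen draw
    expect_identical(snn$hidden$W, elm$hidden$W)
    expect_lte(train_sse(snn, ft$features, H),
               train_sse(elm, ft$features, H) + 1e-10)
  }
})

test_that("dRVFL concatenates direct links and stacks layers", {
  ft <- small_features(2, dim = 3, seed = 61)   # N=6, n=3
  H <- one_hot_encode(ft$labels, 3)
  fit <- fit_drvfl(ft$features, H, drvfl_params(l = 2, v = 3, seed = 8))
  expect_equal(ncol(fit$d), 3)
  expect_equal(nrow(fit$d), 3 + 2 * 3)  # n + l*v
  expect_equal(fit$l, 2L)
  # layer recursion: layer 2 consumes layer 1 activations
  M1 <- hidden_activations(ft$features, fit$hidden[[1]])
  M2 <- hidden_activations(M1, fit$hidden[[2]])
  S <- cbind(ft$features, M1, M2) %*% fit$d
  expect_equal(predict_scores(fit, ft$features), S)
})

test_that("deeper dRVFL never increases the training residual (shared weights)", {
  for (s in 1:20) {
    ft <- small_features(8, dim = 5, sep = 2, seed = 300 + s)
    H <- one_hot_encode(ft$labels, 3)
    p2 <- drvfl_params(l = 2, v = 4, seed = 700 + s)
    p1 <- drvfl_params(l = 1, v = 4, seed = 700 + s)
    f2 <- fit_drvfl(ft$features, H, p2)
    f1 <- fit_drvfl(ft$features, H, p1)
    # layer-1 draws identical: the l=2 design matrix extends the l=1 one
    expect_identical(f1$hidden[[1]]$W, f2$hidden[[1]]$W)
    expect_lte(train_sse(f2, ft$features, H),
               train_sse(f1, ft$features, H) + 1e-10)
    # and RVFL (l=1, with direct links) never loses to ELM on the same draw
    elm <- fit_elm(ft$features, H,
                   rnn_hidden_spec(v = 4, seed = p1$specs[[1]]$seed))
    expect_identical(elm$hidden$W, f1$hidden[[1]]$W)
    expect_lte(train_sse(f1, ft$features, H),
               train_sse(elm, ft$features, H) + 1e-10)
  }
})

test_that("dRVFL reaches 100% training accuracy in the interpolation regime", {
  ft <- generate_feature_table(synthetic_feature_spec(
    n_per_class = 100, dim = 128, class_mean_separation = 6, seed = 4))
  H <- one_hot_encode(ft$labels, 3)
  fit <- fit_drvfl(ft$features, H, drvfl_params(l = 3, v = 400, seed = 12))
  expect_equal(mean(predict_labels(fit, ft$features) == ft$labels), 1)
})

test_that("fitting is deterministic and never touches the frozen hidden weights", {
  ft <- small_features(10, dim = 6, seed = 19)
  H <- one_hot_encode(ft$labels, 3)
  spec <- rnn_hidden_spec(v = 12, seed = 77)
  f1 <- fit_elm(ft$features, H, spec)
  f2 <- fit_elm(ft$features, H, spec)
  expect_identical(f1$hidden$W, f2$hidden$W)
  expect_identical(f1$d, f2$d)
  # frozen draw equals the spec's materialization, independent of the data
  raw <- rernet:::materialize_hidden(spec, ncol(ft$features))
  expect_identical(f1$hidden$W, raw$W)
  expect_identical(f1$hidden$b, raw$b)
  expect_identical(predict_labels(f1, ft$features),
                   predict_labels(f2, ft$features))
})

test_that("predict_labels takes the argmax with ties to the lowest index", {
  fake <- structure(list(kind = "ELM",
                         hidden = list(W = diag(3), b = rep(0, 3), v = 3,
                                       n_in = 3, activation = "sigmoid"),
                         d = diag(3), e = NULL, n = 3, m = 3),
                    class = "trained_rnn")
  # brute-force argmax oracle over an exhaustive small grid of score rows
  grid <- expand.grid(a = c(0.1, 0.5, 0.9), b = c(0.1, 0.5, 0.9),
                      c = c(0.1, 0.5, 0.9))
  S <- as.matrix(grid)
  oracle <- apply(S, 1, function(r) which(r == max(r))[1] - 1L)
  expect_equal(max.col(S, ties.method = "first") - 1L, unname(oracle))
  # SNN with d = 0: every score row equals e
  snn0 <- structure(list(kind = "SNN",
                         hidden = list(W = matrix(0, 2, 3), b = rep(0, 3),
                                       v = 3, n_in = 2,
                                       activation = "sigmoid"),
                         d = matrix(0, 3, 3), e = c(0.2, 0.7, 0.1),
                         n = 2, m = 3),
                    class = "trained_rnn")
  S0 <- predict_scores(snn0, matrix(rnorm(6), 3, 2))
  expect_equal(S0, matrix(rep(c(0.2, 0.7, 0.1), each = 3), 3, 3))
  expect_equal(predict_labels(snn0, matrix(rnorm(6), 3, 2)), rep(1L, 3))
})

test_that("zero hidden weights give scores 0.5 * column sums of d", {
  d <- matrix(rnorm(12), 4, 3)
  elm0 <- structure(list(kind = "ELM",
                         hidden = list(W = matrix(0, 5, 4), b = rep(0, 4),
                                       v = 4, n_in = 5,
                                       activation = "sigmoid"),
                         d = d, e = NULL, n = 5, m = 3),
                    class = "trained_rnn")
  S <- predict_scores(elm0, matrix(0, 1, 5))
  expect_equal(S, matrix(0.5 * colSums(d), 1, 3))
})
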