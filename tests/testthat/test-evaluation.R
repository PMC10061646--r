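test_that("confusion_matrix tallies true/predicted pairs", {
  expect_equal(unname(confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)), diag(3) * 1L)
  cm <- confusion_matrix(c(0, 0), c(1, 1), 3)
  expect_equal(cm[1, 2], 2L)
  expect_equal(sum(cm), 2L)
  # 500 seeded random pairs vs a brute-force tally oracle
  set.seed(71)
  yt <- sample(0:3, 500, TRUE); yp <- sample(0:3, 500, TRUE)
  cm <- confusion_matrix(yt, yp, 4)
  for (t in 0:3) for (p in 0:3) {
    expect_equal(cm[t + 1, p + 1], sum(yt == t & yp == p))
  }
  expect_error(confusion_matrix(0:1, 0:2, 3), "length")
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 3), "outside")
})

# The printed-test-split scenario: class sizes 623/620/620, one eosinophil
# predicted as lymphocyte, everything else correct.
single_error_cm <- function() {
  cm <- diag(c(622L, 620L, 620L))
  cm[1, 2] <- 1L
  cm
}

test_that("single-error scenario reproduces the printed per-class row", {
  cm <- single_error_cm()
  pc <- per_class_metrics(cm, 0)
  # eosinophil: accuracy 1862/1863, sensitivity 622/623, precision 622/622
  expect_equal(round_half_up(pc$accuracy, 2), 99.95)
  expect_equal(round_half_up(pc$sensitivity, 2), 99.84)
  expect_equal(round_half_up(pc$precision, 2), 100.00)
  expect_equal(round_half_up(pc$f1, 2), 99.92)
  # lymphocyte gains one false positive instead
  pl <- per_class_metrics(cm, 1)
  expect_equal(round_half_up(pl$accuracy, 2), 99.95)
  expect_equal(round_half_up(pl$sensitivity, 2), 100.00)
  expect_equal(round_half_up(pl$precision, 2), 99.84)
  # macro sensitivity over the three classes
  mm <- macro_metrics(all_class_metrics(cm))
  expect_equal(round_half_up(mm$average_sensitivity, 2), 99.95)
})

test_that("perfect predictions give 100.00 everywhere", {
  cm <- diag(c(10L, 20L, 30L))
  pc <- all_class_metrics(cm)
  expect_true(all(abs(as.matrix(pc[, c("accuracy", "sensitivity",
                                       "precision", "f1")]) - 100) < 1e-12))
})

test_that("one-vs-rest counts partition the samples and match a sample-level oracle", {
  set.seed(33)
  for (rep in 1:10) {
    yt <- sample(0:2, 200, TRUE)
    yp <- sample(0:2, 200, TRUE)
    cm <- confusion_matrix(yt, yp, 3)
    for (cls in 0:2) {
      ct <- ovr_counts(cm, cls)
      expect_equal(ct$tp + ct$tn + ct$fp + ct$fn, 200L)
      # brute-force binary tally at the sample level
      expect_equal(ct$tp, sum(yt == cls & yp == cls))
      expect_equal(ct$fn, sum(yt == cls & yp != cls))
      expect_equal(ct$fp, sum(yt != cls & yp == cls))
      expect_equal(ct$tn, sum(yt != cls & yp != cls))
    }
    # trace and off-diagonal identities
    tps <- sum(sapply(0:2, function(c) ovr_counts(cm, c)$tp))
    fns <- sum(sapply(0:2, function(c) ovr_counts(cm, c)$fn))
    fps <- sum(sapply(0:2, function(c) ovr_counts(cm, c)$fp))
    expect_equal(tps, sum(diag(cm)))
    expect_equal(fns, sum(cm) - sum(diag(cm)))
    expect_equal(fps, fns)
  }
})

test_that("f1_from is the harmonic mean on the percentage scale", {
  expect_equal(round_half_up(f1_from(100, 99.84), 2), 99.92)
  expect_equal(f1_from(73.2, 73.2), 73.2)
  expect_equal(round_half_up(f1_from(100, 50), 2), 66.67)
  expect_warning(out <- f1_from(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("macro averages are unweighted class means, idempotent on constants", {
  pc <- data.frame(class = 0:2, accuracy = c(100, 99.95, 99.90),
                   sensitivity = rep(100, 3), precision = rep(100, 3),
                   f1 = rep(100, 3))
  mm <- macro_metrics(pc)
  expect_equal(mm$average_accuracy, 99.95)
  expect_equal(mm$average_sensitivity, 100)
  expect_error(macro_metrics(pc[0, ]), "empty")
})

test_that("undefined ratios are flagged NA, excluded from means with a warning", {
  cm <- matrix(c(5L, 0L, 3L, 0L, 0L, 0L, 0L, 0L, 4L), 3, 3, byrow = TRUE)
  # class 1 has no true samples and is never predicted
  expect_warning(expect_warning(pc1 <- per_class_metrics(cm, 1),
                                "no true samples"),
                 "never predicted")
  expect_true(is.na(pc1$sensitivity))
  pc <- suppressWarnings(all_class_metrics(cm))
  expect_warning(mm <- macro_metrics(pc, na.rm = TRUE), "excluded")
  expect_false(anyNA(mm))
})

test_that("fold-to-run aggregation reproduces the printed run summary", {
  # run-1 eosinophil fold values from the published fold table
  acc <- c(100.00, 99.95, 100.00, 100.00, 100.00)
  sens <- c(100.00, 99.84, 100.00, 100.00, 100.00)
  fold_metrics <- data.frame(run = 1, fold = 1:5, class = 0,
                             accuracy = acc, sensitivity = sens,
                             precision = 100, f1 = c(100, 99.92, 100, 100, 100))
  ag <- aggregate_metrics(fold_metrics)
  expect_equal(round_half_up(ag$per_run_per_class$accuracy, 2), 99.99)
  expect_equal(round_half_up(ag$per_run_per_class$sensitivity, 2), 99.97)
})

test_that("aggregation order is folds, then classes, then runs", {
  set.seed(4)
  fm <- expand.grid(run = 1:3, fold = 1:4, class = 0:2)
  for (cl in c("accuracy", "sensitivity", "precision", "f1")) {
    fm[[cl]] <- runif(nrow(fm), 90, 100)
  }
  ag <- aggregate_metrics(fm)
  # manual ladder for accuracy
  by_rc <- aggregate(accuracy ~ run + class, fm, mean)
  by_r <- aggregate(accuracy ~ run, by_rc, mean)
  expect_equal(ag$overall$average_accuracy, mean(by_r$accuracy))
  # five identical runs collapse to any single run
  fm1 <- fm[fm$run == 1, ]
  rep5 <- do.call(rbind, lapply(1:5, function(r) transform(fm1, run = r)))
  ag5 <- aggregate_metrics(rep5)
  expect_equal(ag5$overall, aggregate_metrics(fm1)$overall)
  expect_equal(unname(ag5$ci["low", ]), unname(ag5$ci["high", ]))
})

test_that("confidence intervals follow the t distribution", {
  expect_equal(unname(confidence_interval(c(5, 5, 5, 5))), c(5, 5, 5))
  ci <- confidence_interval(c(0, 1), 0.95)
  expect_equal(unname(ci["mean"]), 0.5)
  expect_equal(unname(ci["high"] - ci["mean"]),
               qt(0.975, 1) * sd(c(0, 1)) / sqrt(2))
  expect_true(ci["low"] <= ci["mean"] && ci["mean"] <= ci["high"])
  expect_error(confidence_interval(3), "at least 2")
})

test_that("pairwise difference intervals are zero-width for identical models", {
  ma <- data.frame(run = 1:5, average_accuracy = c(99, 98, 99.5, 99, 98.5))
  d <- pairwise_difference_ci(ma, ma)
  expect_equal(unname(d[, "average_accuracy"]), c(0, 0, 0))
})

test_that("round_half_up rounds .5 away from zero at 2 decimals", {
  expect_equal(round_half_up(99.945, 2), 99.95)
  expect_equal(round_half_up(99.974, 2), 99.97)
  expect_equal(round_half_up(-1.005, 2), -1.01)
  expect_equal(round_half_up(100 * 1862 / 1863, 2), 99.95)
})
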