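# One-vs-rest multi-class metrics: the m-class problem is scored as m
# binary problems (class positive vs rest negative), each yielding
# accuracy, sensitivity, precision and F1 as percentages; macro averages
# are unweighted means over classes. Aggregation order is fixed: within a
# class over folds, then over classes, then over runs.

#' Confusion matrix from label vectors
#'
#' @param y_true,y_pred integer vectors of 0-based class codes, equal
#'   length.
#' @param m class count.
#' @return m x m integer matrix; rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, m) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion_matrix: length mismatch")
  }
  lv <- seq_len(m) - 1L
  if (any(!y_true %in% lv) || any(!y_pred %in% lv)) {
    stop("confusion_matrix: label outside 0..", m - 1)
  }
  cm <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  matrix(as.integer(cm), m, m,
         dimnames = list(true = lv, predicted = lv))
}

#' One-vs-rest counts for a class
#'
#' Partition of all samples for the binary view of class `class_index`:
#' TP = diagonal cell, FN = rest of the true-class row, FP = rest of the
#' predicted-class column, TN = everything else. TP+TN+FP+FN is always the
#' total sample count.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param class_index 0-based class code.
#' @return named list with tp, tn, fp, fn.
#' @export
ovr_counts <- function(cm, class_index) {
  i <- class_index + 1L
  if (i < 1 || i > nrow(cm)) stop("ovr_counts: class index out of range")
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean on the same percentage scale. Undefined (both zero)
#' yields `NA` with a warning rather than a silent 0.
#'
#' @param precision,sensitivity percentages in `[0, 100]`.
#' @return percentage, or `NA` if undefined.
#' @export
f1_from <- function(precision, sensitivity) {
  if (is.na(precision) || is.na(sensitivity)) return(NA_real_)
  s <- precision + sensitivity
  if (s == 0) {
    warning("f1_from: precision + sensitivity is zero; F1 undefined")
    return(NA_real_)
  }
  2 * precision * sensitivity / s
}

#' Per-class one-vs-rest metrics
#'
#' Accuracy, sensitivity (recall), precision and F1 for one class as
#' percentages. Ratios with empty denominators (a class absent from truth
#' or never predicted) are returned as `NA` with a warning, never coerced
#' to 0.
#'
#' @inheritParams ovr_counts
#' @return one-row data.frame: class, accuracy, sensitivity, precision,
#'   f1 (percent), plus tp/tn/fp/fn counts.
#' @export
per_class_metrics <- function(cm, class_index) {
  if (sum(cm) == 0) stop("per_class_metrics: empty confusion matrix")
  ct <- ovr_counts(cm, class_index)
  total <- ct$tp + ct$tn + ct$fp + ct$fn
  acc <- 100 * (ct$tp + ct$tn) / total
  sens <- if (ct$tp + ct$fn == 0) {
    warning("per_class_metrics: class ", class_index,
            " has no true samples; sensitivity undefined")
    NA_real_
  } else 100 * ct$tp / (ct$tp + ct$fn)
  prec <- if (ct$tp + ct$fp == 0) {
    warning("per_class_metrics: class ", class_index,
            " never predicted; precision undefined")
    NA_real_
  } else 100 * ct$tp / (ct$tp + ct$fp)
  f1 <- if (is.na(sens) || is.na(prec)) NA_real_ else
    suppressWarnings(f1_from(prec, sens))
  data.frame(class = class_index, accuracy = acc, sensitivity = sens,
             precision = prec, f1 = f1, tp = ct$tp, tn = ct$tn,
             fp = ct$fp, fn = ct$fn)
}

#' Per-class metrics for every class
#'
#' @param cm confusion matrix.
#' @return data.frame with one row per class (see [per_class_metrics()]).
#' @export
all_class_metrics <- function(cm) {
  do.call(rbind, lapply(seq_len(nrow(cm)) - 1L,
                        function(i) per_class_metrics(cm, i)))
}

#' Macro (unweighted) averages over classes
#'
#' @param per_class data.frame from [all_class_metrics()] (columns
#'   accuracy, sensitivity, precision, f1).
#' @param na.rm drop undefined per-class values (with a warning) instead
#'   of propagating `NA`.
#' @return one-row data.frame: average_accuracy, average_sensitivity,
#'   average_precision, average_f1 (percent).
#' @export
macro_metrics <- function(per_class, na.rm = FALSE) {
  if (is.null(per_class) || nrow(per_class) == 0) {
    stop("macro_metrics: empty per-class table")
  }
  if (na.rm && anyNA(per_class[, c("accuracy", "sensitivity",
                                   "precision", "f1")])) {
    warning("macro_metrics: undefined per-class values excluded from means")
  }
  data.frame(
    average_accuracy = mean(per_class$accuracy, na.rm = na.rm),
    average_sensitivity = mean(per_class$sensitivity, na.rm = na.rm),
    average_precision = mean(per_class$precision, na.rm = na.rm),
    average_f1 = mean(per_class$f1, na.rm = na.rm)
  )
}

#' Student-t confidence interval
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)`; appropriate for the
#' handful of run-level values the protocol produces (n = 5 runs).
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level.
#' @return named numeric vector: mean, low, high.
#' @export
confidence_interval <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("confidence_interval: need at least 2 values")
  m <- mean(values)
  hw <- qt((1 + level) / 2, n - 1) * sd(values) / sqrt(n)
  c(mean = m, low = m - hw, high = m + hw)
}

#' Aggregate fold-level metrics to run and overall summaries
#'
#' Input is the long fold-level per-class table (columns run, fold, class,
#' accuracy, sensitivity, precision, f1, percentages). Averaging follows
#' the reporting ladder of the protocol: per-run per-class = mean over
#' folds; per-run macro = mean over classes; overall = mean over runs;
#' Student-t confidence intervals over the run-level macro values. Full
#' precision is retained; use [round_half_up()] (or the report writers)
#' for 2-decimal rendering.
#'
#' @param fold_metrics fold-level per-class data.frame.
#' @param ci_level confidence level for the run-level intervals.
#' @return list with `per_run_per_class`, `per_run_macro`, `overall`, and
#'   `ci` (rows low/mean/high per index), of class `rernet_summary`.
#' @export
aggregate_metrics <- function(fold_metrics, ci_level = 0.95) {
  need <- c("run", "fold", "class", "accuracy", "sensitivity",
            "precision", "f1")
  if (!all(need %in% names(fold_metrics))) {
    stop("aggregate_metrics: missing columns ",
         paste(setdiff(need, names(fold_metrics)), collapse = ", "))
  }
  idx_cols <- c("accuracy", "sensitivity", "precision", "f1")
  runs <- sort(unique(fold_metrics$run))
  classes <- sort(unique(fold_metrics$class))
  k_by <- table(fold_metrics$run, fold_metrics$class)
  if (length(unique(as.vector(k_by))) != 1) {
    stop("aggregate_metrics: ragged run/fold/class structure")
  }
  per_run_per_class <- do.call(rbind, lapply(runs, function(r) {
    do.call(rbind, lapply(classes, function(cl) {
      sub <- fold_metrics[fold_metrics$run == r & fold_metrics$class == cl, ]
      out <- as.data.frame(lapply(sub[idx_cols], mean))
      cbind(data.frame(run = r, class = cl), out)
    }))
  }))
  per_run_macro <- do.call(rbind, lapply(runs, function(r) {
    sub <- per_run_per_class[per_run_per_class$run == r, ]
    cbind(data.frame(run = r),
          setNames(as.data.frame(lapply(sub[idx_cols], mean)),
                   paste0("average_", idx_cols)))
  }))
  avg_cols <- paste0("average_", idx_cols)
  overall <- setNames(as.data.frame(lapply(per_run_macro[avg_cols], mean)),
                      avg_cols)
  ci <- if (length(runs) >= 2) {
    sapply(avg_cols, function(cl) confidence_interval(per_run_macro[[cl]],
                                                      ci_level))
  } else NULL
  structure(list(per_run_per_class = per_run_per_class,
                 per_run_macro = per_run_macro, overall = overall, ci = ci),
            class = "rernet_summary")
}

#' @export
print.rernet_summary <- function(x, ...) {
  cat("Overall macro metrics (%):\n")
  print(round_half_up(as.matrix(x$overall), 2))
  if (!is.null(x$ci)) {
    cat("95% CI over runs:\n")
    print(round_half_up(x$ci, 2))
  }
  invisible(x)
}

#' Difference-of-means confidence intervals between models
#'
#' For each metric column, a Student-t interval on the paired per-run
#' difference between two models' macro values; a plain interval summary,
#' with no named hypothesis test attached.
#'
#' @param macro_a,macro_b per-run macro data.frames (same runs, columns
#'   `average_*`).
#' @param level confidence level.
#' @return matrix with rows mean/low/high per metric.
#' @export
pairwise_difference_ci <- function(macro_a, macro_b, level = 0.95) {
  cols <- grep("^average_", names(macro_a), value = TRUE)
  sapply(cols, function(cl) {
    confidence_interval(macro_a[[cl]] - macro_b[[cl]], level)
  })
}
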