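# Repeated stratified k-fold protocol: for each of `runs` seeded
# repetitions the data are split into k stratified folds; per fold the
# backbone is fine-tuned on the training portion (image input), features
# are extracted, the three randomized members are fit, and the held-out
# fold is scored with one-vs-rest metrics.

#' Seeded stratified fold assignment
#'
#' Each class is shuffled under the seed and dealt round-robin to folds, so
#' per-class fold counts differ by at most one and assignments are
#' deterministic given the seed.
#'
#' @param labels integer vector of 0-based class codes.
#' @param k fold count (default 5).
#' @param seed integer seed.
#' @param stratified shuffle-within-class (default) or plain shuffle.
#' @return integer vector of fold ids in `1..k`, length of `labels`.
#' @export
make_folds <- function(labels, k = 5, seed = 1, stratified = TRUE) {
  labels <- as.integer(labels)
  N <- length(labels)
  if (stratified) {
    cls_n <- table(labels)
    if (k > min(cls_n)) {
      stop("make_folds: k = ", k, " exceeds the smallest class count (",
           min(cls_n), ")")
    }
    folds <- integer(N)
    for (cl in sort(unique(labels))) {
      rows <- which(labels == cl)
      ord <- with_seed(derive_seed(seed, 29, cl), sample.int(length(rows)))
      folds[rows[ord]] <- rep(seq_len(k), length.out = length(rows))
    }
    folds
  } else {
    if (k > N) stop("make_folds: k exceeds sample count")
    ord <- with_seed(derive_seed(seed, 29, -1), sample.int(N))
    folds <- integer(N)
    folds[ord] <- rep(seq_len(k), length.out = N)
    folds
  }
}

#' Cross-validation / pipeline configuration
#'
#' Bundles the protocol and model settings: fold and run counts, the
#' backbone and its fine-tune recipe (mini-batch 10, 2 epochs, learning
#' rate 1e-4), the members' hidden width `v = 400`, the deep RVFL depth,
#' and the ridge penalty (0 = plain pseudoinverse).
#'
#' @param k folds per run.
#' @param runs repetitions of the k-fold split.
#' @param base_seed base seed; run r uses seeds derived from
#'   `base_seed + r`.
#' @param backbone `"tiny_resnet"` (or `"none"` for feature-table input).
#' @param finetune_mode `"per_fold"` (leakage-free, default) or
#'   `"once_global"` (one fine-tune on the whole pool, faster but the
#'   extractor has seen test images).
#' @param v hidden nodes per randomized member.
#' @param drvfl_layers deep RVFL hidden-layer count.
#' @param ridge ridge penalty for the output solves.
#' @param mini_batch,max_epoch,learning_rate,momentum fine-tune recipe.
#' @param input_size backbone input side in pixels.
#' @param fallback_class majority-vote fallback code.
#' @param activation hidden activation of the members.
#' @param cv_pool `"all"`: fold over the full dataset.
#' @return a `rernet_config` list.
#' @export
rernet_config <- function(k = 5, runs = 5, base_seed = 1,
                          backbone = "tiny_resnet",
                          finetune_mode = c("per_fold", "once_global"),
                          v = 400, drvfl_layers = 3, ridge = 0,
                          mini_batch = 10, max_epoch = 2,
                          learning_rate = 1e-4, momentum = 0.9,
                          input_size = 64, fallback_class = 0,
                          activation = "sigmoid", cv_pool = "all") {
  finetune_mode <- match.arg(finetune_mode)
  structure(list(k = as.integer(k), runs = as.integer(runs),
                 base_seed = as.integer(base_seed), backbone = backbone,
                 finetune_mode = finetune_mode, v = as.integer(v),
                 drvfl_layers = as.integer(drvfl_layers), ridge = ridge,
                 mini_batch = as.integer(mini_batch),
                 max_epoch = as.integer(max_epoch),
                 learning_rate = learning_rate, momentum = momentum,
                 input_size = as.integer(input_size),
                 fallback_class = as.integer(fallback_class),
                 activation = activation, cv_pool = cv_pool),
            class = "rernet_config")
}

dataset_kind <- function(dataset) {
  if (is.list(dataset) && !is.null(dataset$images)) "images"
  else if (is.list(dataset) && !is.null(dataset$features)) "features"
  else stop("run_protocol: dataset must carry $images or $features plus $labels")
}

#' Run the repeated k-fold cross-validation protocol
#'
#' For every run and fold: fine-tune the backbone on the training portion
#' (image input; skipped for feature-table input), extract feature-layer
#' activations, fit the three randomized members, predict the held-out
#' fold, vote, and score. Per-fold per-class metrics are aggregated to run
#' and overall summaries. Fully deterministic given the config.
#'
#' @param dataset list with `labels` and either `images` (H x W x 3 x N
#'   array) or `features` (N x n matrix); `class_names` optional.
#' @param config an [rernet_config()].
#' @param verbose print per-fold progress.
#' @return object of class `rernet_cv`: `predictions` (data.frame
#'   sample_id, run, fold, true, snn, elm, drvfl, ensemble),
#'   `fold_metrics`, `member_fold_metrics`, `summary` (see
#'   [aggregate_metrics()]), `config`, `class_names`.
#' @export
run_protocol <- function(dataset, config = rernet_config(), verbose = FALSE) {
  kind <- dataset_kind(dataset)
  labels <- as.integer(dataset$labels)
  N <- length(labels)
  m <- max(labels) + 1L
  class_names <- dataset$class_names
  if (is.null(class_names)) class_names <- paste0("class", seq_len(m) - 1L)
  if (any(table(factor(labels, levels = 0:(m - 1))) < config$k)) {
    stop("run_protocol: every class needs at least k samples")
  }
  if (kind == "images" && !identical(config$backbone, "tiny_resnet")) {
    build_extractor(config$backbone, m)  # surfaces the config error
  }
  preds <- list()
  for (r in seq_len(config$runs)) {
    run_seed <- config$base_seed + r
    folds <- make_folds(labels, config$k, seed = run_seed)
    extractor_global <- NULL
    if (kind == "images" && config$finetune_mode == "once_global") {
      bb <- build_extractor(config$backbone, m, config$input_size,
                            seed = derive_seed(run_seed, 5, 0))
      extractor_global <- fine_tune(bb, dataset$images, labels,
        train_config(config$mini_batch, config$max_epoch,
                     config$learning_rate, config$momentum,
                     seed = derive_seed(run_seed, 6, 0)))
    }
    for (f in seq_len(config$k)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      if (length(unique(labels[te])) < m || length(unique(labels[tr])) < m) {
        stop("run_protocol: a fold is missing a class; reduce k")
      }
      if (kind == "images") {
        if (config$finetune_mode == "per_fold") {
          bb <- build_extractor(config$backbone, m, config$input_size,
                                seed = derive_seed(run_seed, 5, f))
          bb <- fine_tune(bb, dataset$images[, , , tr, drop = FALSE],
                          labels[tr],
                          train_config(config$mini_batch, config$max_epoch,
                                       config$learning_rate, config$momentum,
                                       seed = derive_seed(run_seed, 6, f)))
        } else {
          bb <- extractor_global
        }
        Xtr <- extract_features(bb, dataset$images[, , , tr, drop = FALSE])
        Xte <- extract_features(bb, dataset$images[, , , te, drop = FALSE])
      } else {
        Xtr <- dataset$features[tr, , drop = FALSE]
        Xte <- dataset$features[te, , drop = FALSE]
      }
      model <- fit_rernet(Xtr, labels[tr], v = config$v,
                          drvfl_layers = config$drvfl_layers,
                          ridge = config$ridge,
                          seed = derive_seed(run_seed, 9, f),
                          class_names = class_names,
                          fallback_class = config$fallback_class,
                          activation = config$activation)
      pr <- predict_rernet(model, Xte, members = TRUE)
      preds[[length(preds) + 1]] <- data.frame(
        sample_id = te, run = r, fold = f, true = labels[te],
        snn = pr$members$snn, elm = pr$members$elm,
        drvfl = pr$members$drvfl, ensemble = pr$ensemble)
      if (verbose) {
        message(sprintf("run %d fold %d: test acc %.4f", r, f,
                        mean(pr$ensemble == labels[te])))
      }
    }
  }
  predictions <- do.call(rbind, preds)
  fold_metrics <- fold_metrics_from_predictions(predictions, m, "ensemble")
  member_fold_metrics <- lapply(
    setNames(c("snn", "elm", "drvfl"), c("snn", "elm", "drvfl")),
    function(col) fold_metrics_from_predictions(predictions, m, col))
  structure(list(predictions = predictions, fold_metrics = fold_metrics,
                 member_fold_metrics = member_fold_metrics,
                 summary = aggregate_metrics(fold_metrics,
                                             ci_level = 0.95),
                 config = config, class_names = class_names),
            class = "rernet_cv")
}

#' Fold-level per-class metrics from persisted predictions
#'
#' Recomputes the long fold-level metric table from a predictions
#' data.frame (as emitted by [run_protocol()] or read back from its CSV),
#' for the ensemble or any single member column.
#'
#' @param predictions data.frame with columns run, fold, true and the
#'   prediction column.
#' @param m class count.
#' @param column prediction column to score (default `"ensemble"`).
#' @return data.frame: run, fold, class, accuracy, sensitivity, precision,
#'   f1, tp, tn, fp, fn.
#' @export
fold_metrics_from_predictions <- function(predictions, m,
                                          column = "ensemble") {
  out <- list()
  for (r in sort(unique(predictions$run))) {
    for (f in sort(unique(predictions$fold[predictions$run == r]))) {
      sub <- predictions[predictions$run == r & predictions$fold == f, ]
      cm <- confusion_matrix(sub$true, sub[[column]], m)
      pc <- all_class_metrics(cm)
      out[[length(out) + 1]] <- cbind(data.frame(run = r, fold = f), pc)
    }
  }
  do.call(rbind, out)
}

#' @export
print.rernet_cv <- function(x, ...) {
  cat(sprintf("<rernet_cv: %d runs x %d folds, %d samples, classes: %s>\n",
              x$config$runs, x$config$k, length(unique(x$predictions$sample_id)),
              paste(x$class_names, collapse = "/")))
  print(x$summary)
  invisible(x)
}
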