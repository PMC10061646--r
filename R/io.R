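# Dataset and model persistence. Images live in class-per-subdirectory
# folders (class code = 0-based rank of the sorted subdirectory name, so
# "eosinophil" is class 0 on the benchmark layout); feature tables are CSV
# with a final integer `label` column; model archives are single-file
# containers with a format/version header whose round trip reproduces
# bit-identical predictions.

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG support needs the EBImage package; convert to PNG")
    }
    aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

resize_image <- function(img, size) {
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) out[, , ch] <- bilinear_resize(img[, , ch], size, size)
  out
}

#' Read a class-per-subdirectory image folder
#'
#' Subdirectories are sorted by name and assigned class codes 0, 1, ...;
#' files within a class are read in sorted order, so the stream is stable
#' across calls. Undecodable files are skipped with a warning; an empty
#' class directory is an error.
#'
#' @param path folder with one subdirectory per class holding PNG (or,
#'   with EBImage installed, JPEG) images.
#' @param size optional square side to resize to (bilinear).
#' @return list with `images` (H x W x 3 x N array), `labels` (0-based),
#'   `class_names`, `files`.
#' @export
read_image_folder <- function(path, size = NULL) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  if (length(dirs) < 2) stop("read_image_folder: need >= 2 class subdirectories")
  class_names <- basename(dirs)
  imgs <- list(); labels <- integer(0); files <- character(0)
  for (ci in seq_along(dirs)) {
    fl <- sort(list.files(dirs[ci], full.names = TRUE,
                          pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))
    n_ok <- 0L
    for (f in fl) {
      img <- tryCatch(read_one_image(f), error = function(e) {
        warning("skipping undecodable file ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      if (!is.null(size)) img <- resize_image(img, size)
      imgs[[length(imgs) + 1]] <- img
      labels <- c(labels, ci - 1L)
      files <- c(files, f)
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) {
      stop("read_image_folder: empty class directory (no decodable image) ",
           dirs[ci])
    }
  }
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(x) identical(dim(x), d), logical(1)))) {
    stop("read_image_folder: images have mixed sizes; pass `size` to resize")
  }
  images <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) images[, , , i] <- imgs[[i]]
  list(images = images, labels = labels, class_names = class_names,
       files = files)
}

#' Write images into a class-per-subdirectory PNG folder
#'
#' Inverse of [read_image_folder()]; file names encode the within-class
#' index so read-back order matches generation order.
#'
#' @param images H x W x 3 x N array in `[0, 1]`.
#' @param labels 0-based class codes, length N.
#' @param path output folder (created).
#' @param class_names character vector naming the classes.
#' @return `path`, invisibly.
#' @export
write_image_folder <- function(images, labels, path,
                               class_names = NULL) {
  labels <- as.integer(labels)
  m <- max(labels) + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(m) - 1L)
  counters <- integer(m)
  for (cn in class_names) dir.create(file.path(path, cn), recursive = TRUE,
                                     showWarnings = FALSE)
  for (i in seq_len(dim(images)[4])) {
    cl <- labels[i] + 1L
    counters[cl] <- counters[cl] + 1L
    png::writePNG(images[, , , i],
                  file.path(path, class_names[cl],
                            sprintf("%s_%04d.png", class_names[cl],
                                    counters[cl])))
  }
  invisible(path)
}

#' Read / write feature-table CSV
#'
#' Header row of feature names with a final integer `label` column.
#'
#' @param path CSV path.
#' @return list with `features` matrix and `labels` integer vector.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature CSV lacks a 'label' column")
  lab <- as.integer(df$label)
  X <- as.matrix(df[setdiff(names(df), "label")])
  storage.mode(X) <- "double"
  list(features = X, labels = lab)
}

#' @rdname read_feature_csv
#' @param features N x n numeric matrix.
#' @param labels 0-based class codes, length N.
#' @export
write_feature_csv <- function(features, labels, path) {
  df <- as.data.frame(features)
  if (is.null(colnames(features))) {
    names(df) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  df$label <- as.integer(labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

ARCHIVE_FORMAT <- "rernet-archive"
ARCHIVE_VERSION <- 1L

#' Save / load a fitted model archive
#'
#' Single-file container holding the ensemble (member kinds, seeds, frozen
#' hidden weights, solved output weights), the optional backbone, class
#' names and a config snapshot. Loading verifies the format and version
#' and fails loudly on corruption; a round trip reproduces bit-identical
#' predictions.
#'
#' @param model an `rernet_model`.
#' @param path archive file path.
#' @param backbone optional `rernet_backbone` stored alongside.
#' @param config optional config snapshot.
#' @return `path` invisibly (`save_model`); the restored objects as a list
#'   with `model`, `backbone`, `config`, `metadata` (`load_model`).
#' @export
save_model <- function(model, path, backbone = NULL, config = NULL) {
  stopifnot(inherits(model, "rernet_model"))
  obj <- list(format = ARCHIVE_FORMAT, version = ARCHIVE_VERSION,
              model = model, backbone = backbone, config = config,
              metadata = list(class_names = model$class_names,
                              member_seeds = c(
                                snn = derive_seed(model$seed, 1),
                                elm = derive_seed(model$seed, 2),
                                drvfl = derive_seed(model$seed, 3)),
                              base_seed = model$seed,
                              created = "rernet model archive"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("load_model: cannot read archive '", path,
         "' (corrupt or truncated): ", conditionMessage(e))
  })
  if (!is.list(obj) || !identical(obj$format, ARCHIVE_FORMAT)) {
    stop("load_model: '", path, "' is not a rernet model archive")
  }
  if (!identical(obj$version, ARCHIVE_VERSION)) {
    stop("load_model: archive version ", obj$version,
         " not supported (expected ", ARCHIVE_VERSION, ")")
  }
  obj[c("model", "backbone", "config", "metadata")]
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected before any compute; known keys override the
#' [rernet_config()] defaults.
#'
#' @param path YAML file.
#' @param overrides named list of command-line overrides (take precedence
#'   over the file).
#' @return an `rernet_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(rernet_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("read_config: unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(rernet_config, vals)
}

fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Write cross-validation reports as CSV
#'
#' Emits the fold-level per-class table, the per-run per-class summary,
#' the overall macro summary with confidence intervals, and the raw
#' per-sample predictions. Metric columns are rendered half-up at 2
#' decimals (column order: accuracy, sensitivity, precision, F1);
#' formatting is fixed so identical results give byte-identical files.
#'
#' @param cv an `rernet_cv` from [run_protocol()].
#' @param dir output directory (created).
#' @return character vector of the files written, invisibly.
#' @export
write_cv_reports <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- c("accuracy", "sensitivity", "precision", "f1")
  fm <- cv$fold_metrics
  fold_df <- data.frame(run = fm$run, fold = fm$fold,
                        class = cv$class_names[fm$class + 1])
  for (cl in idx) fold_df[[cl]] <- fmt2(fm[[cl]])
  prc <- cv$summary$per_run_per_class
  run_df <- data.frame(run = prc$run, class = cv$class_names[prc$class + 1])
  for (cl in idx) run_df[[paste0("average_", cl)]] <- fmt2(prc[[cl]])
  ov <- cv$summary$overall
  head_df <- data.frame(metric = paste0("average_", idx),
                        value = fmt2(as.numeric(ov[paste0("average_", idx)])))
  if (!is.null(cv$summary$ci)) {
    ci <- cv$summary$ci
    head_df$ci_low <- fmt2(ci["low", paste0("average_", idx)])
    head_df$ci_high <- fmt2(ci["high", paste0("average_", idx)])
  }
  files <- file.path(dir, c("fold_metrics.csv", "run_summary.csv",
                            "overall_summary.csv", "predictions.csv"))
  write.csv(fold_df, files[1], row.names = FALSE, quote = FALSE)
  write.csv(run_df, files[2], row.names = FALSE, quote = FALSE)
  write.csv(head_df, files[3], row.names = FALSE, quote = FALSE)
  write.csv(cv$predictions, files[4], row.names = FALSE, quote = FALSE)
  invisible(files)
}
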