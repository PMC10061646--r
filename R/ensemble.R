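#' Majority vote over three member predictions
#'
#' Returns the class predicted by at least two of the three members; when
#' all three disagree, returns the fixed fallback class (class 0, the
#' eosinophil on the blood-cell benchmark's alphabetical ordering).
#' Vectorized over samples.
#'
#' @param p_alpha,p_beta,p_gamma integer vectors of 0-based class codes
#'   (equal length), one per ensemble member.
#' @param fallback_class class code returned when all three disagree.
#' @param m optional class count for validation.
#' @return integer vector of fused class codes.
#' @examples
#' majority_vote(2, 2, 0)           # two agree -> 2
#' majority_vote(0, 1, 2)           # all differ -> fallback 0
#' @export
majority_vote <- function(p_alpha, p_beta, p_gamma, fallback_class = 0L,
                          m = NULL) {
  p_alpha <- as.integer(p_alpha)
  p_beta <- as.integer(p_beta)
  p_gamma <- as.integer(p_gamma)
  if (length(p_beta) != length(p_alpha) || length(p_gamma) != length(p_alpha)) {
    stop("majority_vote: member prediction vectors must have equal length")
  }
  all_p <- c(p_alpha, p_beta, p_gamma, fallback_class)
  if (anyNA(all_p) || any(all_p < 0) || (!is.null(m) && any(all_p >= m))) {
    stop("majority_vote: invalid class index")
  }
  out <- ifelse(p_alpha == p_beta | p_alpha == p_gamma, p_alpha,
         ifelse(p_beta == p_gamma, p_beta, as.integer(fallback_class)))
  as.integer(out)
}

#' Fit the full three-member ensemble on extracted features
#'
#' Trains the Schmidt network, extreme learning machine, and deep RVFL
#' members on identical features and one-hot targets, each with an
#' independently seeded random hidden draw, and packages them with the
#' voting rule.
#'
#' @param features N x n numeric feature matrix (e.g. 128-dim backbone
#'   features).
#' @param labels integer vector of 0-based class codes, length N; every
#'   class `0..m-1` must be present.
#' @param v hidden nodes per member (default 400).
#' @param drvfl_layers hidden-layer count of the deep RVFL member.
#' @param ridge ridge penalty for the output solves (0 = plain
#'   pseudoinverse).
#' @param seed base seed; the three members use seeds derived from it.
#' @param class_names optional character vector, length m.
#' @param fallback_class vote fallback code (default 0).
#' @param activation hidden activation tag.
#' @param share_deep_weights passed to [drvfl_params()].
#' @return object of class `rernet_model`.
#' @export
fit_rernet <- function(features, labels, v = 400, drvfl_layers = 3,
                       ridge = 0, seed = 1, class_names = NULL,
                       fallback_class = 0L, activation = "sigmoid",
                       share_deep_weights = FALSE) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  m <- max(labels) + 1L
  if (m < 2) stop("fit_rernet: need at least two classes")
  missing_cls <- setdiff(seq_len(m) - 1L, unique(labels))
  if (length(missing_cls)) {
    stop("fit_rernet: class ", missing_cls[1], " has zero samples")
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(m) - 1L)
  stopifnot(length(class_names) == m)
  H <- one_hot_encode(labels, m)
  snn <- fit_snn(features, H,
                 rnn_hidden_spec(v, activation, derive_seed(seed, 1)), ridge)
  elm <- fit_elm(features, H,
                 rnn_hidden_spec(v, activation, derive_seed(seed, 2)), ridge)
  drv <- fit_drvfl(features, H,
                   drvfl_params(drvfl_layers, v, activation,
                                derive_seed(seed, 3),
                                share_deep_weights), ridge)
  structure(list(rnn_snn = snn, rnn_elm = elm, rnn_drvfl = drv,
                 class_names = class_names, n = ncol(features), m = m,
                 fallback_class = as.integer(fallback_class), seed = seed,
                 v = v, drvfl_layers = drvfl_layers, ridge = ridge,
                 backbone_ref = NULL),
            class = "rernet_model")
}

#' @export
print.rernet_model <- function(x, ...) {
  cat(sprintf("<rernet_model: %d classes (%s), n=%d features, v=%d, dRVFL l=%d>\n",
              x$m, paste(x$class_names, collapse = "/"), x$n, x$v,
              x$drvfl_layers))
  invisible(x)
}

#' Predict with the majority-voting ensemble
#'
#' Each member predicts hard labels; the per-sample fused label is the
#' majority vote with the model's fallback class.
#'
#' @param model an `rernet_model` from [fit_rernet()].
#' @param features N x n feature matrix.
#' @param members if `TRUE`, also return the per-member label matrix.
#' @return integer vector of fused class codes, or (with `members = TRUE`)
#'   a list with `ensemble` and a data.frame `members` (columns snn, elm,
#'   drvfl).
#' @export
predict_rernet <- function(model, features, members = FALSE) {
  stopifnot(inherits(model, "rernet_model"))
  features <- as.matrix(features)
  if (ncol(features) != model$n) {
    stop("predict_rernet: feature width ", ncol(features),
         " does not match model width ", model$n)
  }
  p_snn <- predict_labels(model$rnn_snn, features)
  p_elm <- predict_labels(model$rnn_elm, features)
  p_drv <- predict_labels(model$rnn_drvfl, features)
  fused <- majority_vote(p_snn, p_elm, p_drv, model$fallback_class, model$m)
  if (!members) return(fused)
  list(ensemble = fused,
       members = data.frame(snn = p_snn, elm = p_elm, drvfl = p_drv))
}
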