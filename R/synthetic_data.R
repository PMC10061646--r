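# Synthetic desk-scale fixtures: caricature blood-cell images with known
# class morphology and position, and Gaussian-mixture feature tables that
# stand in for backbone feature vectors. The image recipes are keyed to the
# gross morphology that distinguishes the three white-cell classes --
# eosinophil: granular cytoplasm and a bi-lobed nucleus; lymphocyte: a
# large round nucleus filling most of a small cell; monocyte: the largest
# cell with a kidney-shaped nucleus. They are learnably distinct and
# localizable, not photorealistic.

#' Specification for synthetic cell images
#'
#' @param n_per_class images per class.
#' @param image_size square side in pixels (>= 32; default 64).
#' @param noise_sd sd of the additive Gaussian pixel noise (default 0.05).
#' @param seed integer seed; output is deterministic given the spec.
#' @return object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(n_per_class = 60, image_size = 64,
                                 noise_sd = 0.05, seed = 1) {
  if (image_size < 32) stop("synthetic_image_spec: image_size must be >= 32")
  stopifnot(n_per_class >= 1, noise_sd >= 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

paint <- function(img, mask, color, alpha = 1) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask] <- (1 - alpha) * pl[mask] + alpha * color[ch]
    img[, , ch] <- pl
  }
  img
}

ellipse_mask <- function(X, Y, cx, cy, rx, ry) {
  ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
}

# Draw one cell image for class code cls (0 eosinophil, 1 lymphocyte,
# 2 monocyte); returns list(img, bbox).
draw_cell <- function(S, cls, noise_sd) {
  X <- matrix(rep(seq_len(S), each = S), S, S)   # column coordinate
  Y <- matrix(rep(seq_len(S), times = S), S, S)  # row coordinate
  img <- array(0, c(S, S, 3))
  img[, , 1] <- 0.96; img[, , 2] <- 0.90; img[, , 3] <- 0.93
  # faint background smear texture (out-of-focus red cells)
  for (b in 1:4) {
    bc <- runif(2, 0.1 * S, 0.9 * S)
    br <- runif(1, 0.06, 0.12) * S
    img <- paint(img, ellipse_mask(X, Y, bc[1], bc[2], br, br),
                 c(0.93, 0.80, 0.82), alpha = 0.5)
  }
  cx <- S / 2 + runif(1, -0.08, 0.08) * S
  cy <- S / 2 + runif(1, -0.08, 0.08) * S
  if (cls == 0L) {                       # eosinophil: granules + two lobes
    r <- runif(1, 0.26, 0.30) * S
    body <- ellipse_mask(X, Y, cx, cy, r, r * runif(1, 0.9, 1))
    img <- paint(img, body, c(0.88, 0.58, 0.55))
    ngr <- 70
    gx <- cx + runif(ngr, -0.8, 0.8) * r
    gy <- cy + runif(ngr, -0.8, 0.8) * r
    for (g in seq_len(ngr)) {
      img <- paint(img, ellipse_mask(X, Y, gx[g], gy[g], 1.2, 1.2),
                   c(0.75, 0.25, 0.28))
    }
    off <- runif(1, 0.35, 0.45) * r
    th <- runif(1, 0, pi)
    for (sgn in c(-1, 1)) {
      img <- paint(img, ellipse_mask(X, Y, cx + sgn * off * cos(th),
                                     cy + sgn * off * sin(th),
                                     0.45 * r, 0.35 * r),
                   c(0.38, 0.15, 0.45))
    }
  } else if (cls == 1L) {                # lymphocyte: large round nucleus
    r <- runif(1, 0.20, 0.24) * S
    body <- ellipse_mask(X, Y, cx, cy, r, r)
    img <- paint(img, body, c(0.62, 0.70, 0.90))
    rn <- runif(1, 0.78, 0.88) * r
    img <- paint(img, ellipse_mask(X, Y, cx, cy, rn, rn),
                 c(0.30, 0.20, 0.55))
  } else {                               # monocyte: largest, kidney nucleus
    r <- runif(1, 0.32, 0.36) * S
    body <- ellipse_mask(X, Y, cx, cy, r, r * runif(1, 0.92, 1))
    img <- paint(img, body, c(0.74, 0.76, 0.86))
    rn <- 0.62 * r
    nuc <- ellipse_mask(X, Y, cx, cy, rn, rn * 0.9)
    bite <- ellipse_mask(X, Y, cx + 0.55 * rn, cy - 0.15 * rn,
                         0.65 * rn, 0.65 * rn)
    img <- paint(img, nuc & !bite, c(0.42, 0.32, 0.62))
  }
  if (noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  bbox <- c(x0 = max(1, floor(cx - r)), y0 = max(1, floor(cy - r)),
            x1 = min(S, ceiling(cx + r)), y1 = min(S, ceiling(cy + r)))
  list(img = img, bbox = bbox)
}

#' Generate labeled synthetic cell images
#'
#' Deterministic given the spec's seed. Each image holds one cell (class
#' recipe above) on a textured background; the cell's bounding box is
#' recorded so attention maps can be checked against the true object
#' position.
#'
#' @param spec a [synthetic_image_spec()].
#' @return list with `images` (size x size x 3 x N array, `[0,1]`),
#'   `labels` (0-based codes, balanced), `class_names`
#'   (eosinophil/lymphocyte/monocyte), and `bboxes` (data.frame sample,
#'   x0, y0, x1, y1 in pixel coordinates).
#' @export
generate_cell_images <- function(spec = synthetic_image_spec()) {
  S <- spec$image_size
  n <- spec$n_per_class
  N <- 3L * n
  images <- array(0, c(S, S, 3, N))
  labels <- integer(N)
  bb <- matrix(0, N, 4)
  i <- 0L
  for (cls in 0:2) {
    for (j in seq_len(n)) {
      i <- i + 1L
      one <- with_seed(derive_seed(spec$seed, cls, j),
                       draw_cell(S, cls, spec$noise_sd))
      images[, , , i] <- one$img
      labels[i] <- cls
      bb[i, ] <- one$bbox
    }
  }
  list(images = images, labels = labels,
       class_names = c("eosinophil", "lymphocyte", "monocyte"),
       bboxes = data.frame(sample = seq_len(N), x0 = bb[, 1], y0 = bb[, 2],
                           x1 = bb[, 3], y1 = bb[, 4]))
}

#' Specification for synthetic Gaussian feature tables
#'
#' Class `c` is drawn from an isotropic Gaussian whose mean is
#' `class_mean_separation` times the `c`-th coordinate unit vector (first
#' `classes` coordinates), emulating well-separated backbone feature
#' vectors.
#'
#' @param n_per_class samples per class.
#' @param dim feature dimension (default 128, the backbone feature width).
#' @param class_mean_separation distance scale between class means.
#' @param noise_sd isotropic Gaussian sd.
#' @param classes number of classes (default 3).
#' @param seed integer seed.
#' @return object of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_per_class = 100, dim = 128,
                                   class_mean_separation = 6, noise_sd = 1,
                                   classes = 3, seed = 1) {
  stopifnot(dim >= 2, dim >= classes, class_mean_separation >= 0,
            noise_sd >= 0, n_per_class >= 1, classes >= 2)
  structure(list(n_per_class = as.integer(n_per_class),
                 dim = as.integer(dim),
                 class_mean_separation = class_mean_separation,
                 noise_sd = noise_sd, classes = as.integer(classes),
                 seed = as.integer(seed)),
            class = "synthetic_feature_spec")
}

#' Generate a synthetic Gaussian-mixture feature table
#'
#' @param spec a [synthetic_feature_spec()].
#' @return list with `features` (N x dim matrix) and `labels` (0-based,
#'   balanced at n_per_class each).
#' @export
generate_feature_table <- function(spec = synthetic_feature_spec()) {
  n <- spec$n_per_class
  N <- spec$classes * n
  with_seed(spec$seed, {
    X <- matrix(rnorm(N * spec$dim, 0, spec$noise_sd), N, spec$dim)
    labels <- rep(seq_len(spec$classes) - 1L, each = n)
    for (cls in seq_len(spec$classes) - 1L) {
      rows <- which(labels == cls)
      X[rows, cls + 1] <- X[rows, cls + 1] + spec$class_mean_separation
    }
    list(features = X, labels = labels)
  })
}
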