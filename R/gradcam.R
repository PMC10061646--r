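# Grad-CAM: class-discriminative attention maps from spatially pooled
# gradients of a class logit with respect to a convolutional feature map.

#' Bilinear resize of a 2-D matrix
#'
#' @param m numeric matrix.
#' @param H,W target dimensions.
#' @return H x W matrix.
#' @export
bilinear_resize <- function(m, H, W) {
  h0 <- nrow(m); w0 <- ncol(m)
  if (h0 == H && w0 == W) return(m)
  # map target pixel centers into source coordinates
  ys <- (seq_len(H) - 0.5) * h0 / H + 0.5
  xs <- (seq_len(W) - 0.5) * w0 / W + 0.5
  y0 <- pmin(pmax(floor(ys), 1), h0); y1 <- pmin(y0 + 1, h0)
  x0 <- pmin(pmax(floor(xs), 1), w0); x1 <- pmin(x0 + 1, w0)
  wy <- pmin(pmax(ys - y0, 0), 1)
  wx <- pmin(pmax(xs - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
    m[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  bot <- m[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
    m[y1, x1, drop = FALSE] * outer(wy, wx)
  top + bot
}

# Core Grad-CAM combination: channel weights are the spatial means of the
# gradient maps; the cam is the rectified weighted sum of feature maps.
cam_from_grads <- function(A, G) {
  stopifnot(identical(dim(A), dim(G)))
  w <- apply(G, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(dim(A)[3])) cam <- cam + w[k] * A[, , k]
  cam[cam < 0] <- 0
  cam
}

# Gradient of logit[class] w.r.t. a target activation of the tiny backbone.
# Head is linear-ish in inference mode (BN uses running stats), so the
# chain through GAP/FC128/ReLU/BN/FC is exact and cheap; below the head the
# stored conv caches are reused.
backbone_layer_grad <- function(model, fw, class_index, target_layer) {
  p <- model$params
  cc <- fw$cache
  m <- model$num_classes
  if (class_index < 0 || class_index >= m) {
    stop("grad_cam: class_index out of range")
  }
  dlogits <- matrix(0, 1, m)
  dlogits[1, class_index + 1] <- 1
  dbn <- dlogits %*% t(p$fc2_W)
  inv_sd <- 1 / sqrt(model$bn_var + model$bn_eps)   # inference-mode BN
  dr <- sweep(dbn, 2, p$bn_gamma * inv_sd, "*")
  dfeat <- dr * (cc$feat > 0)
  df <- dfeat %*% t(p$fc1_W)
  d4 <- dim(cc$a4)
  da4 <- array(rep(t(df) / cc$gap_hw, each = cc$gap_hw), d4)
  if (target_layer == "block2") return(da4)
  ds2 <- da4 * (cc$s2 > 0)
  bcB <- conv_backward(ds2, cc$cB)
  du2 <- bcB$dx * (cc$u2 > 0)
  bcA <- conv_backward(du2, cc$cA)
  da3 <- bcA$dx + ds2
  dz2 <- da3 * (cc$a3 > 0)
  bc2 <- conv_backward(dz2, cc$c2)
  da2 <- bc2$dx
  if (target_layer == "block1") return(da2)
  ds1 <- da2 * (cc$s1 > 0)
  bbB <- conv_backward(ds1, cc$bB)
  du1 <- bbB$dx * (cc$u1 > 0)
  bbA <- conv_backward(du1, cc$bA)
  da1 <- bbA$dx + ds1
  if (target_layer == "conv1") return(da1)
  stop("grad_cam: unknown target layer '", target_layer,
       "' (use \"block2\", \"block1\" or \"conv1\")")
}

#' Grad-CAM attention heatmap
#'
#' Computes the gradient of the chosen class logit with respect to a
#' convolutional feature map of the backbone, averages it spatially per
#' channel to get channel weights, forms the rectified weighted sum of the
#' feature maps, upsamples it bilinearly to the input size and scales it to
#' maximum 1 (unless identically zero). Red/high regions mark where the
#' network's evidence for the class is concentrated.
#'
#' @param model an `rernet_backbone` (typically fine-tuned).
#' @param image a single image, array (H, W, 3) or (H, W, 3, 1).
#' @param class_index 0-based class whose evidence is mapped; default the
#'   model's own predicted class.
#' @param target_layer `"block2"` (last convolutional stage, default),
#'   `"block1"` or `"conv1"`.
#' @return H x W matrix with entries in `[0, 1]`.
#' @export
grad_cam <- function(model, image, class_index = NULL,
                     target_layer = "block2") {
  stopifnot(inherits(model, "rernet_backbone"))
  d <- dim(image)
  if (length(d) == 3) dim(image) <- c(d, 1)
  fw <- backbone_forward(model, image, mode = "infer", keep_cache = TRUE)
  if (is.null(class_index)) {
    class_index <- which.max(fw$probs[1, ]) - 1L
  }
  G <- backbone_layer_grad(model, fw, class_index, target_layer)
  A <- switch(target_layer, block2 = fw$cache$a4, block1 = fw$cache$a2,
              conv1 = fw$cache$a1)
  cam <- cam_from_grads(A[, , , 1], G[, , , 1])
  cam <- bilinear_resize(cam, dim(image)[1], dim(image)[2])
  cam[cam < 0] <- 0
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  cam
}

#' Write a Grad-CAM overlay image
#'
#' Blends the heatmap (red channel up, blue channel down) over the input
#' image and writes a PNG.
#'
#' @param image array (H, W, 3) in `[0, 1]`.
#' @param cam heatmap from [grad_cam()].
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap.
#' @return `path`, invisibly.
#' @export
write_cam_overlay <- function(image, cam, path, alpha = 0.45) {
  d <- dim(image)
  if (length(d) == 4) image <- image[, , , 1]
  heat <- array(0, dim(image))
  heat[, , 1] <- cam
  heat[, , 3] <- 1 - cam
  out <- (1 - alpha) * image + alpha * heat
  out[out < 0] <- 0; out[out > 1] <- 1
  png::writePNG(out, path)
  invisible(path)
}
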