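# Grad-CAM++ explainability: class-activation heatmaps over a chosen deep
# feature map, overlay rendering, and kappa agreement against reference
# masks.
#
# The scalar target for a dense sigmoid output is the sum of predicted
# probabilities over predicted-foreground pixels (probability > 0.5), the
# standard segmentation adaptation of "the predicted class score". Channel
# weights follow the Grad-CAM++ positive-gradient weighting: with first
# gradients g of the target w.r.t. the activation A,
# alpha = g^2 / (2 g^2 + sum_spatial(A) * g^3) where g != 0, and
# w_k = sum_spatial(alpha_k * relu(g_k)); the map is relu(sum_k w_k A_k),
# min-max normalized and bilinearly upsampled to the input size.

.GRADCAM_LAYERS <- c(paste0("resnet_tap", 1:4), paste0("mobilenet_tap", 1:4),
                     paste0("fused", 1:4), "aspp", paste0("decoder", 1:4))

pick_layer_node <- function(res, layer_id) {
  pick <- function(lst, i) if (!is.null(lst) && length(lst) >= i) lst[[i]]
  num <- suppressWarnings(as.integer(sub("^[a-z_]+", "", layer_id)))
  node <- switch(sub("[0-9]+$", "", layer_id),
                 resnet_tap = pick(res$resnet_taps, num),
                 mobilenet_tap = pick(res$mobilenet_taps, num),
                 fused = pick(res$fused, num),
                 decoder = pick(res$decoder, num),
                 aspp = res$aspp,
                 NULL)
  if (is.null(node))
    stop("unknown or unavailable layer: ", layer_id, " (choose from ",
         paste(.GRADCAM_LAYERS, collapse = ", "), ")")
  node
}

gradcam_weighting <- function(A, g) {
  # A, g: (H*W) x C matrices for one sample
  colA <- colSums(A)
  denom <- 2 * g^2 + row_rep(colA, nrow(g)) * g^3
  alpha <- ifelse(abs(g) > 0, g^2 / ifelse(abs(denom) > 1e-12, denom, 1e-12),
                  0)
  w <- colSums(alpha * pmax(g, 0))
  cam <- pmax(drop(A %*% w), 0)
  cam
}

#' Grad-CAM++ heatmap for a segmentation model
#'
#' Computes the class-activation map of the model's predicted lesion region
#' with respect to a named feature map, normalized to [0, 1] and upsampled
#' to the input size. If the target has zero gradient everywhere (e.g. no
#' pixel is predicted foreground), an all-zero heatmap is returned with a
#' warning.
#'
#' @param model a \linkS4class{SegModel}.
#' @param image H x W x 3 array in [0, 1] or a \linkS4class{SamplePair}.
#' @param layer feature map identifier; default \code{"resnet_tap4"}, the
#'   deepest residual-branch tap.
#' @param threshold probability cutoff defining the predicted region whose
#'   summed probability is the explanation target.
#' @return a \linkS4class{Heatmap}.
#' @export
gradCAMpp <- function(model, image, layer = "resnet_tap4", threshold = 0.5) {
  stopifnot(is(model, "SegModel"))
  if (is(image, "SamplePair")) image <- image@image
  h <- dim(image)[1]; w <- dim(image)[2]
  x <- featureMatrix(image)
  res <- model@engine$forward(x, training = FALSE, collect = TRUE)
  node <- pick_layer_node(res, layer)
  sel <- (res$out$value > threshold) * 1
  target_desc <- sprintf("sum of sigmoid outputs over pixels > %.2f",
                         threshold)
  if (sum(sel) == 0) {
    warning("no predicted foreground; returning all-zero heatmap")
    return(new("Heatmap", values = matrix(0, h, w), sourceLayer = layer,
               targetDescription = target_desc))
  }
  target <- ad_weighted_sum(res$out, sel)
  ad_zero_grads(model@engine$params)
  ad_backward(target)
  g <- node$grad
  if (is.null(g) || all(g == 0)) {
    warning("zero gradients at layer ", layer,
            "; returning all-zero heatmap")
    return(new("Heatmap", values = matrix(0, h, w), sourceLayer = layer,
               targetDescription = target_desc))
  }
  cam <- gradcam_weighting(node$value, g)
  d <- tdim(node$value)
  cam <- normalize_heatmap(cam)
  up <- cpp_resize_bilinear_fw(tmeta(matrix(cam, ncol = 1), 1L, d[2], d[3]),
                               1L, d[2], d[3], h, w)
  vals <- normalize_heatmap(featureArray(tmeta(up, 1L, h, w)))
  new("Heatmap", values = matrix(vals, h, w), sourceLayer = layer,
      targetDescription = target_desc)
}

#' Min-max normalize a non-negative activation map
#'
#' Maps to [0, 1] with maximum exactly 1 when any value is positive;
#' idempotent.
#'
#' @param v numeric vector or matrix, values >= 0.
#' @return normalized values, same shape.
#' @export
normalize_heatmap <- function(v) {
  v <- pmax(v, 0)
  mx <- max(v)
  if (mx > 0) v / mx else v
}

#' Render a heatmap over an image
#'
#' Blends a blue-to-red colormap rendering of the heatmap onto the image:
#' \code{(1 - opacity) * image + opacity * colormap(heatmap)}. Opacity 0
#' returns the image; opacity 1 the pure colormap render.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param heatmap a \linkS4class{Heatmap} (or bare H x W matrix in [0, 1])
#'   of the same spatial size.
#' @param opacity blend fraction in [0, 1].
#' @return H x W x 3 array in [0, 1].
#' @export
overlayHeatmap <- function(image, heatmap, opacity = 0.4) {
  vals <- if (is(heatmap, "Heatmap")) heatmap@values else heatmap
  if (!all(dim(image)[1:2] == dim(vals)))
    stop("image and heatmap spatial sizes differ")
  if (opacity < 0 || opacity > 1) stop("opacity must be in [0, 1]")
  ramp <- grDevices::colorRamp(c("navy", "blue", "cyan", "green", "yellow",
                                 "red"))
  rgbv <- ramp(as.vector(vals)) / 255
  h <- nrow(vals); w <- ncol(vals)
  cm <- array(rgbv, c(h, w, 3))
  (1 - opacity) * image + opacity * cm
}

#' Kappa agreement between a heatmap and a reference mask
#'
#' Binarizes the normalized heatmap at \code{threshold} and computes
#' pixel-wise Cohen's kappa against the reference mask. A constant
#' binarized heatmap against a non-constant reference yields the usual
#' chance-corrected value (at or below 0).
#'
#' @param heatmap a \linkS4class{Heatmap} or H x W matrix in [0, 1].
#' @param reference binary mask of the same size.
#' @param threshold binarization cutoff on the normalized map.
#' @return kappa in [-1, 1].
#' @export
heatmapAgreementKappa <- function(heatmap, reference, threshold = 0.5) {
  vals <- if (is(heatmap, "Heatmap")) heatmap@values else heatmap
  if (!all(dim(vals) == dim(reference)))
    stop("heatmap and reference sizes differ")
  binz <- (vals >= threshold) * 1L
  storage.mode(binz) <- "integer"
  cohensKappa(binz, reference)
}
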