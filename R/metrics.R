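# Evaluation suite: confusion-count region metrics (PA, MPA, MIoU, FWIoU,
# Dice), boundary Hausdorff distance, and Cohen's kappa.
#
# All region metrics derive from the (k+1) x (k+1) pixel confusion matrix p
# with p[i, j] = pixels of true class i predicted as class j; the binary
# lesion task instantiates k = 1 (background, lesion). Dataset-level numbers
# pool the confusion counts over all images; Hausdorff and kappa, which do
# not pool, are averaged per image.

empty_confusion <- function(k = 1L) {
  new("ConfusionCounts", k = as.integer(k),
      p = matrix(0, k + 1L, k + 1L))
}

#' Accumulate pixel confusion counts
#'
#' @param y reference binary mask (H x W of 0/1).
#' @param yhat predicted binary mask, same shape.
#' @param running optional \linkS4class{ConfusionCounts} to increment;
#'   accumulation order is irrelevant.
#' @return updated \linkS4class{ConfusionCounts}.
#' @export
accumulateConfusion <- function(y, yhat, running = NULL) {
  if (!all(dim(y) == dim(yhat))) stop("mask shapes differ")
  assert_mask(y); assert_mask(yhat)
  if (is.null(running)) running <- empty_confusion(1L)
  running@p <- running@p + confusion_core(y, yhat)
  running
}

confusion_core <- function(y, yhat) {
  tp <- sum(y == 1L & yhat == 1L)
  fn <- sum(y == 1L & yhat == 0L)
  fp <- sum(y == 0L & yhat == 1L)
  tn <- length(y) - tp - fn - fp
  matrix(c(tn, fn, fp, tp), 2L, 2L)  # p[i+1, j+1], i = true, j = predicted
}

counts_of <- function(x) {
  if (is.matrix(x)) x
  else if (is(x, "ConfusionCounts")) x@p
  else stop("expected ConfusionCounts or a counts matrix")
}

pa_core <- function(p) sum(diag(p)) / sum(p)

mpa_core <- function(p) {
  rs <- rowSums(p)
  keep <- rs > 0
  if (!all(keep)) warning("class(es) with no reference pixels excluded")
  mean(diag(p)[keep] / rs[keep])
}

miou_core <- function(p) {
  rs <- rowSums(p); cs <- colSums(p)
  keep <- rs > 0
  if (!all(keep)) warning("class(es) with no reference pixels excluded")
  iou <- diag(p) / (rs + cs - diag(p))
  mean(iou[keep])
}

fwiou_core <- function(p) {
  rs <- rowSums(p); cs <- colSums(p)
  freq <- rs / sum(p)
  iou <- ifelse(rs + cs - diag(p) > 0, diag(p) / (rs + cs - diag(p)), 0)
  sum(freq * iou)
}

dice_core <- function(p) {
  tp <- p[2, 2]; fp <- p[1, 2]; fn <- p[2, 1]
  if (2 * tp + fp + fn == 0) stop("Dice undefined: no foreground in either mask")
  2 * tp / (2 * tp + fp + fn)
}

#' Pixel accuracy
#'
#' Fraction of pixels assigned the correct class:
#' \code{sum(diag(p)) / sum(p)}.
#' @param counts a \linkS4class{ConfusionCounts} (or counts matrix).
#' @return fraction in [0, 1].
#' @export
pixelAccuracy <- function(counts) {
  p <- counts_of(counts)
  if (sum(p) == 0) stop("empty confusion counts")
  pa_core(p)
}

#' Mean pixel accuracy
#'
#' Per-class recall averaged over classes with reference pixels.
#' @inheritParams pixelAccuracy
#' @return fraction in [0, 1].
#' @export
meanPixelAccuracy <- function(counts) {
  p <- counts_of(counts)
  if (sum(p) == 0) stop("empty confusion counts")
  mpa_core(p)
}

#' Mean intersection over union
#'
#' Per-class IoU, \code{p_ii / (row_i + col_i - p_ii)}, averaged over
#' classes with reference pixels.
#' @inheritParams pixelAccuracy
#' @return fraction in [0, 1].
#' @export
meanIoU <- function(counts) {
  p <- counts_of(counts)
  if (sum(p) == 0) stop("empty confusion counts")
  miou_core(p)
}

#' Frequency-weighted intersection over union
#'
#' Per-class IoU weighted by the class's share of reference pixels; a convex
#' combination of the per-class IoUs.
#' @inheritParams pixelAccuracy
#' @return fraction in [0, 1].
#' @export
fwIoU <- function(counts) {
  p <- counts_of(counts)
  if (sum(p) == 0) stop("empty confusion counts")
  fwiou_core(p)
}

#' Dice coefficient from confusion counts
#'
#' Foreground overlap \code{2 TP / (2 TP + FP + FN)}; equals
#' \code{1 - diceLoss} in the limit of vanishing smoothing on the same
#' binary masks.
#' @inheritParams pixelAccuracy
#' @return fraction in [0, 1].
#' @export
diceCoefficient <- function(counts) dice_core(counts_of(counts))

#' Boundary pixels of a binary mask
#'
#' Foreground pixels with at least one 4-neighbor outside the foreground
#' (image borders count as outside).
#' @param mask H x W binary matrix.
#' @return m x 2 matrix of (row, col) indices, 1-based.
#' @export
boundaryPixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  nb_min <- pmin(pad[1:h, 2:(w + 1L)], pad[3:(h + 2L), 2:(w + 1L)],
                 pad[2:(h + 1L), 1:w], pad[2:(h + 1L), 3:(w + 2L)])
  which(core == 1L & nb_min == 0L, arr.ind = TRUE)
}

#' Hausdorff distance between mask boundaries
#'
#' The larger of the two directed sup-inf Euclidean distances between the
#' boundary pixel sets of the two masks, in pixels. Undefined when either
#' mask has no foreground: that raises a condition of class
#' \code{"hausdorffUndefinedError"} rather than silently returning 0.
#'
#' @param a,b binary masks of the same shape, each with >= 1 foreground
#'   pixel.
#' @return distance in pixels.
#' @export
#' @examples
#' m1 <- matrix(0L, 8, 8); m1[1, 1] <- 1L
#' m2 <- matrix(0L, 8, 8); m2[4, 5] <- 1L
#' hausdorffDistance(m1, m2)  # 5
hausdorffDistance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  assert_mask(a); assert_mask(b)
  if (sum(a) == 0L || sum(b) == 0L)
    stop(errorCondition("Hausdorff distance undefined for empty mask",
                        class = c("hausdorffUndefinedError", "error",
                                  "condition")))
  ba <- boundaryPixels(a)
  bb <- boundaryPixels(b)
  cpp_hausdorff(matrix(as.numeric(ba), ncol = 2),
                matrix(as.numeric(bb), ncol = 2))
}

#' Cohen's kappa between two binary label maps
#'
#' Chance-corrected pixel agreement \code{(po - pe) / (1 - pe)} where
#' \code{po} is the observed agreement fraction and \code{pe} the agreement
#' expected from the two maps' marginal label frequencies. When both maps
#' are constant and identical (pe = 1, po = 1), kappa is defined as 1;
#' constant but unequal maps raise an error.
#'
#' @param a,b binary masks of the same shape.
#' @return value in [-1, 1].
#' @export
cohensKappa <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  assert_mask(a); assert_mask(b)
  n <- length(a)
  po <- sum(a == b) / n
  fa <- c(sum(a == 0L), sum(a == 1L)) / n
  fb <- c(sum(b == 0L), sum(b == 1L)) / n
  pe <- sum(fa * fb)
  if (abs(1 - pe) < 1e-12) {
    if (po == 1) return(1)
    stop("kappa undefined: raters constant with pe = 1 but po < 1")
  }
  (po - pe) / (1 - pe)
}

#' Evaluate a set of mask pairs
#'
#' Pools confusion counts over all pairs for the region metrics (PA, MPA,
#' MIoU, FWIoU, Dice) and averages Hausdorff distance and Cohen's kappa per
#' image. Pairs for which the Hausdorff distance is undefined (an empty
#' mask) are excluded from its average and counted in
#' \code{details$hd_excluded}; if no pair defines it, it is reported as
#' \code{NA}.
#'
#' @param pairs list of \code{list(truth = , prediction = )} binary masks
#'   (or a list of 2-element lists).
#' @param perImage also return per-image metric rows in \code{details}.
#' @return a \linkS4class{MetricReport}.
#' @export
evaluateDataset <- function(pairs, perImage = FALSE) {
  if (length(pairs) == 0L) stop("need at least one mask pair")
  pooled <- empty_confusion(1L)
  hd <- numeric(0)
  hd_excluded <- 0L
  kap <- numeric(0)
  rows <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    truth <- if (!is.null(pr$truth)) pr$truth else pr[[1]]
    pred <- if (!is.null(pr$prediction)) pr$prediction else pr[[2]]
    pooled <- accumulateConfusion(truth, pred, pooled)
    h <- tryCatch(hausdorffDistance(truth, pred),
                  hausdorffUndefinedError = function(e) NA_real_)
    if (is.na(h)) hd_excluded <- hd_excluded + 1L else hd <- c(hd, h)
    kap <- c(kap, cohensKappa(truth, pred))
    if (perImage) {
      pc <- confusion_core(truth, pred)
      rows[[i]] <- data.frame(image = i, pa = pa_core(pc),
                              dice = tryCatch(dice_core(pc),
                                              error = function(e) NA_real_),
                              hausdorff = h, kappa = kap[length(kap)])
    }
  }
  details <- list(hd_excluded = hd_excluded, counts = pooled@p)
  if (perImage) details$per_image <- do.call(rbind, rows)
  new("MetricReport",
      pa = pa_core(pooled@p), mpa = mpa_core(pooled@p),
      miou = miou_core(pooled@p), fwiou = fwiou_core(pooled@p),
      dice = tryCatch(dice_core(pooled@p), error = function(e) NA_real_),
      hausdorff = if (length(hd)) mean(hd) else NA_real_,
      kappa = if (length(kap)) mean(kap) else NA_real_,
      nImages = length(pairs), details = details)
}

#' Serialize a metric report to JSON
#' @param report a \linkS4class{MetricReport}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMetricReport <- function(report, path) {
  obj <- list(pa = report@pa, mpa = report@mpa, miou = report@miou,
              fwiou = report@fwiou, dice = report@dice,
              hausdorff = report@hausdorff, kappa = report@kappa,
              n_images = report@nImages,
              hd_excluded = report@details$hd_excluded)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a metric report from JSON
#' @param path JSON file written by \code{\link{writeMetricReport}}.
#' @return a \linkS4class{MetricReport} (details hold only counts present).
#' @export
readMetricReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  new("MetricReport", pa = num(obj$pa), mpa = num(obj$mpa),
      miou = num(obj$miou), fwiou = num(obj$fwiou), dice = num(obj$dice),
      hausdorff = num(obj$hausdorff), kappa = num(obj$kappa),
      nImages = as.integer(obj$n_images),
      details = list(hd_excluded = as.integer(obj$hd_excluded)))
}
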