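# Dataset preparation: resizing, normalization, backbone standardization,
# paired augmentation, proportional expansion, stratified splitting and the
# class-imbalance statistic.

#' Resize and normalize an image/mask pair
#'
#' Resizes both to \code{size} x \code{size}: the image with bilinear
#' interpolation, the mask with nearest neighbor followed by re-thresholding
#' at 0.5 so no interpolation gray values survive. Image intensities are
#' scaled to [0, 1] (inputs on a 0-255 scale are detected by their maximum).
#'
#' @param image raw RGB array (H x W x 3), values in [0, 1] or [0, 255].
#' @param mask raw mask (H x W), any values binarizable by thresholding at
#'   half its maximum.
#' @param size output side in pixels.
#' @param classLabel,id metadata for the resulting pair.
#' @return a \linkS4class{SamplePair}.
#' @export
resizeNormalize <- function(image, mask, size, classLabel = "CIN1",
                            id = "sample") {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  d <- dim(image)
  if (any(d[1:2] == 0L) || any(dim(mask) == 0L))
    stop("image and mask must have positive dimensions")
  if (max(image) > 1 + 1e-9) image <- image / 255
  image <- pmin(pmax(image, 0), 1)
  mthr <- if (max(mask) > 0) max(mask) / 2 else 0.5
  maskb <- (mask > mthr) * 1L
  img_r <- featureArray(
    tmeta(cpp_resize_bilinear_fw(featureMatrix(image), 1L, d[1], d[2],
                                 size, size), 1L, size, size),
    drop = FALSE)
  mask_r <- resize_nearest(maskb, size, size)
  samplePair(img_r, mask_r, classLabel = classLabel, id = id)
}

resize_nearest <- function(mask, ho, wo) {
  h <- nrow(mask); w <- ncol(mask)
  ri <- pmin(pmax(floor((seq_len(ho) - 0.5) * h / ho + 0.5), 1L), h)
  ci <- pmin(pmax(floor((seq_len(wo) - 0.5) * w / wo + 0.5), 1L), w)
  out <- mask[ri, ci, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# Per-channel standardization constants on the 0-255 intensity scale.
# residual branch: ImageNet channel means/sds as conventionally used with
# ResNet-family encoders; lightweight branch: the symmetric [-1, 1] mapping
# conventional for MobileNet-family encoders.
.STANDARDIZE <- list(
  "resnet-branch" = list(mean = c(123.675, 116.28, 103.53),
                         sd = c(58.395, 57.12, 57.375)),
  "mobilenet-branch" = list(mean = c(127.5, 127.5, 127.5),
                            sd = c(127.5, 127.5, 127.5)))

#' Backbone-specific input standardization
#'
#' Maps a [0, 1] image to the standardized scale expected by the named
#' encoder family: per channel, (255 * image - mean) / sd using fixed
#' constants (documented in \code{cervseg:::.STANDARDIZE}). The mask of a
#' pair is untouched.
#'
#' @param pair a \linkS4class{SamplePair} (or a bare H x W x 3 array).
#' @param backboneId \code{"resnet-branch"} or \code{"mobilenet-branch"}.
#' @return standardized H x W x 3 array.
#' @export
backboneStandardize <- function(pair, backboneId) {
  if (!backboneId %in% names(.STANDARDIZE))
    stop("unknown backboneId: ", backboneId, " (use ",
         paste(names(.STANDARDIZE), collapse = " or "), ")")
  img <- if (is(pair, "SamplePair")) pair@image else pair
  cst <- .STANDARDIZE[[backboneId]]
  out <- img
  for (c in 1:3) out[, , c] <- (255 * img[, , c] - cst$mean[c]) / cst$sd[c]
  out
}

#' Invert backbone standardization
#' @param image standardized array.
#' @param backboneId encoder family identifier.
#' @return image array back on the [0, 1] scale.
#' @export
backboneUnstandardize <- function(image, backboneId) {
  cst <- .STANDARDIZE[[backboneId]]
  out <- image
  for (c in 1:3) out[, , c] <- (image[, , c] * cst$sd[c] + cst$mean[c]) / 255
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicate padding
gauss_blur <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq(1L - r, n + r), 1L), n)
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  m1 <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
  m1 <- m1[(r + 1L):(r + nrow(m)), , drop = FALSE]
  mp <- m1[, pad_idx(ncol(m)), drop = FALSE]
  m2 <- t(apply(mp, 1, function(row) stats::filter(row, k, sides = 2)))
  m2[, (r + 1L):(r + ncol(m)), drop = FALSE]
}

#' Apply a random augmentation to an image/mask pair
#'
#' Draws one transform from the policy and applies the identical geometric
#' component (flips, rotation, elastic deformation) to image and mask; the
#' photometric component (brightness/contrast) touches the image only. The
#' mask is resampled with nearest neighbor, so it remains strictly binary,
#' and output dimensions are unchanged.
#'
#' @param pair a \linkS4class{SamplePair}.
#' @param policy an \linkS4class{AugmentationPolicy}.
#' @param seed optional seed; when given, the draw is reproducible and the
#'   caller's RNG state is untouched.
#' @return augmented \linkS4class{SamplePair}.
#' @export
augmentPair <- function(pair, policy, seed = NULL) {
  stopifnot(is(pair, "SamplePair"), is(policy, "AugmentationPolicy"))
  if (!is.null(seed)) return(with_seed(seed, augmentPair(pair, policy)))
  img <- pair@image
  mask <- pair@mask
  h <- nrow(mask); w <- ncol(mask)

  if (policy@flipHorizontal && stats::runif(1) < 0.5) {
    img <- img[, w:1, , drop = FALSE]
    mask <- mask[, w:1, drop = FALSE]
  }
  if (policy@flipVertical && stats::runif(1) < 0.5) {
    img <- img[h:1, , , drop = FALSE]
    mask <- mask[h:1, , drop = FALSE]
  }

  angle <- if (policy@rotationLimit > 0)
    stats::runif(1, -policy@rotationLimit, policy@rotationLimit) else 0
  elastic <- policy@elasticAlpha > 0
  if (angle != 0 || elastic) {
    gi <- matrix(rep(seq_len(h) - 1, w), h, w)        # row index per pixel
    gj <- matrix(rep(seq_len(w) - 1, each = h), h, w) # col index per pixel
    map_r <- gi
    map_c <- gj
    if (angle != 0) {
      th <- angle * pi / 180
      ci <- (h - 1) / 2; cj <- (w - 1) / 2
      # backward map: source = R(-theta) * (target - center) + center
      map_r <- ci + cos(th) * (gi - ci) - sin(th) * (gj - cj)
      map_c <- cj + sin(th) * (gi - ci) + cos(th) * (gj - cj)
    }
    if (elastic) {
      dr <- gauss_blur(matrix(stats::runif(h * w, -1, 1), h, w),
                       policy@elasticSigma)
      dc <- gauss_blur(matrix(stats::runif(h * w, -1, 1), h, w),
                       policy@elasticSigma)
      nrm <- max(max(abs(dr)), max(abs(dc)), .Machine$double.eps)
      map_r <- map_r + policy@elasticAlpha * dr / nrm * 0.05
      map_c <- map_c + policy@elasticAlpha * dc / nrm * 0.05
    }
    for (c in 1:3) img[, , c] <- cpp_warp_bilinear(img[, , c], map_r, map_c, 0)
    mask <- cpp_warp_nearest(matrix(as.numeric(mask), h, w), map_r, map_c, 0)
    mask <- (mask > 0.5) * 1L
  }

  if (policy@brightnessLimit > 0) {
    img <- img + stats::runif(1, -policy@brightnessLimit,
                              policy@brightnessLimit)
  }
  if (policy@contrastLimit > 0) {
    img <- 0.5 + (img - 0.5) *
      (1 + stats::runif(1, -policy@contrastLimit, policy@contrastLimit))
  }
  img <- pmin(pmax(img, 0), 1)
  storage.mode(mask) <- "integer"
  samplePair(img, mask, classLabel = pair@classLabel, id = pair@id)
}

#' Largest-remainder proportional allocation
#'
#' Allocates \code{total} units to groups proportionally to \code{counts},
#' flooring the quotas and distributing the remaining units to the largest
#' fractional remainders, so the result sums to \code{total} exactly and
#' every group is within one unit of its exact quota.
#'
#' @param counts non-negative group counts.
#' @param total total to allocate.
#' @return integer vector summing to \code{total}.
#' @export
proportionalAllocation <- function(counts, total) {
  quota <- total * counts / sum(counts)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Expand a dataset by augmentation, preserving class proportions
#'
#' Grows the manifest to \code{targetTotal} samples: originals are all
#' retained and augmented copies are generated per class so the per-class
#' totals follow the largest-remainder allocation of
#' \code{targetTotal} over the original class proportions. Augmented images
#' and masks are written as PNGs under \code{outDir} with provenance ids
#' (\code{<origid>_aug<k>}).
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param targetTotal desired total (>= current size).
#' @param policy augmentation policy for the generated copies.
#' @param outDir directory for augmented files.
#' @param seed RNG seed.
#' @return expanded \linkS4class{DatasetManifest}.
#' @export
expandDataset <- function(manifest, targetTotal, policy = augmentationPolicy(),
                          outDir = tempfile("expanded"), seed = 1L) {
  stopifnot(is(manifest, "DatasetManifest"))
  rec <- manifest@records
  if (targetTotal < nrow(rec))
    stop("targetTotal must be >= current dataset size")
  counts <- table(factor(rec$class_label, levels = CIN_LEVELS))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("manifest is empty")
  alloc <- proportionalAllocation(as.integer(counts), targetTotal)
  names(alloc) <- names(counts)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  new_rows <- list()
  with_seed(seed, {
    for (cl in names(alloc)) {
      rows <- rec[rec$class_label == cl, , drop = FALSE]
      need <- alloc[[cl]] - nrow(rows)
      if (need < 0)
        stop("class ", cl, " already exceeds its allocation")
      if (need == 0) next
      src <- rows[rep(seq_len(nrow(rows)), length.out = need), , drop = FALSE]
      for (k in seq_len(need)) {
        row <- src[k, ]
        img <- readImagePNG(row$image_path)
        mask <- readMask(row$mask_path)
        pair <- samplePair(img, mask, classLabel = cl, id = row$id)
        aug <- augmentPair(pair, policy)
        new_id <- sprintf("%s_aug%d", row$id, k)
        ipath <- file.path(outDir, paste0(new_id, ".png"))
        mpath <- file.path(outDir, paste0(new_id, "_mask.png"))
        writeImagePNG(aug@image, ipath)
        writeMask(aug@mask, mpath)
        out_row <- row
        out_row$id <- new_id
        out_row$image_path <- ipath
        out_row$mask_path <- mpath
        new_rows[[length(new_rows) + 1L]] <- out_row
      }
    }
  })
  if (length(new_rows)) rec <- rbind(rec, do.call(rbind, new_rows))
  rownames(rec) <- NULL
  datasetManifest(rec)
}

#' Stratified train/validation/test split
#'
#' Partitions the manifest into three disjoint, exhaustive subsets. With
#' stratification each class is allocated to the splits by largest
#' remainder, so per-class proportions are preserved within one sample.
#' Deterministic given the seed.
#'
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param spec a \linkS4class{SplitSpec}.
#' @return named list of manifests: \code{train}, \code{validation},
#'   \code{test}.
#' @export
stratifiedSplit <- function(manifest, spec = splitSpec()) {
  stopifnot(is(manifest, "DatasetManifest"), is(spec, "SplitSpec"))
  rec <- manifest@records
  labels <- character(nrow(rec))
  with_seed(spec@seed, {
    if (spec@stratifyByClass) {
      classes <- sort(unique(rec$class_label))
      sizes <- t(vapply(classes, function(cl)
        proportionalAllocation(spec@ratios,
                               sum(rec$class_label == cl)), integer(3L)))
      if (any(rowSums(sizes) < 3L))
        warning("class with fewer samples than splits; ",
                "degenerate assignment")
      # rebalance so the global split sizes also follow largest remainder,
      # moving single samples between splits while staying within one
      # sample of each class quota
      global <- proportionalAllocation(spec@ratios, nrow(rec))
      quota <- vapply(classes, function(cl)
        sum(rec$class_label == cl), numeric(1)) %o% spec@ratios
      for (guard in 1:100) {
        excess <- colSums(sizes) - global
        if (all(excess == 0L)) break
        s_over <- which(excess > 0L)[1]
        s_under <- which(excess < 0L)[1]
        cand <- which(sizes[, s_over] > floor(quota[, s_over]) &
                        sizes[, s_under] < ceiling(quota[, s_under]))
        if (length(cand) == 0L)
          cand <- which(sizes[, s_over] > 0L)
        sizes[cand[1], s_over] <- sizes[cand[1], s_over] - 1L
        sizes[cand[1], s_under] <- sizes[cand[1], s_under] + 1L
      }
      for (ci in seq_along(classes)) {
        idx <- which(rec$class_label == classes[ci])
        labels[idx] <- sample(rep(c("train", "validation", "test"),
                                  times = sizes[ci, ]))
      }
    } else {
      if (nrow(rec) < 3L) warning("fewer samples than splits; ",
                                  "degenerate assignment")
      labels <- sample(rep(c("train", "validation", "test"),
                           times = proportionalAllocation(spec@ratios,
                                                          nrow(rec))))
    }
  })
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(s) {
                  r <- rec[labels == s, , drop = FALSE]
                  rownames(r) <- NULL
                  datasetManifest(r)
                })
  out
}

#' Class-imbalance percentage
#'
#' The spread between the largest and smallest class share,
#' 100 * (max - min) / total, rounded to two decimals for display. For the
#' primary-source class sizes (278, 286, 296) this is 2.09.
#'
#' @param counts per-class sample counts (or a
#'   \linkS4class{DatasetManifest}).
#' @return percentage, rounded to 2 decimals.
#' @export
#' @examples
#' classImbalancePercent(c(278, 286, 296))
classImbalancePercent <- function(counts) {
  if (is(counts, "DatasetManifest")) counts <- classCounts(counts)
  if (length(counts) == 0L || sum(counts) <= 0)
    stop("counts must be nonempty with positive total")
  round(100 * (max(counts) - min(counts)) / sum(counts), 2)
}
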