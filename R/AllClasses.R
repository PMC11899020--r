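#' @import methods
NULL

CIN_LEVELS <- c("CIN1", "CIN2", "CIN3")

#' Polygonal annotations for one image
#'
#' Holds the labeled polygon outlines drawn on a single colposcopic image,
#' in the LabelMe coordinate convention: 0-based, x = column, y = row,
#' origin at the top-left corner. Each shape is a list with elements
#' \code{label} (character) and \code{points} (an n x 2 numeric matrix of
#' (x, y) vertices, at least 3 rows, implicitly closed).
#'
#' @slot imageHeight,imageWidth image dimensions in pixels.
#' @slot shapes list of polygon shapes in file order.
#' @slot sourcePath path of the annotation file this set was read from
#'   (may be \code{NA} for programmatically built sets).
#' @export
setClass("AnnotationSet",
  representation(imageHeight = "integer", imageWidth = "integer",
                 shapes = "list", sourcePath = "character"),
  prototype(sourcePath = NA_character_))

setValidity("AnnotationSet", function(object) {
  if (object@imageHeight <= 0L || object@imageWidth <= 0L)
    return("imageHeight and imageWidth must be positive")
  for (i in seq_along(object@shapes)) {
    s <- object@shapes[[i]]
    if (!is.list(s) || is.null(s$points) || is.null(s$label))
      return(sprintf("shape %d must have 'label' and 'points'", i))
    if (!is.matrix(s$points) || ncol(s$points) != 2L || nrow(s$points) < 3L)
      return(sprintf("shape %d must have >= 3 (x, y) points", i))
  }
  TRUE
})

#' Aligned image, mask and class label
#'
#' The unit flowing through the data pipeline: an RGB image with values in
#' [0, 1], its binary lesion mask (same spatial size, values 0/1), and the
#' CIN grade of the image.
#'
#' @slot image H x W x 3 numeric array in [0, 1].
#' @slot mask H x W integer matrix with values in {0, 1}.
#' @slot classLabel one of \code{"CIN1"}, \code{"CIN2"}, \code{"CIN3"}.
#' @slot id sample identifier.
#' @export
setClass("SamplePair",
  representation(image = "array", mask = "matrix", classLabel = "character",
                 id = "character"))

setValidity("SamplePair", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) return("image must be H x W x 3")
  if (!all(dim(object@mask) == d[1:2]))
    return("mask spatial dimensions must equal the image's")
  if (min(object@image) < -1e-9 || max(object@image) > 1 + 1e-9)
    return("image values must lie in [0, 1]")
  if (!all(object@mask %in% c(0L, 1L))) return("mask values must be 0/1")
  if (!object@classLabel %in% CIN_LEVELS)
    return("classLabel must be one of CIN1, CIN2, CIN3")
  TRUE
})

#' Dataset manifest
#'
#' A table of samples: one row per image with its mask (or annotation) path
#' and CIN grade. Columns: \code{id}, \code{image_path}, \code{mask_path},
#' \code{class_label}, optionally \code{annotation_path}.
#'
#' @slot records data.frame as described above.
#' @export
setClass("DatasetManifest", representation(records = "data.frame"))

setValidity("DatasetManifest", function(object) {
  need <- c("id", "image_path", "mask_path", "class_label")
  if (!all(need %in% names(object@records)))
    return(paste("manifest must have columns:", paste(need, collapse = ", ")))
  if (!all(object@records$class_label %in% CIN_LEVELS))
    return("class_label values must be CIN1, CIN2 or CIN3")
  if (anyDuplicated(object@records$id)) return("sample ids must be unique")
  TRUE
})

#' Augmentation policy
#'
#' Magnitudes for the paired image/mask augmentations: random rotations,
#' horizontal/vertical flips, brightness/contrast jitter (image only) and
#' elastic deformation. Geometric transforms are applied identically to
#' image and mask; the mask is resampled with nearest neighbor so it stays
#' binary.
#'
#' @slot rotationLimit maximum absolute rotation, degrees.
#' @slot flipHorizontal,flipVertical enable the respective flips (p = 0.5).
#' @slot brightnessLimit,contrastLimit maximum absolute adjustment, fractions.
#' @slot elasticAlpha displacement magnitude, pixels (0 disables).
#' @slot elasticSigma smoothing bandwidth of the displacement field, pixels.
#' @export
setClass("AugmentationPolicy",
  representation(rotationLimit = "numeric", flipHorizontal = "logical",
                 flipVertical = "logical", brightnessLimit = "numeric",
                 contrastLimit = "numeric", elasticAlpha = "numeric",
                 elasticSigma = "numeric"))

setValidity("AugmentationPolicy", function(object) {
  lims <- c(object@rotationLimit, object@brightnessLimit,
            object@contrastLimit, object@elasticAlpha, object@elasticSigma)
  if (any(lims < 0)) return("all limits must be >= 0")
  TRUE
})

#' Train/validation/test split specification
#'
#' @slot ratios fractions for (train, validation, test); must sum to 1.
#' @slot seed RNG seed making the split reproducible.
#' @slot stratifyByClass preserve per-class proportions in each split.
#' @export
setClass("SplitSpec",
  representation(ratios = "numeric", seed = "integer",
                 stratifyByClass = "logical"))

setValidity("SplitSpec", function(object) {
  if (length(object@ratios) != 3L) return("ratios must have length 3")
  if (abs(sum(object@ratios) - 1) > 1e-8) return("ratios must sum to 1")
  if (any(object@ratios < 0)) return("ratios must be non-negative")
  TRUE
})

#' Loss configuration
#'
#' Parameters of the hybrid Dice + Tversky loss. \code{alpha} weights false
#' negatives and \code{beta} false positives in the Tversky term; raising
#' \code{alpha} above \code{beta} penalizes missed lesion pixels more, the
#' sensible asymmetry when small lesions must not be overlooked.
#'
#' @slot alpha false-negative weight (>= 0).
#' @slot beta false-positive weight (>= 0).
#' @slot epsilon smoothing constant (> 0) guarding the ratios.
#' @slot includeBCE also add a pixel-wise binary cross-entropy term
#'   (off by default; the hybrid loss is Dice + Tversky).
#' @export
setClass("LossConfig",
  representation(alpha = "numeric", beta = "numeric", epsilon = "numeric",
                 includeBCE = "logical"))

setValidity("LossConfig", function(object) {
  if (object@epsilon <= 0) return("epsilon must be > 0")
  if (object@alpha < 0 || object@beta < 0) return("alpha, beta must be >= 0")
  TRUE
})

#' Segmentation network configuration
#'
#' Widths and structural switches of the dual-encoder network. The defaults
#' realize the published tensor contract for 256 x 256 inputs: residual-style
#' taps projected to 64/128/256/512 channels, depthwise-separable-style taps
#' to 16/24/32/96 channels, a 608-channel fused bottleneck at stride 16, a
#' 4 x 256 = 1024-channel multi-scale context block, and a 512/256/128/64
#' decoder ending in a 1-channel sigmoid map.
#'
#' @slot inputSize input spatial size in pixels; must be divisible by 16.
#' @slot resnetTapChannels projected channels of the 4 residual-branch taps.
#' @slot mobilenetTapChannels projected channels of the 4 lightweight-branch
#'   taps.
#' @slot fusedBottleneckChannels channels of the deepest fused map
#'   (sum of the two deepest tap widths).
#' @slot asppBranchChannels channels per ASPP branch (output is 4x this).
#' @slot asppRates dilation rates of the three convolutional ASPP branches.
#' @slot seReduction bottleneck reduction ratio of the SE attention blocks.
#' @slot decoderChannels output channels of the 4 decoder stages
#'   (strictly decreasing).
#' @slot ablationMode drop the lightweight branch and its fusion (single
#'   residual-style encoder; attention and ASPP retained).
#' @export
setClass("ModelConfig",
  representation(inputSize = "integer", resnetTapChannels = "integer",
                 mobilenetTapChannels = "integer",
                 fusedBottleneckChannels = "integer",
                 asppBranchChannels = "integer", asppRates = "integer",
                 seReduction = "integer", decoderChannels = "integer",
                 ablationMode = "logical"))

setValidity("ModelConfig", function(object) {
  if (object@inputSize %% 16L != 0L)
    return("inputSize must be divisible by 16")
  if (length(object@resnetTapChannels) != 4L ||
      length(object@mobilenetTapChannels) != 4L)
    return("tap channel vectors must have length 4")
  if (any(object@resnetTapChannels <= 0L) ||
      any(object@mobilenetTapChannels <= 0L))
    return("tap channels must be positive")
  if (length(object@asppRates) != 3L) return("asppRates must have length 3")
  if (length(object@decoderChannels) != 4L ||
      any(diff(object@decoderChannels) >= 0L))
    return("decoderChannels must be 4 strictly decreasing values")
  expected <- object@resnetTapChannels[4] +
    (if (object@ablationMode) 0L else object@mobilenetTapChannels[4])
  if (object@fusedBottleneckChannels != expected)
    return("fusedBottleneckChannels must equal the sum of the deepest taps")
  TRUE
})

#' Multi-scale feature pyramid
#'
#' Four feature maps at strides 2, 4, 8, 16 relative to the input, stored in
#' the engine's (N*H*W) x C matrix layout (see \code{\link{featureArray}}).
#'
#' @slot levels list of 4 batched activation matrices.
#' @slot strides integer strides of the levels.
#' @export
setClass("FeaturePyramid",
  representation(levels = "list", strides = "integer"))

setValidity("FeaturePyramid", function(object) {
  if (length(object@levels) != length(object@strides))
    return("levels and strides lengths differ")
  if (any(diff(object@strides) <= 0L))
    return("strides must be strictly increasing")
  TRUE
})

#' Pixel confusion counts
#'
#' The (k+1) x (k+1) matrix p with p[i, j] = number of pixels of true class
#' i predicted as class j (classes 0..k; binary lesion task: k = 1, so rows
#' and columns are background then lesion). Every region metric of the
#' evaluation suite derives from this matrix.
#'
#' @slot k number of classes minus one.
#' @slot p the counts matrix.
#' @export
setClass("ConfusionCounts", representation(k = "integer", p = "matrix"))

setValidity("ConfusionCounts", function(object) {
  if (!all(dim(object@p) == object@k + 1L)) return("p must be (k+1) x (k+1)")
  if (any(object@p < 0)) return("counts must be non-negative")
  TRUE
})

#' Aggregated evaluation report
#'
#' @slot pa,mpa,miou,fwiou,dice pooled fractional metrics in [0, 1].
#' @slot hausdorff mean per-image Hausdorff distance in pixels
#'   (\code{NA} when undefined for every image).
#' @slot kappa mean per-image Cohen's kappa in [-1, 1].
#' @slot nImages number of image pairs scored.
#' @slot details list with per-image values and exclusion counts.
#' @export
setClass("MetricReport",
  representation(pa = "numeric", mpa = "numeric", miou = "numeric",
                 fwiou = "numeric", dice = "numeric", hausdorff = "numeric",
                 kappa = "numeric", nImages = "integer", details = "list"))

setValidity("MetricReport", function(object) {
  fr <- c(object@pa, object@mpa, object@miou, object@fwiou, object@dice)
  fr <- fr[!is.na(fr)]
  if (length(fr) && (min(fr) < -1e-9 || max(fr) > 1 + 1e-9))
    return("fractional metrics must lie in [0, 1]")
  TRUE
})

#' Class-activation heatmap
#'
#' A normalized Grad-CAM++ map: values in [0, 1], maximum exactly 1 whenever
#' any activation survived the ReLU.
#'
#' @slot values H x W numeric matrix in [0, 1].
#' @slot sourceLayer identifier of the feature map the heatmap explains.
#' @slot targetDescription short description of the scalar target used.
#' @export
setClass("Heatmap",
  representation(values = "matrix", sourceLayer = "character",
                 targetDescription = "character"))

setValidity("Heatmap", function(object) {
  v <- object@values
  if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
    return("heatmap values must lie in [0, 1]")
  TRUE
})

#' Synthetic phantom specification
#'
#' Controls the phantom generator that emulates colposcopic appearance with
#' exact ground truth: a bright pinkish elliptical cervix field on a dark
#' background, irregular smooth-boundary acetowhite lesion blobs inside it
#' whose total area fraction is class dependent, Gaussian texture noise and
#' optional small specular highlights that are never part of the mask.
#'
#' @slot size image side in pixels (>= 32).
#' @slot classLabel CIN grade the phantom represents.
#' @slot lesionCount number of lesion blobs (>= 0).
#' @slot areaFractionRange (lo, hi) bounds on the total lesion area fraction.
#' @slot lesionContrast grayscale brightness added inside lesions.
#' @slot noiseSigma standard deviation of the additive Gaussian noise.
#' @slot specularArtifacts number of specular discs.
#' @slot seed RNG seed; phantoms are bit-reproducible given the seed.
#' @export
setClass("PhantomSpec",
  representation(size = "integer", classLabel = "character",
                 lesionCount = "integer", areaFractionRange = "numeric",
                 lesionContrast = "numeric", noiseSigma = "numeric",
                 specularArtifacts = "integer", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (object@size < 32L) return("size must be >= 32")
  r <- object@areaFractionRange
  if (length(r) != 2L || r[1] < 0 || r[2] > 0.5 || r[1] > r[2])
    return("areaFractionRange must satisfy 0 <= lo <= hi <= 0.5")
  if (!object@classLabel %in% CIN_LEVELS)
    return("classLabel must be one of CIN1, CIN2, CIN3")
  if (object@lesionCount < 0L) return("lesionCount must be >= 0")
  TRUE
})

#' Training configuration
#'
#' @slot epochs maximum training epochs.
#' @slot batchSize minibatch size.
#' @slot learningRate initial Adam learning rate.
#' @slot earlyStoppingPatience epochs without validation improvement before
#'   halting.
#' @slot lrFactor,lrPatience reduce-on-plateau schedule: multiply the rate by
#'   \code{lrFactor} after \code{lrPatience} stale epochs.
#' @slot loss \linkS4class{LossConfig}.
#' @slot model \linkS4class{ModelConfig}.
#' @slot seed RNG seed for initialization, shuffling and augmentation.
#' @slot freezeBackbones do not update encoder parameters.
#' @slot onlineAugment apply the augmentation policy to each training batch.
#' @slot augmentation \linkS4class{AugmentationPolicy} used when
#'   \code{onlineAugment} is on.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", earlyStoppingPatience = "integer",
                 lrFactor = "numeric", lrPatience = "integer",
                 loss = "LossConfig", model = "ModelConfig", seed = "integer",
                 freezeBackbones = "logical", onlineAugment = "logical",
                 augmentation = "AugmentationPolicy"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  TRUE
})

#' Assembled segmentation network
#'
#' Wraps the engine state of a built network: its parameters, batch-norm
#' running statistics and forward closure. Use \code{\link{predictMask}} for
#' inference, \code{\link{trainModel}} to fit, and \code{\link{paramCount}}
#' for the parameter total.
#'
#' @slot config the \linkS4class{ModelConfig} the network was built from.
#' @slot engine environment holding parameters and the forward function.
#' @export
setClass("SegModel",
  representation(config = "ModelConfig", engine = "environment"))

#' Training run log
#'
#' @slot history data.frame with one row per epoch: train loss, validation
#'   loss, validation Dice and the learning rate in force.
#' @slot bestEpoch epoch with the lowest validation loss.
#' @slot checkpointPath where the best weights were saved ("" if not saved).
#' @slot wallTime elapsed seconds (informational).
#' @export
setClass("RunLog",
  representation(history = "data.frame", bestEpoch = "integer",
                 checkpointPath = "character", wallTime = "numeric"))
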