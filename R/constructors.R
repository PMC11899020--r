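# User-facing constructors and show methods.

#' Build an annotation set in code
#'
#' @param imageHeight,imageWidth image dimensions in pixels.
#' @param shapes list of shapes; each a list with \code{label} and
#'   \code{points} (n x 2 matrix of (x, y), LabelMe convention).
#' @param sourcePath optional provenance path.
#' @return an \linkS4class{AnnotationSet}.
#' @export
annotationSet <- function(imageHeight, imageWidth, shapes = list(),
                          sourcePath = NA_character_) {
  new("AnnotationSet", imageHeight = as.integer(imageHeight),
      imageWidth = as.integer(imageWidth), shapes = shapes,
      sourcePath = sourcePath)
}

#' Build a sample pair
#'
#' @param image H x W x 3 array in [0, 1].
#' @param mask H x W matrix of 0/1 (numeric or integer).
#' @param classLabel CIN grade.
#' @param id sample identifier.
#' @return a \linkS4class{SamplePair}.
#' @export
samplePair <- function(image, mask, classLabel = "CIN1", id = "sample") {
  storage.mode(mask) <- "integer"
  new("SamplePair", image = image, mask = mask, classLabel = classLabel,
      id = id)
}

#' Default augmentation policy
#'
#' Rotation within +-30 degrees, both flips at probability 0.5, brightness
#' and contrast jitter of +-0.2, and elastic deformation with displacement
#' 40 px smoothed at 6 px. The transform families follow the preparation
#' protocol; the magnitudes are conventional medical-imaging defaults and
#' all configurable.
#'
#' @param rotationLimit,flipHorizontal,flipVertical,brightnessLimit
#'   see \linkS4class{AugmentationPolicy}.
#' @param contrastLimit,elasticAlpha,elasticSigma see
#'   \linkS4class{AugmentationPolicy}.
#' @return an \linkS4class{AugmentationPolicy}.
#' @export
augmentationPolicy <- function(rotationLimit = 30, flipHorizontal = TRUE,
                               flipVertical = TRUE, brightnessLimit = 0.2,
                               contrastLimit = 0.2, elasticAlpha = 40,
                               elasticSigma = 6) {
  new("AugmentationPolicy", rotationLimit = rotationLimit,
      flipHorizontal = flipHorizontal, flipVertical = flipVertical,
      brightnessLimit = brightnessLimit, contrastLimit = contrastLimit,
      elasticAlpha = elasticAlpha, elasticSigma = elasticSigma)
}

#' Identity augmentation policy (no-op)
#' @return an \linkS4class{AugmentationPolicy} with all limits zero and
#'   flips disabled.
#' @export
identityPolicy <- function() {
  augmentationPolicy(rotationLimit = 0, flipHorizontal = FALSE,
                     flipVertical = FALSE, brightnessLimit = 0,
                     contrastLimit = 0, elasticAlpha = 0, elasticSigma = 1)
}

#' Split specification
#'
#' @param ratios train/validation/test fractions (default 8:1:1).
#' @param seed RNG seed.
#' @param stratifyByClass preserve class proportions per split.
#' @return a \linkS4class{SplitSpec}.
#' @export
splitSpec <- function(ratios = c(0.8, 0.1, 0.1), seed = 1L,
                      stratifyByClass = TRUE) {
  new("SplitSpec", ratios = ratios, seed = as.integer(seed),
      stratifyByClass = stratifyByClass)
}

#' Loss configuration
#'
#' Defaults emphasize false negatives (alpha = 0.7 vs beta = 0.3): a missed
#' lesion pixel costs more than a spurious one, the clinically conservative
#' choice for screening.
#'
#' @param alpha false-negative weight.
#' @param beta false-positive weight.
#' @param epsilon smoothing constant.
#' @param includeBCE add a binary cross-entropy term (default off).
#' @return a \linkS4class{LossConfig}.
#' @export
lossConfig <- function(alpha = 0.7, beta = 0.3, epsilon = 1e-6,
                       includeBCE = FALSE) {
  new("LossConfig", alpha = alpha, beta = beta, epsilon = epsilon,
      includeBCE = includeBCE)
}

#' Network configuration
#'
#' The defaults reproduce the published tensor contract at 256 x 256 input.
#' Smaller widths (see \code{\link{deskModelConfig}}) keep the same topology
#' for CPU-scale experiments.
#'
#' @param inputSize input side in pixels (divisible by 16).
#' @param resnetTapChannels,mobilenetTapChannels projected tap widths.
#' @param asppBranchChannels per-branch ASPP width.
#' @param asppRates dilation rates of the convolutional ASPP branches.
#' @param seReduction SE bottleneck reduction ratio.
#' @param decoderChannels decoder stage widths (strictly decreasing).
#' @param ablationMode single-encoder variant (residual branch only).
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(inputSize = 256L,
                        resnetTapChannels = c(64L, 128L, 256L, 512L),
                        mobilenetTapChannels = c(16L, 24L, 32L, 96L),
                        asppBranchChannels = 256L,
                        asppRates = c(1L, 6L, 12L),
                        seReduction = 16L,
                        decoderChannels = c(512L, 256L, 128L, 64L),
                        ablationMode = FALSE) {
  resnetTapChannels <- as.integer(resnetTapChannels)
  mobilenetTapChannels <- as.integer(mobilenetTapChannels)
  fused <- resnetTapChannels[4] +
    (if (ablationMode) 0L else mobilenetTapChannels[4])
  new("ModelConfig", inputSize = as.integer(inputSize),
      resnetTapChannels = resnetTapChannels,
      mobilenetTapChannels = mobilenetTapChannels,
      fusedBottleneckChannels = fused,
      asppBranchChannels = as.integer(asppBranchChannels),
      asppRates = as.integer(asppRates),
      seReduction = as.integer(seReduction),
      decoderChannels = as.integer(decoderChannels),
      ablationMode = ablationMode)
}

#' Phantom specification
#'
#' Per-class default lesion area fractions are CIN1 (0.02, 0.06), CIN2
#' (0.06, 0.12), CIN3 (0.12, 0.22): a monotone, class-correlated signal with
#' genuinely small CIN1 lesions, exercising the class-imbalance rationale of
#' the Tversky term.
#'
#' @param size image side in pixels.
#' @param classLabel CIN grade.
#' @param lesionCount number of lesion blobs.
#' @param areaFractionRange total lesion area fraction bounds; default picked
#'   by class as above.
#' @param lesionContrast added grayscale brightness inside lesions.
#' @param noiseSigma additive Gaussian noise level.
#' @param specularArtifacts number of specular highlight discs.
#' @param seed RNG seed.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(size = 256L, classLabel = "CIN1", lesionCount = 2L,
                        areaFractionRange = NULL, lesionContrast = 0.25,
                        noiseSigma = 0.03, specularArtifacts = 3L,
                        seed = 1L) {
  if (is.null(areaFractionRange)) {
    areaFractionRange <- switch(classLabel,
      CIN1 = c(0.02, 0.06), CIN2 = c(0.06, 0.12), CIN3 = c(0.12, 0.22),
      c(0.02, 0.22))
  }
  new("PhantomSpec", size = as.integer(size), classLabel = classLabel,
      lesionCount = as.integer(lesionCount),
      areaFractionRange = areaFractionRange,
      lesionContrast = lesionContrast, noiseSigma = noiseSigma,
      specularArtifacts = as.integer(specularArtifacts),
      seed = as.integer(seed))
}

#' Training configuration
#'
#' Full-scale defaults follow the published training strategy: Adam, 300
#' epochs, batch 16, learning rate 1e-4, early stopping and
#' reduce-on-plateau scheduling. See \code{\link{deskRecipe}} for the
#' CPU-scale phantom recipe.
#'
#' @param epochs,batchSize,learningRate core optimizer settings.
#' @param earlyStoppingPatience epochs without improvement before halting.
#' @param lrFactor,lrPatience reduce-on-plateau schedule.
#' @param loss a \linkS4class{LossConfig}.
#' @param model a \linkS4class{ModelConfig}.
#' @param seed RNG seed.
#' @param freezeBackbones keep encoder weights fixed.
#' @param onlineAugment augment each training batch on the fly.
#' @param augmentation policy used for online augmentation.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(epochs = 300L, batchSize = 16L, learningRate = 1e-4,
                        earlyStoppingPatience = 25L, lrFactor = 0.5,
                        lrPatience = 10L, loss = lossConfig(),
                        model = modelConfig(), seed = 1L,
                        freezeBackbones = FALSE, onlineAugment = TRUE,
                        augmentation = augmentationPolicy()) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      earlyStoppingPatience = as.integer(earlyStoppingPatience),
      lrFactor = lrFactor, lrPatience = as.integer(lrPatience), loss = loss,
      model = model, seed = as.integer(seed),
      freezeBackbones = freezeBackbones, onlineAugment = onlineAugment,
      augmentation = augmentation)
}

#' Build a manifest from a records table
#' @param records data.frame with columns id, image_path, mask_path,
#'   class_label (optionally annotation_path).
#' @return a \linkS4class{DatasetManifest}.
#' @export
datasetManifest <- function(records) {
  records$id <- as.character(records$id)
  new("DatasetManifest", records = records)
}

#' Per-class sample counts of a manifest
#' @param manifest a \linkS4class{DatasetManifest}.
#' @return named integer vector of counts per CIN grade present.
#' @export
classCounts <- function(manifest) {
  stopifnot(is(manifest, "DatasetManifest"))
  tab <- table(factor(manifest@records$class_label, levels = CIN_LEVELS))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[out > 0 | names(out) %in% unique(manifest@records$class_label)]
}

#' Number of samples in a manifest
#' @param manifest a \linkS4class{DatasetManifest}.
#' @return integer count.
#' @export
manifestSize <- function(manifest) nrow(manifest@records)

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet: %d shape(s), image %d x %d\n",
              length(object@shapes), object@imageHeight, object@imageWidth))
})

setMethod("show", "SamplePair", function(object) {
  d <- dim(object@image)
  cat(sprintf("SamplePair '%s' [%s]: image %d x %d x 3, mask foreground %.1f%%\n",
              object@id, object@classLabel, d[1], d[2],
              100 * mean(object@mask)))
})

setMethod("show", "DatasetManifest", function(object) {
  cc <- table(object@records$class_label)
  cat(sprintf("DatasetManifest: %d samples (%s)\n", nrow(object@records),
              paste(names(cc), as.integer(cc), sep = "=", collapse = ", ")))
})

setMethod("show", "FeaturePyramid", function(object) {
  cat("FeaturePyramid:\n")
  for (k in seq_along(object@levels)) {
    d <- tdim(object@levels[[k]])
    cat(sprintf("  level %d (stride %2d): %d x %d x %d channels, batch %d\n",
                k, object@strides[k], d[2], d[3],
                ncol(object@levels[[k]]), d[1]))
  }
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (k = %d), %g pixels\n", object@k,
              sum(object@p)))
  print(object@p)
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(paste0("MetricReport over %d image(s)\n",
                     "  PA %.4f  MPA %.4f  MIoU %.4f  FWIoU %.4f  Dice %.4f\n",
                     "  Hausdorff %s px  kappa %s\n"),
              object@nImages, object@pa, object@mpa, object@miou,
              object@fwiou, object@dice,
              ifelse(is.na(object@hausdorff), "NA",
                     sprintf("%.2f", object@hausdorff)),
              ifelse(is.na(object@kappa), "NA",
                     sprintf("%.4f", object@kappa))))
})

setMethod("show", "Heatmap", function(object) {
  cat(sprintf("Heatmap %d x %d from layer '%s' (%s)\n",
              nrow(object@values), ncol(object@values), object@sourceLayer,
              object@targetDescription))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig: input %d, taps %s | %s, fused %d, ",
                     "ASPP 4 x %d, decoder %s%s\n"),
              object@inputSize,
              paste(object@resnetTapChannels, collapse = "/"),
              paste(object@mobilenetTapChannels, collapse = "/"),
              object@fusedBottleneckChannels, object@asppBranchChannels,
              paste(object@decoderChannels, collapse = "/"),
              if (object@ablationMode) " [ablation]" else ""))
})

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel (%s): %s parameters\n",
              if (object@config@ablationMode) "single encoder"
              else "dual encoder",
              format(paramCount(object), big.mark = ",")))
  show(object@config)
})

setMethod("show", "RunLog", function(object) {
  cat(sprintf("RunLog: %d epoch(s), best epoch %d (val loss %.4f), %.1f s\n",
              nrow(object@history), object@bestEpoch,
              object@history$val_loss[object@bestEpoch], object@wallTime))
})
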