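# Training and evaluation orchestration.

load_pair <- function(row, input_size) {
  img <- readImagePNG(row$image_path)
  mask <- readMask(row$mask_path)
  if (!all(dim(mask) == c(input_size, input_size)) ||
      !all(dim(img)[1:2] == c(input_size, input_size))) {
    resizeNormalize(img, mask, input_size, classLabel = row$class_label,
                    id = row$id)
  } else {
    samplePair(img, mask, classLabel = row$class_label, id = row$id)
  }
}

load_dataset <- function(manifest, input_size) {
  lapply(seq_len(nrow(manifest@records)), function(i)
    load_pair(manifest@records[i, ], input_size))
}

batch_tensors <- function(pairs) {
  x <- stack_batch(lapply(pairs, function(p) featureMatrix(p@image)))
  y <- do.call(rbind, lapply(pairs, function(p)
    featureMatrix(matrix(as.numeric(p@mask), nrow(p@mask)))))
  list(x = x, y = y)
}

model_loss_node <- function(model, x, y, loss_cfg, training) {
  res <- model@engine$forward(x, training = training, collect = FALSE)
  dice <- ad_dice_loss(y, res$out, eps = loss_cfg@epsilon)
  tv <- ad_tversky_loss(y, res$out, alpha = loss_cfg@alpha,
                        beta = loss_cfg@beta, eps = loss_cfg@epsilon)
  list(loss = ad_scalar_add(dice, tv), out = res$out)
}

trainable_params <- function(model, freeze_backbones) {
  ps <- model@engine$params
  if (!freeze_backbones) return(ps)
  keep <- !grepl("^(resnet|mobilenet)\\.", names(ps))
  ps[keep]
}

#' Train a segmentation model
#'
#' Minimizes the combined Dice + Tversky loss with Adam, shuffling each
#' epoch, optionally augmenting every training batch on the fly, tracking
#' the best validation loss, halting early after
#' \code{config@earlyStoppingPatience} stale epochs, and halving the
#' learning rate (factor \code{config@lrFactor}) after
#' \code{config@lrPatience} stale epochs. The returned model carries the
#' best-validation weights. A NaN loss aborts with diagnostics.
#'
#' @param manifestTrain,manifestVal training and validation
#'   \linkS4class{DatasetManifest}s.
#' @param config a \linkS4class{TrainConfig}.
#' @param checkpointPath optional RDS path for the best weights.
#' @param model optionally continue training an existing
#'   \linkS4class{SegModel} (otherwise one is assembled from
#'   \code{config@model} with \code{config@seed}).
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (a \linkS4class{SegModel}) and \code{log}
#'   (a \linkS4class{RunLog}).
#' @export
trainModel <- function(manifestTrain, manifestVal, config,
                       checkpointPath = NULL, model = NULL, verbose = TRUE) {
  stopifnot(is(config, "TrainConfig"))
  if (manifestSize(manifestTrain) == 0L || manifestSize(manifestVal) == 0L)
    stop("training and validation manifests must be non-empty")
  t0 <- proc.time()[["elapsed"]]
  input_size <- config@model@inputSize
  train_pairs <- load_dataset(manifestTrain, input_size)
  val_pairs <- load_dataset(manifestVal, input_size)
  if (is.null(model)) model <- assembleModel(config@model, seed = config@seed)
  params <- model@engine$params
  upd <- trainable_params(model, config@freezeBackbones)

  lr <- config@learningRate
  best_val <- Inf
  best_epoch <- 0L
  best_state <- NULL
  stale <- 0L
  lr_stale <- 0L
  step <- 0L
  hist <- list()

  with_seed(config@seed + 1L, {
    for (epoch in seq_len(config@epochs)) {
      ord <- sample(length(train_pairs))
      tot_loss <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = config@batchSize)) {
        idx <- ord[start:min(start + config@batchSize - 1L, length(ord))]
        pairs <- train_pairs[idx]
        if (config@onlineAugment)
          pairs <- lapply(pairs, augmentPair, policy = config@augmentation)
        bt <- batch_tensors(pairs)
        ad_zero_grads(params)
        ln <- model_loss_node(model, bt$x, bt$y, config@loss,
                              training = TRUE)
        if (!is.finite(ln$loss$value))
          stop(sprintf(paste0("NaN/Inf loss at epoch %d (lr %.2e, batch ",
                              "mean prob %.3f); aborting"),
                       epoch, lr, mean(ln$out$value)))
        ad_backward(ln$loss)
        step <- step + 1L
        adam_step(upd, lr, step)
        tot_loss <- tot_loss + ln$loss$value
        nb <- nb + 1L
      }
      vm <- validate_once(model, val_pairs, config@loss)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tot_loss / nb,
                                  val_loss = vm$loss, val_dice = vm$dice,
                                  lr = lr)
      if (verbose)
        message(sprintf(
          "epoch %3d  train %.4f  val %.4f  val Dice %.4f  lr %.1e",
          epoch, tot_loss / nb, vm$loss, vm$dice, lr))
      if (vm$loss < best_val - 1e-6) {
        best_val <- vm$loss
        best_epoch <- epoch
        best_state <- snapshot_state(model)
        stale <- 0L
        lr_stale <- 0L
      } else {
        stale <- stale + 1L
        lr_stale <- lr_stale + 1L
        if (lr_stale >= config@lrPatience) {
          lr <- lr * config@lrFactor
          lr_stale <- 0L
        }
        if (stale >= config@earlyStoppingPatience) break
      }
    }
  })
  if (!is.null(best_state)) restore_state(model, best_state)
  ckpt <- ""
  if (!is.null(checkpointPath)) {
    saveCheckpoint(model, checkpointPath)
    ckpt <- checkpointPath
  }
  log <- new("RunLog", history = do.call(rbind, hist),
             bestEpoch = best_epoch, checkpointPath = ckpt,
             wallTime = proc.time()[["elapsed"]] - t0)
  list(model = model, log = log)
}

validate_once <- function(model, val_pairs, loss_cfg) {
  bt <- batch_tensors(val_pairs)
  res <- model@engine$forward(bt$x, training = FALSE, collect = FALSE)
  loss <- diceLoss(bt$y, res$out$value, epsilon = loss_cfg@epsilon) +
    tverskyLoss(bt$y, res$out$value, alpha = loss_cfg@alpha,
                beta = loss_cfg@beta, epsilon = loss_cfg@epsilon)
  pred <- (res$out$value > 0.5) * 1
  tp <- sum(bt$y * pred); fp <- sum((1 - bt$y) * pred)
  fn <- sum(bt$y * (1 - pred))
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  list(loss = loss, dice = dice)
}

snapshot_state <- function(model) {
  list(params = lapply(model@engine$params, function(p) p$value),
       bn = lapply(model@engine$bn, function(s)
         list(rm = s$rm, rv = s$rv)))
}

restore_state <- function(model, state) {
  for (nm in names(state$params))
    model@engine$params[[nm]]$value <- state$params[[nm]]
  for (nm in names(state$bn)) {
    model@engine$bn[[nm]]$rm <- state$bn[[nm]]$rm
    model@engine$bn[[nm]]$rv <- state$bn[[nm]]$rv
  }
  invisible(model)
}

#' Save model weights to an RDS checkpoint
#' @param model a \linkS4class{SegModel}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
saveCheckpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(config = model@config, state = snapshot_state(model)), path)
  invisible(path)
}

#' Load a model from a checkpoint
#' @param path RDS file written by \code{\link{saveCheckpoint}}.
#' @return a \linkS4class{SegModel} with restored weights.
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  model <- assembleModel(obj$config, seed = 1L)
  restore_state(model, obj$state)
  model
}

#' Evaluate a model on a test manifest
#'
#' Predicts every test image, binarizes at \code{threshold}, and scores
#' the full metric suite (pooled region metrics; per-image Hausdorff and
#' kappa). A threshold at or above 1 produces empty predictions, for which
#' the Hausdorff distance is undefined and reported as missing.
#'
#' @param manifestTest a \linkS4class{DatasetManifest}.
#' @param model a \linkS4class{SegModel} or a checkpoint path.
#' @param threshold probability cutoff.
#' @param perImage include per-image rows in the report details.
#' @return a \linkS4class{MetricReport}.
#' @export
evaluateModel <- function(manifestTest, model, threshold = 0.5,
                          perImage = FALSE) {
  if (is.character(model)) model <- loadCheckpoint(model)
  stopifnot(is(model, "SegModel"))
  pairs <- load_dataset(manifestTest, model@config@inputSize)
  mask_pairs <- lapply(pairs, function(p) {
    list(truth = p@mask, prediction = predictMask(model, p, threshold))
  })
  evaluateDataset(mask_pairs, perImage = perImage)
}

#' Desk-scale phantom training recipe
#'
#' The package's CPU-scale end-to-end study conditions: 64 x 64 phantoms,
#' 150 training / 30 validation / 30 test images (50/10/10 per CIN grade),
#' the reduced-width network of \code{\link{deskModelConfig}} with randomly
#' initialized encoders, combined Dice + Tversky loss, Adam at 1e-3 for 30
#' epochs with batch 8 and online augmentation off. Sized so a full
#' train/evaluate cycle completes in minutes on one CPU while remaining
#' learnable to a held-out Dice of 0.8 or better.
#'
#' @param seed RNG seed for the run.
#' @param ablationMode train the single-encoder variant.
#' @return list with \code{nPerClass} (train/val/test counts per class) and
#'   \code{config} (a \linkS4class{TrainConfig}).
#' @export
deskRecipe <- function(seed = 1L, ablationMode = FALSE) {
  list(
    nPerClass = c(train = 50L, validation = 10L, test = 10L),
    config = trainConfig(
      epochs = 30L, batchSize = 8L, learningRate = 1e-3,
      earlyStoppingPatience = 30L, lrFactor = 0.5, lrPatience = 10L,
      loss = lossConfig(), model = deskModelConfig(64L, ablationMode),
      seed = seed, freezeBackbones = FALSE, onlineAugment = FALSE))
}

#' Run the desk-scale phantom experiment
#'
#' Generates the phantom splits, trains with the desk recipe, and evaluates
#' on the held-out test set.
#'
#' @param seed RNG seed controlling phantom generation and training.
#' @param dir working directory for the generated dataset (default
#'   temporary).
#' @param ablationMode train the single-encoder variant.
#' @param verbose print progress.
#' @return list with \code{report} (\linkS4class{MetricReport}),
#'   \code{log} (\linkS4class{RunLog}) and \code{model}.
#' @export
runDeskExperiment <- function(seed = 1L, dir = tempfile("desk"),
                              ablationMode = FALSE, verbose = TRUE) {
  recipe <- deskRecipe(seed = seed, ablationMode = ablationMode)
  n <- recipe$nPerClass
  man_train <- generatePhantomDataset(rep(n[["train"]], 3),
                                      file.path(dir, "train"), size = 64L,
                                      seed = seed)
  man_val <- generatePhantomDataset(rep(n[["validation"]], 3),
                                    file.path(dir, "val"), size = 64L,
                                    seed = seed + 1000L)
  man_test <- generatePhantomDataset(rep(n[["test"]], 3),
                                     file.path(dir, "test"), size = 64L,
                                     seed = seed + 2000L)
  fit <- trainModel(man_train, man_val, recipe$config, verbose = verbose)
  report <- evaluateModel(man_test, fit$model)
  list(report = report, log = fit$log, model = fit$model)
}

#' Read a training configuration from YAML
#'
#' Recognized top-level blocks: \code{train} (epochs, batch_size,
#' learning_rate, early_stopping_patience, lr_factor, lr_patience, seed,
#' freeze_backbones, online_augment), \code{loss} (alpha, beta, epsilon),
#' \code{model} (input_size, resnet_tap_channels, mobilenet_tap_channels,
#' aspp_branch_channels, aspp_rates, se_reduction, decoder_channels,
#' ablation_mode) and \code{augmentation} (rotation_limit, flip_horizontal,
#' flip_vertical, brightness_limit, contrast_limit, elastic_alpha,
#' elastic_sigma). Unspecified fields keep the package defaults.
#'
#' @param path YAML file.
#' @return a \linkS4class{TrainConfig}.
#' @export
readTrainConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  pick <- function(block, key, default) {
    v <- y[[block]][[key]]
    if (is.null(v)) default else v
  }
  model <- modelConfig(
    inputSize = pick("model", "input_size", 256L),
    resnetTapChannels = pick("model", "resnet_tap_channels",
                             c(64L, 128L, 256L, 512L)),
    mobilenetTapChannels = pick("model", "mobilenet_tap_channels",
                                c(16L, 24L, 32L, 96L)),
    asppBranchChannels = pick("model", "aspp_branch_channels", 256L),
    asppRates = pick("model", "aspp_rates", c(1L, 6L, 12L)),
    seReduction = pick("model", "se_reduction", 16L),
    decoderChannels = pick("model", "decoder_channels",
                           c(512L, 256L, 128L, 64L)),
    ablationMode = pick("model", "ablation_mode", FALSE))
  loss <- lossConfig(alpha = pick("loss", "alpha", 0.7),
                     beta = pick("loss", "beta", 0.3),
                     epsilon = pick("loss", "epsilon", 1e-6))
  aug <- augmentationPolicy(
    rotationLimit = pick("augmentation", "rotation_limit", 30),
    flipHorizontal = pick("augmentation", "flip_horizontal", TRUE),
    flipVertical = pick("augmentation", "flip_vertical", TRUE),
    brightnessLimit = pick("augmentation", "brightness_limit", 0.2),
    contrastLimit = pick("augmentation", "contrast_limit", 0.2),
    elasticAlpha = pick("augmentation", "elastic_alpha", 40),
    elasticSigma = pick("augmentation", "elastic_sigma", 6))
  trainConfig(
    epochs = pick("train", "epochs", 300L),
    batchSize = pick("train", "batch_size", 16L),
    learningRate = pick("train", "learning_rate", 1e-4),
    earlyStoppingPatience = pick("train", "early_stopping_patience", 25L),
    lrFactor = pick("train", "lr_factor", 0.5),
    lrPatience = pick("train", "lr_patience", 10L),
    loss = loss, model = model,
    seed = pick("train", "seed", 1L),
    freezeBackbones = pick("train", "freeze_backbones", FALSE),
    onlineAugment = pick("train", "online_augment", TRUE),
    augmentation = aug)
}
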