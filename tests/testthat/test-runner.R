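tiny_train_config <- function(epochs = 1L, seed = 1L, size = 32L,
                              freeze = FALSE, ablation = FALSE) {
  trainConfig(epochs = epochs, batchSize = 3L, learningRate = 1e-3,
              earlyStoppingPatience = 50L, lrFactor = 0.5, lrPatience = 20L,
              loss = lossConfig(), model = tiny_model_config(size, ablation),
              seed = seed, freezeBackbones = freeze, onlineAugment = FALSE)
}

test_that("one training epoch produces a log and a checkpoint", {
  withr::local_seed(50)
  setup <- tiny_train_setup(seed = 60)
  ckpt <- withr::local_tempfile(fileext = ".rds")
  fit <- suppressMessages(trainModel(setup$train, setup$val,
                                     tiny_train_config(epochs = 1L),
                                     checkpointPath = ckpt, verbose = FALSE))
  expect_s4_class(fit$log, "RunLog")
  expect_equal(nrow(fit$log@history), 1L)
  expect_true(file.exists(ckpt))
  expect_true(all(is.finite(fit$log@history$train_loss)))

  # checkpoint restores the exact weights
  m2 <- suppressMessages(loadCheckpoint(ckpt))
  expect_equal(lapply(m2@engine$params, function(p) p$value),
               lapply(fit$model@engine$params, function(p) p$value))
})

test_that("training reduces the loss on a learnable phantom problem", {
  withr::local_seed(51)
  setup <- tiny_train_setup(seed = 61, n_train = 9, n_val = 3)
  fit <- suppressMessages(trainModel(setup$train, setup$val,
                                     tiny_train_config(epochs = 6L,
                                                       seed = 2L),
                                     verbose = FALSE))
  h <- fit$log@history
  expect_lt(h$train_loss[6], h$train_loss[1])
  expect_gte(fit$log@bestEpoch, 1L)
  # best tracked validation loss never exceeds any later recorded minimum
  expect_equal(h$val_loss[fit$log@bestEpoch], min(h$val_loss))
})

test_that("frozen encoders keep their parameters fixed", {
  withr::local_seed(52)
  setup <- tiny_train_setup(seed = 62)
  cfg <- tiny_train_config(epochs = 1L, freeze = TRUE)
  model <- suppressMessages(assembleModel(cfg@model, seed = cfg@seed))
  before <- lapply(model@engine$params, function(p) p$value)
  fit <- suppressMessages(trainModel(setup$train, setup$val, cfg,
                                     model = model, verbose = FALSE))
  after <- lapply(fit$model@engine$params, function(p) p$value)
  bb <- grep("^(resnet|mobilenet)\\.", names(before), value = TRUE)
  expect_gt(length(bb), 0L)
  for (nm in bb) expect_identical(after[[nm]], before[[nm]])
  head_nms <- grep("^decoder", names(before), value = TRUE)
  expect_false(all(vapply(head_nms, function(nm)
    identical(after[[nm]], before[[nm]]), logical(1))))
})

test_that("evaluation reports the full metric suite and handles empty preds", {
  withr::local_seed(53)
  setup <- tiny_train_setup(seed = 63, n_train = 3, n_val = 3)
  cfg <- tiny_train_config()
  model <- suppressMessages(assembleModel(cfg@model, seed = 7))
  rep <- evaluateModel(setup$val, model)
  expect_s4_class(rep, "MetricReport")
  expect_equal(rep@nImages, 3L)
  expect_true(all(c(rep@pa, rep@miou, rep@fwiou) >= 0))

  # threshold at/above 1 -> empty predictions -> the undefined-HD path
  rep2 <- evaluateModel(setup$val, model, threshold = 1)
  expect_true(is.na(rep2@hausdorff))
  expect_equal(rep2@details$hd_excluded, 3L)
})

test_that("ablation and full model both train one epoch without NaN", {
  withr::local_seed(54)
  setup <- tiny_train_setup(seed = 64)
  for (abl in c(FALSE, TRUE)) {
    fit <- suppressMessages(trainModel(setup$train, setup$val,
                                       tiny_train_config(ablation = abl),
                                       verbose = FALSE))
    expect_true(all(is.finite(fit$log@history$train_loss)),
                label = sprintf("ablation = %s", abl))
  }
})

test_that("YAML configuration round-trips into a TrainConfig", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "train:",
    "  epochs: 12",
    "  batch_size: 4",
    "  learning_rate: 0.001",
    "  seed: 9",
    "loss:",
    "  alpha: 0.6",
    "  beta: 0.4",
    "model:",
    "  input_size: 64",
    "  ablation_mode: true",
    "  resnet_tap_channels: [8, 16, 32, 64]",
    "  mobilenet_tap_channels: [4, 6, 8, 12]",
    "  aspp_branch_channels: 16",
    "  decoder_channels: [32, 24, 16, 12]",
    "augmentation:",
    "  rotation_limit: 15"), f)
  cfg <- readTrainConfig(f)
  expect_equal(cfg@epochs, 12L)
  expect_equal(cfg@batchSize, 4L)
  expect_equal(cfg@loss@alpha, 0.6)
  expect_equal(cfg@model@inputSize, 64L)
  expect_true(cfg@model@ablationMode)
  expect_equal(cfg@model@fusedBottleneckChannels, 64L)
  expect_equal(cfg@augmentation@rotationLimit, 15)
  # defaults survive for unspecified fields
  expect_equal(cfg@lrFactor, 0.5)
  expect_equal(cfg@loss@epsilon, 1e-6)
})
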