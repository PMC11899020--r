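test_that("encoder taps have the contracted channels and strides", {
  withr::local_seed(30)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  res <- extractTaps(makeBackbone("resnet50-style", seed = 1), img)
  mob <- extractTaps(makeBackbone("mobilenetv2-style", seed = 1), img)
  for (k in 1:4) {
    dr <- cervseg:::tdim(res@levels[[k]])
    dm <- cervseg:::tdim(mob@levels[[k]])
    expect_equal(dr[2:3], c(64, 64) / res@strides[k])
    expect_equal(dm[2:3], c(64, 64) / mob@strides[k])
  }
  expect_equal(vapply(res@levels, ncol, integer(1)), c(64L, 128L, 256L, 512L))
  expect_equal(vapply(mob@levels, ncol, integer(1)), c(16L, 24L, 32L, 96L))
  expect_equal(res@strides, c(2L, 4L, 8L, 16L))
  expect_error(extractTaps(makeBackbone("resnet50-style"),
                           array(0, c(60, 60, 3))), "divisible by 16")
})

test_that("fusion concatenates channels after spatial alignment", {
  withr::local_seed(31)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  res <- extractTaps(makeBackbone("resnet50-style", seed = 1), img)
  mob <- extractTaps(makeBackbone("mobilenetv2-style", seed = 1), img)
  fused <- alignAndFuse(res, mob)
  expect_equal(vapply(fused@levels, ncol, integer(1)),
               c(64L + 16L, 128L + 24L, 256L + 32L, 512L + 96L))
  expect_equal(ncol(fused@levels[[4]]), 608L)
  # fusing a pyramid with itself doubles every level's channels
  selfed <- alignAndFuse(res, res)
  expect_equal(vapply(selfed@levels, ncol, integer(1)),
               2L * vapply(res@levels, ncol, integer(1)))
})

test_that("SE attention gates channels as sigmoid(W2 relu(W1 GAP(x)))", {
  withr::local_seed(32)
  x <- array(runif(8 * 8 * 6), c(8, 8, 6))
  # forced identity gate: huge positive bias
  w_id <- list(w1 = matrix(0, 6, 3), b1 = rep(0, 3),
               w2 = matrix(0, 3, 6), b2 = rep(50, 6))
  expect_equal(seAttention(x, weights = w_id), x, ignore_attr = TRUE,
               tolerance = 1e-12)
  # forced null gate
  w_null <- list(w1 = matrix(0, 6, 3), b1 = rep(0, 3),
                 w2 = matrix(0, 3, 6), b2 = rep(-50, 6))
  expect_true(all(abs(seAttention(x, weights = w_null)) < 1e-12))

  # random weights: output equals gate * x with the gate recomputed by an
  # independent two-layer perceptron on channel means
  w <- list(w1 = matrix(rnorm(6 * 3), 6, 3), b1 = rnorm(3),
            w2 = matrix(rnorm(3 * 6), 3, 6), b2 = rnorm(6))
  out <- seAttention(x, weights = w)
  gate <- attr(out, "gate")
  means <- apply(x, 3, mean)
  hidden <- pmax(as.numeric(means %*% w$w1) + w$b1, 0)
  gate_ref <- plogis(as.numeric(hidden %*% w$w2) + w$b2)
  expect_equal(gate, gate_ref, tolerance = 1e-12)
  for (c in 1:6)
    expect_equal(out[, , c], x[, , c] * gate_ref[c], tolerance = 1e-12)
  expect_true(all(gate > 0 & gate < 1))
  # gate in (0,1) means attenuation only
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("lightweight ASPP concatenates 4 branches at unchanged size", {
  withr::local_seed(33)
  x <- array(runif(16 * 16 * 10), c(16, 16, 10))
  out <- lightweightASPP(x, branchChannels = 8L, seed = 2)
  expect_equal(dim(out), c(16L, 16L, 32L))
  out2 <- lightweightASPP(array(runif(16 * 16 * 608 / 8), c(16, 16, 76)),
                          branchChannels = 256L, seed = 2)
  expect_equal(dim(out2)[3], 1024L)

  # constant input: the pooling branch is spatially constant
  xc <- array(1, c(8, 8, 4))
  oc <- lightweightASPP(xc, branchChannels = 4L, seed = 3)
  pool_branch <- oc[, , 13:16]
  for (c in 1:4)
    expect_lt(diff(range(pool_branch[, , c])), 1e-12)
})

test_that("decoder stage upsamples x2 and meets the shape contract", {
  withr::local_seed(34)
  deep <- array(runif(8 * 8 * 12), c(8, 8, 12))
  skip <- array(runif(16 * 16 * 6), c(16, 16, 6))
  out <- decoderStage(deep, skip, outChannels = 5L, seReduction = 2L)
  expect_equal(dim(out), c(16L, 16L, 5L))
  noskip <- decoderStage(deep, NULL, outChannels = 4L)
  expect_equal(dim(noskip), c(16L, 16L, 4L))
  expect_error(decoderStage(deep, array(0, c(24, 24, 6)), 5L), "twice")
})

test_that("assembled model honors the tensor contract at reduced width", {
  withr::local_seed(35)
  cfg <- tiny_model_config(32L)
  m <- suppressMessages(assembleModel(cfg, seed = 1))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fp <- forwardPass(m, img, collect = TRUE)
  expect_equal(dim(fp$probs), c(32L, 32L))
  expect_true(all(fp$probs >= 0 & fp$probs <= 1))
  ints <- fp$intermediates
  expect_equal(vapply(ints$resnet_taps, ncol, integer(1)),
               cfg@resnetTapChannels)
  expect_equal(ncol(ints$fused[[4]]),
               cfg@resnetTapChannels[4] + cfg@mobilenetTapChannels[4])
  expect_equal(ncol(ints$aspp), 4L * cfg@asppBranchChannels)
  expect_equal(vapply(ints$decoder, ncol, integer(1)), cfg@decoderChannels)
  dd <- lapply(ints$decoder, cervseg:::tdim)
  expect_equal(vapply(dd, function(d) d[2], numeric(1)), c(4, 8, 16, 32))

  # same seed -> identical initial parameters; different seed -> different
  m2 <- suppressMessages(assembleModel(cfg, seed = 1))
  expect_identical(lapply(m@engine$params, function(p) p$value),
                   lapply(m2@engine$params, function(p) p$value))
  m3 <- suppressMessages(assembleModel(cfg, seed = 2))
  expect_false(identical(m@engine$params[[1]]$value,
                         m3@engine$params[[1]]$value))
})

test_that("ablation variant drops the lightweight branch", {
  withr::local_seed(36)
  full <- suppressMessages(assembleModel(tiny_model_config(32L), seed = 1))
  abl <- suppressMessages(assembleAblation(tiny_model_config(32L), seed = 1))
  expect_lt(paramCount(abl), paramCount(full))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  fp <- forwardPass(abl, img, collect = TRUE)
  expect_equal(dim(fp$probs), c(32L, 32L))
  expect_null(fp$intermediates$mobilenet_taps)
  # bottleneck entering ASPP is the deepest residual tap alone
  expect_equal(ncol(fp$intermediates$fused[[4]]),
               tiny_model_config()@resnetTapChannels[4])
  expect_false(any(grepl("^mobilenet", names(abl@engine$params))))
})

test_that("forward pass stays finite over many random inputs", {
  m <- suppressMessages(assembleModel(tiny_model_config(32L), seed = 3))
  for (sd in 1:20) {
    set.seed(sd)
    fp <- forwardPass(m, array(runif(32 * 32 * 3), c(32, 32, 3)))
    expect_true(all(is.finite(fp$probs)), label = sprintf("seed %d", sd))
  }
})

test_that("engine gradients match finite differences end to end", {
  withr::local_seed(37)
  m <- suppressMessages(assembleModel(tiny_model_config(32L), seed = 5))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(rbinom(32 * 32, 1, 0.2), ncol = 1)
  x <- featureMatrix(img)
  lcfg <- lossConfig()
  loss_of <- function() {
    cervseg:::model_loss_node(m, x, y, lcfg, training = FALSE)$loss$value
  }
  ln <- cervseg:::model_loss_node(m, x, y, lcfg, training = FALSE)
  cervseg:::ad_zero_grads(m@engine$params)
  cervseg:::ad_backward(ln$loss)
  nms <- sample(names(m@engine$params), 8)
  for (nm in nms) {
    p <- m@engine$params[[nm]]
    i <- sample(length(p$value), 1)
    eps <- 1e-5
    v0 <- p$value[i]
    p$value[i] <- v0 + eps
    lp <- loss_of()
    p$value[i] <- v0 - eps
    lm <- loss_of()
    p$value[i] <- v0
    num <- (lp - lm) / (2 * eps)
    ana <- if (is.null(p$grad)) 0 else p$grad[i]
    expect_lt(abs(num - ana), 1e-4)
  }
})
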