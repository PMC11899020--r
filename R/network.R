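# Dual-encoder segmentation network.
#
# Topology: two encoder branches produce 4-level feature pyramids at strides
# 2/4/8/16, each tap projected by a 1x1 convolution to its contracted width
# (residual branch 64/128/256/512, lightweight branch 16/24/32/96 at default
# widths). Per level the branches are fused by bilinear alignment +
# channel concatenation (deepest fusion: 512 + 96 = 608 channels at 16x16
# for 256x256 input). The fused bottleneck passes through a lightweight
# ASPP (depthwise-separable dilated branches at rates 1/6/12 plus a global
# pooling branch, 4 x 256 = 1024 channels), then four decoder stages each
# upsample x2 by transposed convolution, concatenate the SE-gated fused skip
# of the matching scale, and convolve down to 512/256/128/64 channels; a
# final 1x1 convolution + sigmoid yields the 1-channel probability map.
#
# The encoder interiors are reduced-depth but faithful in style: the
# residual branch uses identity-mapping blocks y = F(x) + x, the
# lightweight branch inverted-residual blocks built from pointwise
# expansions and depthwise convolutions.

reg_param <- function(net, name, value) {
  p <- ad_param(value, name)
  net$params[[name]] <- p
  p
}

mk_conv <- function(net, name, cin, cout, k = 3L, stride = 1L, dil = 1L,
                    bias = TRUE) {
  force(k); force(stride); force(dil)
  w <- reg_param(net, paste0(name, ".w"),
                 he_weights(cin * k * k, cin * k * k, cout))
  b <- if (bias) reg_param(net, paste0(name, ".b"), rep(0, cout)) else NULL
  function(x) ad_conv(x, w, b, k = k, stride = stride, dil = dil)
}

mk_dw <- function(net, name, C, dil = 1L, stride = 1L, k = 3L) {
  force(dil); force(stride)
  w <- reg_param(net, paste0(name, ".w"), he_weights(k * k, k * k, C))
  function(x) ad_dwconv(x, w, dil = dil, stride = stride)
}

mk_bn <- function(net, name, C) {
  gamma <- reg_param(net, paste0(name, ".gamma"), rep(1, C))
  beta <- reg_param(net, paste0(name, ".beta"), rep(0, C))
  state <- new.env(parent = emptyenv())
  state$rm <- rep(0, C)
  state$rv <- rep(1, C)
  net$bn[[name]] <- state
  function(x, training) ad_batchnorm(x, gamma, beta, state, training)
}

mk_dense <- function(net, name, cin, cout) {
  w <- reg_param(net, paste0(name, ".w"), he_weights(cin, cin, cout))
  b <- reg_param(net, paste0(name, ".b"), rep(0, cout))
  function(x) ad_dense(x, w, b)
}

mk_bnrelu <- function(net, name, C) {
  gamma <- reg_param(net, paste0(name, ".gamma"), rep(1, C))
  beta <- reg_param(net, paste0(name, ".beta"), rep(0, C))
  state <- new.env(parent = emptyenv())
  state$rm <- rep(0, C)
  state$rv <- rep(1, C)
  net$bn[[name]] <- state
  function(x, training) ad_bn_relu(x, gamma, beta, state, training)
}

mk_cbr <- function(net, name, cin, cout, k = 3L, stride = 1L, dil = 1L) {
  conv <- mk_conv(net, paste0(name, ".conv"), cin, cout, k, stride, dil,
                  bias = FALSE)
  bnr <- mk_bnrelu(net, paste0(name, ".bn"), cout)
  function(x, training) bnr(conv(x), training)
}

# identity-mapping residual block: y = ReLU(BN(conv(ReLU(BN(conv(x))))) + x)
mk_resblock <- function(net, name, C) {
  c1 <- mk_cbr(net, paste0(name, ".c1"), C, C)
  c2 <- mk_conv(net, paste0(name, ".c2"), C, C, bias = FALSE)
  b2 <- mk_bn(net, paste0(name, ".b2"), C)
  function(x, training) ad_relu(ad_add(b2(c2(c1(x, training)), training), x))
}

# inverted residual block: pointwise expand -> depthwise -> linear pointwise
mk_invres <- function(net, name, cin, cout, stride = 1L, expand = 4L) {
  force(stride)
  ce <- cin * expand
  pw1 <- mk_conv(net, paste0(name, ".expand"), cin, ce, k = 1L,
                 bias = FALSE)
  bn1 <- mk_bnrelu(net, paste0(name, ".bn1"), ce)
  dw <- mk_dw(net, paste0(name, ".dw"), ce, stride = stride)
  bn2 <- mk_bnrelu(net, paste0(name, ".bn2"), ce)
  pw2 <- mk_conv(net, paste0(name, ".project"), ce, cout, k = 1L,
                 bias = FALSE)
  bn3 <- mk_bn(net, paste0(name, ".bn3"), cout)
  function(x, training) {
    e <- bn1(pw1(x), training)
    d <- bn2(dw(e), training)
    out <- bn3(pw2(d), training)
    if (stride == 1L && ncol(x$value) == ncol(out$value))
      out <- ad_add(out, x)
    list(out = out, expanded = d)
  }
}

mk_se <- function(net, name, C, reduction) {
  cb <- max(1L, ceiling(C / reduction))
  d1 <- mk_dense(net, paste0(name, ".fc1"), C, cb)
  d2 <- mk_dense(net, paste0(name, ".fc2"), cb, C)
  function(x) {
    g <- ad_sigmoid(d2(ad_relu(d1(ad_gap(x)))))
    ad_scale_channels(x, g)
  }
}

mk_backbone_resnet <- function(net, prefix, tapCh) {
  stem <- mk_cbr(net, paste0(prefix, ".stem"), 3L, tapCh[1], stride = 2L)
  blocks <- list()
  downs <- list()
  projs <- list()
  for (k in 1:4) {
    if (k > 1)
      downs[[k]] <- mk_cbr(net, sprintf("%s.down%d", prefix, k),
                           tapCh[k - 1], tapCh[k], stride = 2L)
    blocks[[k]] <- mk_resblock(net, sprintf("%s.block%d", prefix, k),
                               tapCh[k])
    projs[[k]] <- mk_cbr(net, sprintf("%s.proj%d", prefix, k),
                         tapCh[k], tapCh[k], k = 1L)
  }
  function(x, training) {
    taps <- vector("list", 4L)
    h <- stem(x, training)
    for (k in 1:4) {
      if (k > 1) h <- downs[[k]](h, training)
      h <- blocks[[k]](h, training)
      taps[[k]] <- projs[[k]](h, training)
    }
    taps
  }
}

mk_backbone_mobilenet <- function(net, prefix, tapCh, expand = 4L) {
  stem <- mk_cbr(net, paste0(prefix, ".stem"), 3L, tapCh[1], stride = 2L)
  blocks <- list()
  projs <- list()
  for (k in 1:4) {
    cin <- if (k == 1) tapCh[1] else tapCh[k - 1]
    blocks[[k]] <- mk_invres(net, sprintf("%s.block%d", prefix, k),
                             cin, tapCh[k],
                             stride = if (k == 1) 1L else 2L,
                             expand = expand)
    projs[[k]] <- mk_cbr(net, sprintf("%s.proj%d", prefix, k),
                         cin * expand, tapCh[k], k = 1L)
  }
  function(x, training) {
    taps <- vector("list", 4L)
    h <- stem(x, training)
    for (k in 1:4) {
      r <- blocks[[k]](h, training)
      taps[[k]] <- projs[[k]](r$expanded, training)
      h <- r$out
    }
    taps
  }
}

mk_aspp <- function(net, prefix, cin, branch, rates) {
  convs <- lapply(seq_along(rates), function(i) {
    dw <- mk_dw(net, sprintf("%s.dw%d", prefix, i), cin, dil = rates[i])
    pw <- mk_conv(net, sprintf("%s.pw%d", prefix, i), cin, branch, k = 1L,
                  bias = FALSE)
    bn <- mk_bnrelu(net, sprintf("%s.bn%d", prefix, i), branch)
    list(dw = dw, pw = pw, bn = bn)
  })
  pool_fc <- mk_dense(net, paste0(prefix, ".pool"), cin, branch)
  function(x, training) {
    d <- tdim(x$value)
    outs <- lapply(convs, function(br)
      br$bn(br$pw(br$dw(x)), training))
    pooled <- ad_relu(pool_fc(ad_gap(x)))
    outs[[length(outs) + 1L]] <- ad_broadcast(pooled, d[2], d[3])
    ad_concat(outs)
  }
}

mk_decoder_stage <- function(net, prefix, cin_deep, cin_skip, cout,
                             reduction) {
  wt <- reg_param(net, paste0(prefix, ".up.w"),
                  he_weights(cin_deep, cin_deep, 4L * cout))
  bt <- reg_param(net, paste0(prefix, ".up.b"), rep(0, cout))
  se <- if (cin_skip > 0)
    mk_se(net, paste0(prefix, ".se"), cin_skip, reduction) else NULL
  c1 <- mk_cbr(net, paste0(prefix, ".c1"), cout + cin_skip, cout)
  c2 <- mk_cbr(net, paste0(prefix, ".c2"), cout, cout)
  function(deep, skip, training) {
    up <- ad_tconv2(deep, wt, bt)
    h <- if (!is.null(skip)) {
      du <- tdim(up$value); ds <- tdim(skip$value)
      if (du[2] != ds[2] || du[3] != ds[3])
        stop("decoder stage: skip spatial size must be twice the deep map's")
      ad_concat(list(up, se(skip)))
    } else up
    c2(c1(h, training), training)
  }
}

#' Assemble the dual-encoder segmentation network
#'
#' Builds the full network for the given configuration with randomly
#' initialized weights (He initialization, deterministic given
#' \code{seed}). With \code{config@ablationMode} the lightweight branch and
#' its fusion are dropped; skips become SE-gated residual-branch taps and
#' the bottleneck entering ASPP has the deepest residual tap width.
#' The parameter total is reported with \code{message()}.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed RNG seed for weight initialization.
#' @return a \linkS4class{SegModel}.
#' @export
#' @examples
#' m <- assembleModel(deskModelConfig(inputSize = 32L), seed = 1)
#' paramCount(m)
assembleModel <- function(config, seed = 1L) {
  stopifnot(is(config, "ModelConfig"))
  with_seed(seed, assemble_impl(config))
}

#' Assemble the single-encoder ablation variant
#'
#' Convenience wrapper forcing \code{ablationMode = TRUE}: identical
#' topology minus the lightweight branch and fusion.
#'
#' @inheritParams assembleModel
#' @return a \linkS4class{SegModel}.
#' @export
assembleAblation <- function(config, seed = 1L) {
  cfg <- modelConfig(inputSize = config@inputSize,
                     resnetTapChannels = config@resnetTapChannels,
                     mobilenetTapChannels = config@mobilenetTapChannels,
                     asppBranchChannels = config@asppBranchChannels,
                     asppRates = config@asppRates,
                     seReduction = config@seReduction,
                     decoderChannels = config@decoderChannels,
                     ablationMode = TRUE)
  assembleModel(cfg, seed = seed)
}

assemble_impl <- function(config) {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$bn <- list()
  rtc <- config@resnetTapChannels
  mtc <- config@mobilenetTapChannels
  abl <- config@ablationMode
  res_bb <- mk_backbone_resnet(net, "resnet", rtc)
  mob_bb <- if (!abl) mk_backbone_mobilenet(net, "mobilenet", mtc)
  fusedCh <- if (abl) rtc else rtc + mtc
  aspp <- mk_aspp(net, "aspp", fusedCh[4], config@asppBranchChannels,
                  config@asppRates)
  dec <- config@decoderChannels
  deepIn <- 4L * config@asppBranchChannels
  stages <- list(
    mk_decoder_stage(net, "decoder1", deepIn, fusedCh[3], dec[1],
                     config@seReduction),
    mk_decoder_stage(net, "decoder2", dec[1], fusedCh[2], dec[2],
                     config@seReduction),
    mk_decoder_stage(net, "decoder3", dec[2], fusedCh[1], dec[3],
                     config@seReduction),
    mk_decoder_stage(net, "decoder4", dec[3], 0L, dec[4],
                     config@seReduction))
  head <- mk_conv(net, "head", dec[4], 1L, k = 1L)

  net$forward <- function(xmat, training = FALSE, collect = FALSE) {
    d <- tdim(xmat)
    if (d[2] %% 16L != 0L || d[3] %% 16L != 0L)
      stop("input spatial size must be divisible by 16")
    # branch-specific input standardization (constants on the 0-255 scale)
    cst_r <- .STANDARDIZE[["resnet-branch"]]
    xr <- ad_const(tmeta(
      sweep(sweep(xmat * 255, 2, cst_r$mean), 2, cst_r$sd, "/"),
      d[1], d[2], d[3]))
    taps_r <- res_bb(xr, training)
    if (!abl) {
      cst_m <- .STANDARDIZE[["mobilenet-branch"]]
      xm <- ad_const(tmeta(
        sweep(sweep(xmat * 255, 2, cst_m$mean), 2, cst_m$sd, "/"),
        d[1], d[2], d[3]))
      taps_m <- mob_bb(xm, training)
      fused <- lapply(1:4, function(k) {
        dk <- tdim(taps_r[[k]]$value)
        ad_concat(list(taps_r[[k]],
                       ad_resize_bilinear(taps_m[[k]], dk[2], dk[3])))
      })
    } else {
      taps_m <- NULL
      fused <- taps_r
    }
    bott <- aspp(fused[[4]], training)
    d1 <- stages[[1]](bott, fused[[3]], training)
    d2 <- stages[[2]](d1, fused[[2]], training)
    d3 <- stages[[3]](d2, fused[[1]], training)
    d4 <- stages[[4]](d3, NULL, training)
    out <- ad_sigmoid(head(d4))
    res <- list(out = out)
    if (collect) {
      res$resnet_taps <- taps_r
      res$mobilenet_taps <- taps_m
      res$fused <- fused
      res$aspp <- bott
      res$decoder <- list(d1, d2, d3, d4)
    }
    res
  }
  model <- new("SegModel", config = config, engine = net)
  message(sprintf("assembled %s model: %s parameters",
                  if (abl) "single-encoder" else "dual-encoder",
                  format(paramCount(model), big.mark = ",")))
  model
}

#' Total number of trainable parameters
#' @param model a \linkS4class{SegModel}.
#' @return integer parameter count.
#' @export
paramCount <- function(model) {
  stopifnot(is(model, "SegModel"))
  sum(vapply(model@engine$params, function(p) length(p$value), numeric(1)))
}

#' Run a forward pass
#'
#' @param model a \linkS4class{SegModel}.
#' @param image H x W x 3 array in [0, 1] (or a \linkS4class{SamplePair}).
#' @param collect also return all intermediate feature maps (engine-layout
#'   matrices) under \code{intermediates}.
#' @return list with \code{probs} (H x W probability matrix) and optionally
#'   \code{intermediates}.
#' @export
forwardPass <- function(model, image, collect = FALSE) {
  if (is(image, "SamplePair")) image <- image@image
  x <- ad_const(featureMatrix(image))
  res <- model@engine$forward(x$value, training = FALSE, collect = collect)
  out <- list(probs = featureArray(res$out$value))
  if (collect) {
    grab <- function(node) node$value
    out$intermediates <- list(
      resnet_taps = lapply(res$resnet_taps, grab),
      mobilenet_taps = if (!is.null(res$mobilenet_taps))
        lapply(res$mobilenet_taps, grab),
      fused = lapply(res$fused, grab),
      aspp = grab(res$aspp),
      decoder = lapply(res$decoder, grab),
      out = grab(res$out))
  }
  out
}

#' Predict a binary mask
#'
#' @param model a \linkS4class{SegModel}.
#' @param image H x W x 3 array in [0, 1] (or \linkS4class{SamplePair}).
#' @param threshold probability cutoff; pixels with probability strictly
#'   above it become foreground.
#' @return H x W integer mask.
#' @export
predictMask <- function(model, image, threshold = 0.5) {
  p <- forwardPass(model, image)$probs
  m <- (p > threshold) * 1L
  storage.mode(m) <- "integer"
  m
}

# ---- functional module surface (shape-contract level API) ------------------

#' Build a standalone encoder branch
#'
#' @param family \code{"resnet50-style"} (residual blocks) or
#'   \code{"mobilenetv2-style"} (inverted residual blocks).
#' @param tapChannels projected widths of the 4 taps.
#' @param seed RNG seed for initialization.
#' @return an opaque backbone object for \code{\link{extractTaps}}.
#' @export
makeBackbone <- function(family = c("resnet50-style", "mobilenetv2-style"),
                         tapChannels = NULL, seed = 1L) {
  family <- match.arg(family)
  if (is.null(tapChannels)) {
    tapChannels <- if (family == "resnet50-style") c(64L, 128L, 256L, 512L)
    else c(16L, 24L, 32L, 96L)
  }
  tapChannels <- as.integer(tapChannels)
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$bn <- list()
  with_seed(seed, {
    net$run <- if (family == "resnet50-style")
      mk_backbone_resnet(net, "bb", tapChannels)
    else mk_backbone_mobilenet(net, "bb", tapChannels)
  })
  structure(list(net = net, family = family, tapChannels = tapChannels),
            class = "cervsegBackbone")
}

#' Extract the 4-level feature pyramid of a backbone
#'
#' Runs the headless encoder on a batch of images and returns the four
#' projected taps at strides 2, 4, 8, 16.
#'
#' @param backbone object from \code{\link{makeBackbone}}.
#' @param images one H x W x 3 array or a list of them (equal sizes).
#' @return a \linkS4class{FeaturePyramid}.
#' @export
extractTaps <- function(backbone, images) {
  stopifnot(inherits(backbone, "cervsegBackbone"))
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input spatial size must be divisible by 16")
  x <- ad_const(stack_batch(lapply(images, featureMatrix)))
  taps <- backbone$net$run(x, training = FALSE)
  new("FeaturePyramid", levels = lapply(taps, function(t) t$value),
      strides = c(2L, 4L, 8L, 16L))
}

#' Align and fuse two feature pyramids
#'
#' Per level, resizes pyramid \code{b} (bilinear) to pyramid \code{a}'s
#' spatial size and concatenates channels, so the fused width is the sum of
#' the two widths (608 at the deepest level under default widths).
#'
#' @param a,b \linkS4class{FeaturePyramid}s from the same input batch.
#' @return fused \linkS4class{FeaturePyramid}.
#' @export
alignAndFuse <- function(a, b) {
  stopifnot(is(a, "FeaturePyramid"), is(b, "FeaturePyramid"))
  if (length(a@levels) != length(b@levels))
    stop("pyramids have different level counts")
  levels <- lapply(seq_along(a@levels), function(k) {
    la <- a@levels[[k]]; lb <- b@levels[[k]]
    da <- tdim(la); db <- tdim(lb)
    if (da[1] != db[1]) stop("pyramids have different batch sizes")
    if (db[2] != da[2] || db[3] != da[3])
      lb <- tmeta(cpp_resize_bilinear_fw(lb, db[1], db[2], db[3],
                                         da[2], da[3]), da[1], da[2], da[3])
    tmeta(cbind(la, lb), da[1], da[2], da[3])
  })
  new("FeaturePyramid", levels = levels, strides = a@strides)
}

#' Squeeze-and-excitation channel attention
#'
#' Recalibrates channels by a gate computed from globally pooled channel
#' statistics: \code{sigmoid(W2 ReLU(W1 GAP(X)))} applied channel-wise.
#' With no weights supplied a randomly initialized gate is used
#' (deterministic given \code{seed}).
#'
#' @param x H x W x C array.
#' @param reduction bottleneck reduction ratio.
#' @param weights optional list with \code{w1} (C x Cb), \code{b1},
#'   \code{w2} (Cb x C), \code{b2} to pin the gate.
#' @param seed RNG seed for random weights.
#' @return H x W x C array; the gate (length-C vector) is attached as
#'   attribute \code{"gate"}.
#' @export
seAttention <- function(x, reduction = 16L, weights = NULL, seed = 1L) {
  m <- featureMatrix(x)
  C <- ncol(m)
  cb <- max(1L, ceiling(C / reduction))
  if (is.null(weights)) {
    weights <- with_seed(seed, list(
      w1 = he_weights(C, C, cb), b1 = rep(0, cb),
      w2 = he_weights(cb, cb, C), b2 = rep(0, C)))
  }
  pooled <- colMeans(m)
  hidden <- pmax(drop(pooled %*% weights$w1) + weights$b1, 0)
  gate <- 1 / (1 + exp(-(drop(hidden %*% weights$w2) + weights$b2)))
  out <- m * row_rep(gate, nrow(m))
  res <- featureArray(tmeta(out, 1L, dim(x)[1], dim(x)[2]), drop = FALSE)
  attr(res, "gate") <- gate
  res
}

#' Lightweight atrous spatial pyramid pooling
#'
#' Four parallel branches over the input map: depthwise-separable 3x3
#' convolutions at the given dilation rates (each to
#' \code{branchChannels}) and a global-average-pool branch broadcast back
#' over the spatial grid, concatenated to \code{4 * branchChannels}
#' channels at unchanged spatial size. Random weights, deterministic given
#' \code{seed}.
#'
#' @param x H x W x C array.
#' @param branchChannels channels per branch.
#' @param rates dilation rates of the three convolutional branches.
#' @param seed RNG seed.
#' @return H x W x (4*branchChannels) array.
#' @export
lightweightASPP <- function(x, branchChannels = 256L, rates = c(1L, 6L, 12L),
                            seed = 1L) {
  net <- new.env(parent = emptyenv())
  net$params <- list(); net$bn <- list()
  d <- dim(x)
  mod <- with_seed(seed, mk_aspp(net, "aspp", d[3], as.integer(branchChannels),
                                 as.integer(rates)))
  out <- mod(ad_const(featureMatrix(x)), training = FALSE)
  featureArray(out$value, drop = FALSE)
}

#' One decoder stage
#'
#' Upsamples the deep map x2 by transposed convolution, concatenates the
#' SE-gated skip (which must be at exactly twice the deep map's spatial
#' size), and convolves to \code{outChannels}. Random weights,
#' deterministic given \code{seed}.
#'
#' @param deep H x W x C array (deep features).
#' @param skip 2H x 2W x Cs array or \code{NULL} for a skipless stage.
#' @param outChannels output width.
#' @param seReduction SE reduction ratio for the skip gate.
#' @param seed RNG seed.
#' @return 2H x 2W x outChannels array.
#' @export
decoderStage <- function(deep, skip, outChannels, seReduction = 16L,
                         seed = 1L) {
  dd <- dim(deep)
  cs <- if (is.null(skip)) 0L else dim(skip)[3]
  if (!is.null(skip) && !all(dim(skip)[1:2] == 2L * dd[1:2]))
    stop("decoder stage: skip spatial size must be twice the deep map's")
  net <- new.env(parent = emptyenv())
  net$params <- list(); net$bn <- list()
  mod <- with_seed(seed,
    mk_decoder_stage(net, "stage", dd[3], cs, as.integer(outChannels),
                     as.integer(seReduction)))
  out <- mod(ad_const(featureMatrix(deep)),
             if (is.null(skip)) NULL else ad_const(featureMatrix(skip)),
             training = FALSE)
  featureArray(out$value, drop = FALSE)
}

#' CPU-scale network configuration
#'
#' Same topology as the default contract at reduced widths, sized for
#' desk-scale experiments and continuous testing on a single CPU: taps
#' 8/16/32/64 and 4/6/8/12, ASPP branches of 16, decoder 32/24/16/12.
#'
#' @param inputSize input side in pixels (default 64).
#' @param ablationMode single-encoder variant.
#' @return a \linkS4class{ModelConfig}.
#' @export
deskModelConfig <- function(inputSize = 64L, ablationMode = FALSE) {
  modelConfig(inputSize = inputSize,
              resnetTapChannels = c(8L, 16L, 32L, 64L),
              mobilenetTapChannels = c(4L, 6L, 8L, 12L),
              asppBranchChannels = 16L,
              asppRates = c(1L, 6L, 12L),
              seReduction = 4L,
              decoderChannels = c(32L, 24L, 16L, 12L),
              ablationMode = ablationMode)
}
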