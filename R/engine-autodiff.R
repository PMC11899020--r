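# Reverse-mode automatic differentiation over batched feature maps.
#
# A batched activation of N samples, spatial size H x W and C channels is a
# numeric matrix of dimension (N*H*W) x C with row index n*H*W + i*W + j
# (0-based i = row, j = column); channels are columns so convolutions reduce
# to im2col + GEMM through BLAS. Graph nodes are environments; parameters are
# persistent leaf nodes whose gradients the optimizer consumes.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_next_id <- function() {
  .ad$counter <- .ad$counter + 1L
  .ad$counter
}

#' @keywords internal
tmeta <- function(m, n, h, w) {
  stopifnot(nrow(m) == n * h * w)
  attr(m, "tdim") <- c(n, h, w)
  m
}

tdim <- function(m) attr(m, "tdim")

new_node <- function(value, parents = list(), backfn = NULL,
                     is_param = FALSE, name = NULL) {
  e <- new.env(parent = emptyenv())
  e$id <- ad_next_id()
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$is_param <- is_param
  e$name <- name
  class(e) <- "ad_node"
  e
}

ad_const <- function(value) new_node(value)

ad_param <- function(value, name = NULL) {
  p <- new_node(value, is_param = TRUE, name = name)
  p$m <- 0 * value
  p$v <- 0 * value
  p
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Accumulate gradients from a scalar root into every reachable node.
ad_backward <- function(root, seed = 1) {
  order <- vector("list", 256L)
  norder <- 0L
  visited <- new.env(parent = emptyenv(), hash = TRUE)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  root$grad <- seed
  for (k in seq(norder, 1L)) {
    node <- order[[k]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    gs <- node$backfn(node$grad)
    for (i in seq_along(node$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- node$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

row_rep <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

# --- convolution ops ---------------------------------------------------------

# im2col cache heuristic: re-materialize patch matrices in the backward pass
# when they would be large, trading time for bounded memory.
.IM2COL_CACHE_MAX <- 3e7

ad_conv <- function(x, w, b = NULL, k = 3L, stride = 1L, pad = NULL,
                    dil = 1L) {
  d <- tdim(x$value)
  n <- d[1]; h <- d[2]; wd <- d[3]
  if (is.null(pad)) pad <- dil * (k - 1L) %/% 2L
  add_bias <- function(y) {
    if (is.null(b)) y else y + row_rep(b$value, nrow(y))
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  if (k == 1L && stride == 1L && dil == 1L) {
    y <- add_bias(x$value %*% w$value)
    node <- new_node(tmeta(y, n, h, wd), parents, name = "conv1x1")
    node$backfn <- function(dy) {
      out <- list(tmeta(dy %*% t(w$value), n, h, wd),
                  crossprod(x$value, dy))
      if (!is.null(b)) out[[3]] <- colSums(dy)
      out
    }
    return(node)
  }
  ho <- (h + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
  wo <- (wd + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
  y <- add_bias(cpp_conv_fw(x$value, n, h, wd, w$value, k, stride, pad, dil))
  node <- new_node(tmeta(y, n, ho, wo), parents, name = "conv")
  node$backfn <- function(dy) {
    r <- cpp_conv_bw(dy, x$value, n, h, wd, w$value, k, stride, pad, dil)
    out <- list(tmeta(r$dx, n, h, wd), r$dw)
    if (!is.null(b)) out[[3]] <- colSums(dy)
    out
  }
  node
}

ad_dwconv <- function(x, w, dil = 1L, stride = 1L) {
  d <- tdim(x$value)
  ho <- (d[2] - 1L) %/% stride + 1L
  wo <- (d[3] - 1L) %/% stride + 1L
  y <- cpp_dwconv_fw(x$value, d[1], d[2], d[3], w$value, dil, stride)
  node <- new_node(tmeta(y, d[1], ho, wo), list(x, w), name = "dwconv")
  node$backfn <- function(dy) {
    r <- cpp_dwconv_bw(dy, x$value, d[1], d[2], d[3], w$value, dil, stride)
    list(tmeta(r$dx, d[1], d[2], d[3]), r$dw)
  }
  node
}

# transposed convolution, kernel 2, stride 2 (exact x2 upsampling)
ad_tconv2 <- function(x, w, b) {
  d <- tdim(x$value)
  cout <- length(b$value)
  m <- x$value %*% w$value
  y <- cpp_tconv2_scatter(m, d[1], d[2], d[3], cout)
  y <- y + row_rep(b$value, nrow(y))
  node <- new_node(tmeta(y, d[1], 2L * d[2], 2L * d[3]), list(x, w, b),
                   name = "tconv2")
  node$backfn <- function(dy) {
    dm <- cpp_tconv2_gather(dy, d[1], d[2], d[3], cout)
    list(tmeta(dm %*% t(w$value), d[1], d[2], d[3]),
         crossprod(x$value, dm),
         colSums(dy))
  }
  node
}

# --- batch normalization -----------------------------------------------------

ad_batchnorm <- function(x, gamma, beta, state, training,
                         momentum = 0.1, eps = 1e-5) {
  d <- tdim(x$value)
  r <- nrow(x$value)
  if (training) {
    mu <- colMeans(x$value)
    v <- colMeans(x$value^2) - mu^2
    v[v < 0] <- 0
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v * r / max(r - 1, 1)
    invstd <- 1 / sqrt(v + eps)
    xhat <- cpp_colscale_shift(x$value, invstd, -mu * invstd)
    y <- cpp_colscale_shift(xhat, gamma$value, beta$value)
    node <- new_node(tmeta(y, d[1], d[2], d[3]), list(x, gamma, beta),
                     name = "bn")
    node$backfn <- function(dy) {
      dxhat <- cpp_colscale_shift(dy, gamma$value, numeric(ncol(dy)))
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dx <- cpp_axpby_cols(dxhat, invstd, xhat, -s2 * invstd / r,
                           -s1 * invstd / r)
      list(tmeta(dx, d[1], d[2], d[3]), colSums(dy * xhat), colSums(dy))
    }
  } else {
    invstd <- 1 / sqrt(state$rv + eps)
    scale <- gamma$value * invstd
    y <- cpp_colscale_shift(x$value, scale, beta$value - state$rm * scale)
    node <- new_node(tmeta(y, d[1], d[2], d[3]), list(x, gamma, beta),
                     name = "bn")
    node$backfn <- function(dy) {
      xhat <- cpp_colscale_shift(x$value, invstd, -state$rm * invstd)
      list(tmeta(cpp_colscale_shift(dy, scale, numeric(ncol(dy))),
                 d[1], d[2], d[3]),
           colSums(dy * xhat), colSums(dy))
    }
  }
  node
}

# fused batch norm + ReLU (the dominant elementwise pattern of the network):
# one pass computes relu(gamma * (x - mu)/sd + beta); the backward pass
# reconstructs the parameter gradients from per-channel sums returned by the
# fused kernel, so no mask or xhat matrix is materialized in the forward.
ad_bn_relu <- function(x, gamma, beta, state, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- tdim(x$value)
  rn <- nrow(x$value)
  if (training) {
    st <- cpp_colstats(x$value)
    mu <- st$mean
    v <- st$var
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v * rn / max(rn - 1, 1)
    invstd <- 1 / sqrt(v + eps)
  } else {
    mu <- state$rm
    invstd <- 1 / sqrt(state$rv + eps)
  }
  scale <- gamma$value * invstd
  shift <- beta$value - mu * scale
  y <- cpp_affine_relu_fw(x$value, scale, shift)
  node <- new_node(tmeta(y, d[1], d[2], d[3]), list(x, gamma, beta),
                   name = "bn_relu")
  node$backfn <- function(dy) {
    r <- cpp_affine_relu_bw(dy, y, scale)
    # recover sum(dy_masked * x) per channel from sum(dy_masked * out)
    sum_dx_raw <- ifelse(abs(scale) > 1e-12,
                         (r$sum_dy_y - shift * r$sum_dy) / scale, 0)
    dgamma <- sum_dx_raw * invstd - r$sum_dy * mu * invstd
    dbeta <- r$sum_dy
    if (training) {
      s1 <- gamma$value * r$sum_dy
      s2 <- gamma$value * dgamma
      xhat <- cpp_colscale_shift(x$value, invstd, -mu * invstd)
      dx <- cpp_axpby_cols(r$dx, rep(1, length(scale)), xhat,
                           -invstd * s2 / rn, -invstd * s1 / rn)
    } else {
      dx <- r$dx
    }
    list(tmeta(dx, d[1], d[2], d[3]), dgamma, dbeta)
  }
  node
}

# --- pointwise and structural ops -------------------------------------------

ad_relu <- function(x) {
  d <- tdim(x$value)
  node <- new_node(tmeta(cpp_relu_fw(x$value), d[1], d[2], d[3]), list(x),
                   name = "relu")
  node$backfn <- function(dy) {
    list(tmeta(cpp_relu_bw(dy, x$value), d[1], d[2], d[3]))
  }
  node
}

ad_sigmoid <- function(x) {
  d <- tdim(x$value)
  y <- 1 / (1 + exp(-x$value))
  node <- new_node(tmeta(y, d[1], d[2], d[3]), list(x), name = "sigmoid")
  node$backfn <- function(dy) list(tmeta(dy * y * (1 - y), d[1], d[2], d[3]))
  node
}

ad_add <- function(a, b) {
  d <- tdim(a$value)
  node <- new_node(tmeta(a$value + b$value, d[1], d[2], d[3]), list(a, b),
                   name = "add")
  node$backfn <- function(dy) list(dy, dy)
  node
}

ad_concat <- function(xs) {
  d <- tdim(xs[[1]]$value)
  vals <- lapply(xs, function(x) x$value)
  y <- do.call(cbind, vals)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  node <- new_node(tmeta(y, d[1], d[2], d[3]), xs, name = "concat")
  node$backfn <- function(dy) {
    lapply(seq_along(xs), function(i) {
      tmeta(dy[, starts[i]:ends[i], drop = FALSE], d[1], d[2], d[3])
    })
  }
  node
}

# global average pooling: (N*H*W) x C -> N x C (stored with H = W = 1)
ad_gap <- function(x) {
  d <- tdim(x$value)
  hw <- d[2] * d[3]
  grp <- rep(seq_len(d[1]), each = hw)
  y <- rowsum(x$value, grp, reorder = TRUE) / hw
  node <- new_node(tmeta(y, d[1], 1L, 1L), list(x), name = "gap")
  node$backfn <- function(dy) {
    list(tmeta(dy[grp, , drop = FALSE] / hw, d[1], d[2], d[3]))
  }
  node
}

# broadcast an N x C map back over H x W
ad_broadcast <- function(g, h, w) {
  d <- tdim(g$value)
  idx <- rep(seq_len(d[1]), each = h * w)
  node <- new_node(tmeta(g$value[idx, , drop = FALSE], d[1], h, w), list(g),
                   name = "broadcast")
  node$backfn <- function(dy) {
    list(tmeta(rowsum(dy, idx, reorder = TRUE), d[1], 1L, 1L))
  }
  node
}

ad_dense <- function(x, w, b) {
  d <- tdim(x$value)
  y <- x$value %*% w$value + row_rep(b$value, nrow(x$value))
  node <- new_node(tmeta(y, d[1], d[2], d[3]), list(x, w, b), name = "dense")
  node$backfn <- function(dy) {
    list(tmeta(dy %*% t(w$value), d[1], d[2], d[3]),
         crossprod(x$value, dy), colSums(dy))
  }
  node
}

# channel-wise gate: x is (N*H*W) x C, g is N x C in (0,1)
ad_scale_channels <- function(x, g) {
  d <- tdim(x$value)
  idx <- rep(seq_len(d[1]), each = d[2] * d[3])
  gexp <- g$value[idx, , drop = FALSE]
  node <- new_node(tmeta(x$value * gexp, d[1], d[2], d[3]), list(x, g),
                   name = "scale")
  node$backfn <- function(dy) {
    list(tmeta(dy * gexp, d[1], d[2], d[3]),
         tmeta(rowsum(dy * x$value, idx, reorder = TRUE), d[1], 1L, 1L))
  }
  node
}

ad_resize_bilinear <- function(x, ho, wo) {
  d <- tdim(x$value)
  if (d[2] == ho && d[3] == wo) return(x)
  y <- cpp_resize_bilinear_fw(x$value, d[1], d[2], d[3], ho, wo)
  node <- new_node(tmeta(y, d[1], ho, wo), list(x), name = "resize")
  node$backfn <- function(dy) {
    list(tmeta(cpp_resize_bilinear_bw(dy, d[1], d[2], d[3], ho, wo),
               d[1], d[2], d[3]))
  }
  node
}

# weighted sum of all entries (weights constant w.r.t. the graph)
ad_weighted_sum <- function(x, weights) {
  node <- new_node(sum(x$value * weights), list(x), name = "wsum")
  d <- tdim(x$value)
  node$backfn <- function(dy) list(tmeta(dy * weights, d[1], d[2], d[3]))
  node
}

# --- losses as analytic scalar nodes ----------------------------------------

ad_dice_loss <- function(y, yhat, eps = 1e-6) {
  d <- tdim(yhat$value)
  s <- sum(y * yhat$value)
  p <- sum(y)
  q <- sum(yhat$value)
  denom <- p + q + eps
  node <- new_node(1 - (2 * s + eps) / denom, list(yhat), name = "dice_loss")
  node$backfn <- function(dy) {
    g <- -(2 * y * denom - (2 * s + eps)) / denom^2
    list(tmeta(dy * g, d[1], d[2], d[3]))
  }
  node
}

ad_tversky_loss <- function(y, yhat, alpha = 0.7, beta = 0.3, eps = 1e-6) {
  d <- tdim(yhat$value)
  s <- sum(y * yhat$value)
  fn <- sum(y * (1 - yhat$value))
  fp <- sum((1 - y) * yhat$value)
  num <- s + eps
  denom <- s + alpha * fn + beta * fp + eps
  node <- new_node(1 - num / denom, list(yhat), name = "tversky_loss")
  node$backfn <- function(dy) {
    ddenom <- y - alpha * y + beta * (1 - y)
    g <- -(y * denom - num * ddenom) / denom^2
    list(tmeta(dy * g, d[1], d[2], d[3]))
  }
  node
}

ad_scalar_add <- function(a, b) {
  node <- new_node(a$value + b$value, list(a, b), name = "scalar_add")
  node$backfn <- function(dy) list(dy, dy)
  node
}

# --- parameter initialization and Adam --------------------------------------

he_weights <- function(fan_in, nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}
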