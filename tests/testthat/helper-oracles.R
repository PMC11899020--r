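# Independent oracles and small fixture builders used across the suite.

# Point-in-polygon oracle: a pixel (i, j) (0-based) is foreground iff its
# center (x = j, y = i) is strictly inside the polygon by the even-odd rule
# or lies exactly on an edge; vertices rounded to integers first. This is a
# per-pixel ray-cast, independent of the scanline implementation.
pip_fill_oracle <- function(height, width, polys) {
  mask <- matrix(0L, height, width)
  shoelace <- function(p) {
    n <- nrow(p)
    j <- c(n, seq_len(n - 1))
    abs(sum(p[j, 1] * p[, 2] - p[, 1] * p[j, 2])) / 2
  }
  for (pts in polys) {
    pts <- round(pts)
    if (shoelace(pts) == 0) next  # zero-area shapes contribute nothing
    nv <- nrow(pts)
    nxt <- c(2:nv, 1)
    for (i in 0:(height - 1)) {
      for (j in 0:(width - 1)) {
        inside <- FALSE
        on_edge <- FALSE
        for (v in seq_len(nv)) {
          x1 <- pts[v, 1]; y1 <- pts[v, 2]
          x2 <- pts[nxt[v], 1]; y2 <- pts[nxt[v], 2]
          # exact on-segment test for integer endpoints and centers
          cross <- (x2 - x1) * (i - y1) - (y2 - y1) * (j - x1)
          if (cross == 0 && j >= min(x1, x2) && j <= max(x1, x2) &&
              i >= min(y1, y2) && i <= max(y1, y2)) {
            on_edge <- TRUE
            break
          }
          if ((y1 > i) != (y2 > i)) {
            xint <- x1 + (i - y1) * (x2 - x1) / (y2 - y1)
            if (j < xint) inside <- !inside
          }
        }
        if (inside || on_edge) mask[i + 1, j + 1] <- 1L
      }
    }
  }
  mask
}

random_polygon <- function(size, margin = 2, nv = sample(3:8, 1)) {
  # star-convex polygon around a random center, vertices in-bounds,
  # regenerated if rounding collapses it to zero area
  repeat {
    cx <- runif(1, margin + 3, size - margin - 4)
    cy <- runif(1, margin + 3, size - margin - 4)
    rmax <- min(cx - margin, cy - margin, size - 1 - margin - cx,
                size - 1 - margin - cy)
    th <- sort(runif(nv, 0, 2 * pi))
    r <- runif(nv, 0.3, 1) * max(rmax, 2)
    p <- cbind(cx + r * cos(th), cy + r * sin(th))
    if (cervseg:::shoelace_area(round(p)) > 0) return(p)
  }
}

random_mask <- function(h, w, p = 0.3) {
  m <- matrix(rbinom(h * w, 1, p), h, w)
  storage.mode(m) <- "integer"
  m
}

# brute-force confusion metrics from TP/FP/FN/TN scalars
oracle_metrics <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1); fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0); tn <- sum(y == 0 & yhat == 0)
  n <- tp + fp + fn + tn
  n0 <- tn + fp  # reference background
  n1 <- tp + fn  # reference foreground
  acc0 <- if (n0 > 0) tn / n0 else NA_real_
  acc1 <- if (n1 > 0) tp / n1 else NA_real_
  # classes with no reference pixels are excluded from the averages
  iou0 <- if (n0 > 0) tn / (tn + fp + fn) else NA_real_
  iou1 <- if (n1 > 0) tp / (tp + fn + fp) else NA_real_
  list(
    pa = (tp + tn) / n,
    mpa = mean(c(acc0, acc1), na.rm = TRUE),
    miou = mean(c(iou0, iou1), na.rm = TRUE),
    fwiou = sum(c(n0 / n * ifelse(is.na(iou0), 0, iou0),
                  n1 / n * ifelse(is.na(iou1), 0, iou1))),
    dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  )
}

# brute-force Hausdorff on boundary sets extracted independently (8-connected
# scan over all foreground pixels, checking 4-neighborhood membership)
oracle_hausdorff <- function(a, b) {
  bnd <- function(m) {
    idx <- which(m == 1L, arr.ind = TRUE)
    keep <- apply(idx, 1, function(rc) {
      i <- rc[1]; j <- rc[2]
      i == 1 || i == nrow(m) || j == 1 || j == ncol(m) ||
        m[i - 1, j] == 0L || m[i + 1, j] == 0L ||
        m[i, j - 1] == 0L || m[i, j + 1] == 0L
    })
    idx[keep, , drop = FALSE]
  }
  A <- bnd(a); B <- bnd(b)
  d2 <- outer(seq_len(nrow(A)), seq_len(nrow(B)), function(i, j)
    (A[i, 1] - B[j, 1])^2 + (A[i, 2] - B[j, 2])^2)
  sqrt(max(max(apply(d2, 1, min)), max(apply(d2, 2, min))))
}

tiny_train_setup <- function(seed = 1, n_train = 6, n_val = 3, size = 32L) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  list(
    train = generatePhantomDataset(rep(ceiling(n_train / 3), 3),
                                   file.path(dir, "train"), size = size,
                                   seed = seed),
    val = generatePhantomDataset(rep(ceiling(n_val / 3), 3),
                                 file.path(dir, "val"), size = size,
                                 seed = seed + 500L))
}

tiny_model_config <- function(size = 32L, ablation = FALSE) {
  modelConfig(inputSize = size,
              resnetTapChannels = c(4L, 6L, 8L, 12L),
              mobilenetTapChannels = c(3L, 4L, 5L, 6L),
              asppBranchChannels = 4L, seReduction = 2L,
              decoderChannels = c(12L, 8L, 6L, 4L),
              ablationMode = ablation)
}
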