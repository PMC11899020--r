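# Synthetic colposcopy phantom generator.
#
# Phantoms emulate the salient structure of acetowhite lesion imaging with
# exact ground truth: a dark background, a bright pinkish elliptical cervix
# field, one or more smooth irregular lesion blobs inside the ellipse that
# are brighter than their surround, Gaussian texture noise, and small
# specular highlight discs that are deliberately NOT part of the mask (a
# model must learn to ignore them). Blob outlines are radial-harmonic
# polygons, r(theta) = R * (1 + sum_{h=2..5} a_h sin(h*theta + phi_h)) with
# |a_h| <= 0.25, sampled at 72 vertices, so the emitted annotations are
# honest polygon annotations and the shipped mask is exactly their
# rasterization.

N_BLOB_VERTICES <- 72L

# polygon for one blob, in pixel coordinates; guaranteed inside the ellipse
# (the blob radius is shrunk if the target area cannot be placed)
blob_polygon <- function(cx, cy, ex, ey, ea, eb, target_area) {
  shrink <- 1
  for (round in 1:6) {
    for (attempt in 1:40) {
      amp <- stats::runif(4, 0.05, 0.25) * sample(c(-1, 1), 4, replace = TRUE)
      phase <- stats::runif(4, 0, 2 * pi)
      theta <- seq(0, 2 * pi,
                   length.out = N_BLOB_VERTICES + 1L)[-(N_BLOB_VERTICES + 1L)]
      shape <- 1 + sapply(theta, function(t)
        sum(amp * sin((2:5) * t + phase)))
      if (min(shape) <= 0.1) next
      # R from the target area: polygon area ~ pi R^2 mean(shape^2)
      R <- sqrt(shrink * target_area / (pi * mean(shape^2)))
      x <- cx + R * shape * cos(theta)
      y <- cy + R * shape * sin(theta)
      # containment within 96% of the ellipse
      if (all(((x - ex) / ea)^2 + ((y - ey) / eb)^2 <= 0.96^2))
        return(cbind(x, y))
    }
    shrink <- shrink * 0.7
  }
  NULL
}

#' Generate one synthetic phantom
#'
#' Deterministic given \code{spec@seed}: the same spec yields a
#' bit-identical image, mask and annotation set. The total lesion area
#' fraction of the mask is guaranteed to fall inside
#' \code{spec@areaFractionRange} (bounded retries, then an error).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{pair} (a \linkS4class{SamplePair}) and
#'   \code{annotations} (an \linkS4class{AnnotationSet} whose rasterization
#'   is exactly the pair's mask).
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(size = 64, classLabel = "CIN3",
#'                                   seed = 7))
#' mean(ph$pair@mask)  # within the CIN3 area fraction range
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  with_seed(spec@seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  s <- spec@size
  npx <- s * s

  # cervix ellipse covering 40-70% of the frame (lower bound raised when
  # the lesion budget demands room)
  cover_lo <- max(0.40, min(0.65, 2.5 * spec@areaFractionRange[2]))
  cover <- stats::runif(1, cover_lo, 0.70)
  aspect <- stats::runif(1, 0.75, 1.3)
  ea <- sqrt(cover * npx * aspect / pi)
  eb <- ea / aspect
  ea <- min(ea, 0.49 * s); eb <- min(eb, 0.49 * s)
  ex <- s / 2 + stats::runif(1, -0.03, 0.03) * s
  ey <- s / 2 + stats::runif(1, -0.03, 0.03) * s

  # lesion blobs: draw a target total fraction, split it across blobs,
  # rescale until the rasterized union lands inside the requested range
  rng <- spec@areaFractionRange
  ann <- NULL
  mask <- matrix(0L, s, s)
  if (spec@lesionCount > 0L && rng[2] > 0) {
    target <- stats::runif(1, rng[1] + 0.2 * (rng[2] - rng[1]),
                           rng[2] - 0.2 * (rng[2] - rng[1]))
    if (target <= 0) target <- rng[2] / 2
    scale <- 1
    ok <- FALSE
    for (iter in 1:30) {
      shares <- stats::runif(spec@lesionCount, 0.6, 1.4)
      shares <- shares / sum(shares)
      polys <- list()
      centers <- NULL
      for (b in seq_len(spec@lesionCount)) {
        area_b <- target * scale * npx * shares[b]
        placed <- NULL
        for (try in 1:60) {
          u <- stats::runif(1, 0, 0.75)
          ang <- stats::runif(1, 0, 2 * pi)
          cx <- ex + ea * u * cos(ang)
          cy <- ey + eb * u * sin(ang)
          if (!is.null(centers) && try <= 30) {
            # prefer non-overlapping placements, accept overlap later
            rad_b <- sqrt(area_b / pi) * 1.3
            dmin <- min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) -
                          centers[, 3] - rad_b)
            if (dmin < 0) next
          }
          placed <- blob_polygon(cx, cy, ex, ey, ea, eb, area_b)
          if (!is.null(placed)) {
            centers <- rbind(centers,
                             c(cx, cy, sqrt(area_b / pi) * 1.3))
            break
          }
        }
        if (is.null(placed)) break
        polys[[b]] <- placed
      }
      if (length(polys) < spec@lesionCount) {
        scale <- max(scale * 0.8, 0.05)
        next
      }
      shapes <- lapply(polys, function(p)
        list(label = "lesion", points = p))
      ann_try <- annotationSet(s, s, shapes)
      mask_try <- rasterizeAnnotations(ann_try)
      frac <- mean(mask_try)
      if (frac >= rng[1] && frac <= rng[2]) {
        ann <- ann_try
        mask <- mask_try
        ok <- TRUE
        break
      }
      # damped multiplicative correction toward the target fraction
      scale <- scale * min(2, max(0.5, (target / max(frac, 1e-6))^0.8))
    }
    if (!ok) stop("could not satisfy lesion area constraints for class ",
                  spec@classLabel)
  } else {
    ann <- annotationSet(s, s, list())
  }

  # paint: dark background, pinkish shaded ellipse, brighter lesions
  gi <- matrix(rep(seq_len(s) - 0.5, s), s, s)
  gj <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)
  edist <- ((gj - ex) / ea)^2 + ((gi - ey) / eb)^2
  inside <- edist <= 1
  shade <- pmax(0, 1 - 0.35 * edist)
  base <- c(0.20, 0.10, 0.10) + stats::runif(3, -0.03, 0.03)
  cervix <- c(0.82, 0.52, 0.55) + stats::runif(3, -0.05, 0.05)
  img <- array(0, c(s, s, 3))
  for (c in 1:3) {
    ch <- matrix(base[c], s, s)
    ch[inside] <- (cervix[c] * shade)[inside]
    ch <- ch + spec@lesionContrast * (mask == 1L)
    img[, , c] <- ch
  }

  # specular highlights: small saturated discs, never overlapping the mask
  spots <- 0L
  guard <- 0L
  while (spots < spec@specularArtifacts && guard < 200L) {
    guard <- guard + 1L
    r <- stats::runif(1, 1.2, 3)
    u <- sqrt(stats::runif(1)) * 0.9
    angs <- stats::runif(1, 0, 2 * pi)
    px <- ex + ea * u * cos(angs)
    py <- ey + eb * u * sin(angs)
    disc <- (gj - px)^2 + (gi - py)^2 <= r^2
    if (!any(disc)) next
    if (any(mask[disc] == 1L)) next
    for (c in 1:3) {
      ch <- img[, , c]
      ch[disc] <- 0.98
      img[, , c] <- ch
    }
    spots <- spots + 1L
  }

  if (spec@noiseSigma > 0) {
    img <- img + array(stats::rnorm(3 * npx, sd = spec@noiseSigma),
                       c(s, s, 3))
  }
  img <- pmin(pmax(img, 0), 1)

  pair <- samplePair(img, mask, classLabel = spec@classLabel,
                     id = sprintf("phantom_%s_seed%d", spec@classLabel,
                                  spec@seed))
  list(pair = pair, annotations = ann)
}

#' Generate a phantom dataset on disk
#'
#' Writes images, masks and LabelMe-dialect annotation files for
#' \code{nPerClass} phantoms of each CIN grade, plus a manifest CSV, and
#' returns the manifest. Per-phantom seeds are derived from \code{seed}, so
#' the dataset is reproducible. The emitted mask of every sample is exactly
#' the rasterization of its emitted annotation file.
#'
#' @param nPerClass integer vector of counts, one per grade (recycled to
#'   length 3: CIN1, CIN2, CIN3).
#' @param outDir output directory.
#' @param size phantom side in pixels.
#' @param seed base RNG seed.
#' @param specTemplate optional function \code{(classLabel, seed)} returning
#'   a \linkS4class{PhantomSpec}; defaults to \code{\link{phantomSpec}}
#'   class defaults with \code{lesionCount} 1-3 by grade.
#' @return a \linkS4class{DatasetManifest}.
#' @export
generatePhantomDataset <- function(nPerClass, outDir, size = 256L, seed = 1L,
                                   specTemplate = NULL) {
  nPerClass <- rep_len(as.integer(nPerClass), 3L)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(specTemplate)) {
    specTemplate <- function(classLabel, sd) {
      phantomSpec(size = size, classLabel = classLabel,
                  lesionCount = switch(classLabel, CIN1 = 1L, CIN2 = 2L,
                                       CIN3 = 2L),
                  seed = sd)
    }
  }
  rows <- list()
  counter <- 0L
  for (ci in seq_along(CIN_LEVELS)) {
    cl <- CIN_LEVELS[ci]
    for (k in seq_len(nPerClass[ci])) {
      counter <- counter + 1L
      sd <- (seed * 10000L + counter) %% .Machine$integer.max
      ph <- generatePhantom(specTemplate(cl, sd))
      id <- sprintf("%s_%03d", cl, k)
      ipath <- file.path(outDir, paste0(id, ".png"))
      mpath <- file.path(outDir, paste0(id, "_mask.png"))
      apath <- file.path(outDir, paste0(id, ".json"))
      writeImagePNG(ph$pair@image, ipath)
      writeMask(ph$pair@mask, mpath)
      writeAnnotations(ph$annotations, apath)
      rows[[counter]] <- data.frame(id = id, image_path = ipath,
                                    mask_path = mpath,
                                    annotation_path = apath,
                                    class_label = cl,
                                    stringsAsFactors = FALSE)
    }
  }
  manifest <- datasetManifest(do.call(rbind, rows))
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  manifest
}
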