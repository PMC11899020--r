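# Image, mask and manifest I/O, plus layout converters between H x W x C
# arrays and the engine's (N*H*W) x C matrix layout.

#' Convert an image array to the engine layout
#'
#' The engine stores a batched activation as an (N*H*W) x C matrix with row
#' index n*H*W + i*W + j. This converts a single H x W x C array (N = 1).
#'
#' @param arr H x W x C numeric array (an H x W matrix is treated as C = 1).
#' @return matrix in engine layout with a \code{tdim} attribute.
#' @export
featureMatrix <- function(arr) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  d <- dim(arr)
  m <- matrix(aperm(arr, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  tmeta(m, 1L, d[1], d[2])
}

#' Convert an engine-layout matrix back to an H x W x C array
#'
#' @param m matrix in engine layout (with \code{tdim} attribute, N = 1).
#' @param drop return an H x W matrix when C = 1.
#' @return numeric array or matrix.
#' @export
featureArray <- function(m, drop = TRUE) {
  d <- tdim(m)
  stopifnot(!is.null(d), d[1] == 1L)
  arr <- aperm(array(m, c(d[3], d[2], ncol(m))), c(2L, 1L, 3L))
  if (drop && dim(arr)[3] == 1L) arr[, , 1L] else arr
}

stack_batch <- function(mats) {
  # list of single-sample engine matrices -> one batched matrix
  d <- tdim(mats[[1]])
  out <- do.call(rbind, mats)
  tmeta(out, length(mats), d[2], d[3])
}

#' Read an RGB image from a PNG file
#'
#' Grayscale files are expanded to 3 channels; an alpha channel is dropped.
#'
#' @param path PNG file path.
#' @return H x W x 3 array in [0, 1].
#' @export
readImagePNG <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] >= 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  img
}

#' Write a binary mask as an 8-bit grayscale PNG
#'
#' Foreground pixels are written as 255, background as 0, so that reading
#' back and thresholding at 128 reproduces the mask bit-exactly.
#'
#' @param mask H x W matrix of 0/1.
#' @param path output path; the parent directory is created if needed.
#' @return invisibly, the path.
#' @export
writeMask <- function(mask, path) {
  assert_mask(mask)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write mask to: ", path)
  invisible(path)
}

#' Read a binary mask from an 8-bit grayscale PNG
#'
#' @param path mask file path.
#' @return H x W integer matrix of 0/1 (threshold at 128/255).
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1L]
  m <- (img >= 128 / 255) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Write an RGB image to a PNG file
#' @param image H x W x 3 array in [0, 1].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeImagePNG <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a dataset manifest CSV
#'
#' Expected columns: id, image_path, mask_path, class_label (optionally
#' annotation_path). Relative paths are resolved against the CSV's
#' directory.
#'
#' @param path CSV file.
#' @param check verify that all referenced files exist.
#' @return a \linkS4class{DatasetManifest}.
#' @export
readManifest <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p,
                            file.path(base, p))
  for (col in intersect(c("image_path", "mask_path", "annotation_path"),
                        names(rec))) {
    rec[[col]] <- fix(rec[[col]])
    if (check) {
      missing <- rec[[col]][!is.na(rec[[col]]) & !file.exists(rec[[col]])]
      if (length(missing))
        stop("manifest references missing file(s), e.g. ", missing[1])
    }
  }
  datasetManifest(rec)
}

#' Write a dataset manifest CSV
#' @param manifest a \linkS4class{DatasetManifest}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeManifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  rec <- manifest@records
  # store resolvable absolute paths so the CSV is independent of the
  # working directory it was written from
  for (col in intersect(c("image_path", "mask_path", "annotation_path"),
                        names(rec))) {
    ex <- !is.na(rec[[col]]) & file.exists(rec[[col]])
    rec[[col]][ex] <- normalizePath(rec[[col]][ex])
  }
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask == 0L | mask == 1L)) stop("mask values must be 0/1")
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
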