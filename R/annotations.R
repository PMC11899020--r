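# Polygon annotation parsing and rasterization to binary lesion masks.
#
# Coordinate convention throughout: LabelMe dialect, 0-based, x = column,
# y = row, origin top-left. A pixel (i, j) is foreground iff its center
# (x = j, y = i) lies inside or on any annotated polygon; vertices are
# rounded to the nearest integer before filling, shapes merge by union, and
# out-of-bounds geometry is clipped to the frame.

#' Parse a LabelMe-dialect annotation file
#'
#' Reads a JSON annotation file with keys \code{imageHeight},
#' \code{imageWidth} and \code{shapes} (each shape holding \code{label} and
#' \code{points}), preserving shape and vertex order.
#'
#' @param path annotation file path.
#' @return an \linkS4class{AnnotationSet}.
#' @export
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeAnnotations(annotationSet(10, 10, list(list(label = "lesion",
#'   points = rbind(c(1, 1), c(8, 1), c(4, 8))))), f)
#' parseLabelmeFile(f)
parseLabelmeFile <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  js <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                                    simplifyDataFrame = FALSE),
                 error = function(e)
                   stop("could not parse annotation file ", path, ": ",
                        conditionMessage(e)))
  if (is.null(js$imageHeight) || is.null(js$imageWidth))
    stop("annotation file ", path, " lacks imageHeight/imageWidth")
  shapes <- lapply(seq_along(js$shapes), function(i) {
    s <- js$shapes[[i]]
    pts <- s$points
    if (is.list(pts)) pts <- do.call(rbind, pts)
    pts <- matrix(as.numeric(pts), ncol = 2L)
    if (nrow(pts) < 3L)
      stop("shape ", i, " in ", path, " has fewer than 3 points")
    list(label = if (is.null(s$label)) "lesion" else s$label, points = pts)
  })
  annotationSet(js$imageHeight, js$imageWidth, shapes, sourcePath = path)
}

#' Write an annotation set as a LabelMe-dialect JSON file
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAnnotations <- function(ann, path) {
  stopifnot(is(ann, "AnnotationSet"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  obj <- list(
    version = "5.0.0",
    imageHeight = ann@imageHeight,
    imageWidth = ann@imageWidth,
    shapes = lapply(ann@shapes, function(s) {
      list(label = s$label, shape_type = "polygon",
           points = lapply(seq_len(nrow(s$points)),
                           function(i) as.numeric(s$points[i, ])))
    })
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Rasterize polygon annotations to a binary mask
#'
#' Fills every annotated polygon on a blank mask of the declared image size
#' and merges the shapes by union. A pixel is foreground iff its center lies
#' inside (even-odd rule on integer-rounded vertices) or on a polygon edge.
#' Geometry extending beyond the frame is clipped, so the output is always
#' in-bounds. Degenerate polygons with zero area contribute no pixels and
#' raise a warning.
#'
#' @param ann an \linkS4class{AnnotationSet}.
#' @return H x W integer matrix of 0/1.
#' @export
rasterizeAnnotations <- function(ann) {
  stopifnot(is(ann, "AnnotationSet"))
  polys <- list()
  for (i in seq_along(ann@shapes)) {
    pts <- round(ann@shapes[[i]]$points)
    if (abs(shoelace_area(pts)) < .Machine$double.eps) {
      warning("shape ", i, " has zero area after rounding; skipped")
      next
    }
    polys[[length(polys) + 1L]] <- pts
  }
  m <- cpp_fill_polygons(ann@imageHeight, ann@imageWidth, polys)
  storage.mode(m) <- "integer"
  m
}

shoelace_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Convert a directory of annotation files to mask images
#'
#' Rasterizes every \code{.json} annotation file in \code{annotationDir} to
#' an 8-bit 0/255 PNG mask in \code{outDir}. Files that fail to parse are
#' skipped with a message and counted in the \code{failures} attribute.
#' With \code{groupByClass}, masks are sorted into CIN1/CIN2/CIN3
#' subdirectories using the class labels of \code{manifest}.
#'
#' @param annotationDir directory of LabelMe-dialect JSON files.
#' @param outDir output directory (created if needed).
#' @param groupByClass sort outputs into per-grade subdirectories.
#' @param manifest optional \linkS4class{DatasetManifest} supplying class
#'   labels; matched by annotation file base name against the manifest
#'   \code{id} column.
#' @return integer count of masks written, with attribute \code{failures}.
#' @export
batchConvert <- function(annotationDir, outDir, groupByClass = FALSE,
                         manifest = NULL) {
  files <- sort(list.files(annotationDir, pattern = "\\.json$",
                           full.names = TRUE))
  if (groupByClass && is.null(manifest))
    stop("groupByClass requires a manifest with class labels")
  labels <- NULL
  if (!is.null(manifest)) {
    labels <- manifest@records$class_label
    names(labels) <- manifest@records$id
  }
  written <- 0L
  failures <- 0L
  for (f in files) {
    id <- sub("\\.json$", "", basename(f))
    mask <- tryCatch(rasterizeAnnotations(parseLabelmeFile(f)),
                     error = function(e) {
                       message("skipping ", f, ": ", conditionMessage(e))
                       NULL
                     })
    if (is.null(mask)) {
      failures <- failures + 1L
      next
    }
    sub <- if (groupByClass) {
      cl <- labels[[id]]
      if (is.null(cl) || is.na(cl)) {
        message("skipping ", f, ": no class label in manifest")
        failures <- failures + 1L
        next
      }
      file.path(outDir, cl)
    } else outDir
    writeMask(mask, file.path(sub, paste0(id, "_mask.png")))
    written <- written + 1L
  }
  attr(written, "failures") <- failures
  written
}
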