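test_that("LabelMe parsing maps fields and preserves shape order", {
  f <- withr::local_tempfile(fileext = ".json")
  tri <- list(label = "lesion", points = rbind(c(1, 1), c(8, 1), c(4, 8)))
  quad <- list(label = "lesion",
               points = rbind(c(2, 2), c(6, 2), c(6, 6), c(2, 6)))
  writeAnnotations(annotationSet(10, 10, list(tri, quad)), f)
  ann <- parseLabelmeFile(f)
  expect_s4_class(ann, "AnnotationSet")
  expect_equal(ann@imageHeight, 10L)
  expect_equal(length(ann@shapes), 2L)
  expect_equal(nrow(ann@shapes[[1]]$points), 3L)
  expect_equal(ann@shapes[[1]]$points, tri$points, ignore_attr = TRUE)
  expect_equal(ann@shapes[[2]]$points, quad$points, ignore_attr = TRUE)

  # empty shape list is legal and yields an empty mask
  f2 <- withr::local_tempfile(fileext = ".json")
  writeAnnotations(annotationSet(6, 6, list()), f2)
  ann2 <- parseLabelmeFile(f2)
  expect_length(ann2@shapes, 0L)
  expect_true(all(rasterizeAnnotations(ann2) == 0L))
})

test_that("parsing errors name the offending path or shape", {
  expect_error(parseLabelmeFile("/nonexistent/x.json"), "x.json")
  f <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", f)
  expect_error(parseLabelmeFile(f), basename(f))
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(imageHeight = 5, imageWidth = 5,
    shapes = list(list(label = "l", points = list(c(1, 1), c(2, 2))))),
    auto_unbox = TRUE), f2)
  expect_error(parseLabelmeFile(f2), "shape 1")
})

test_that("rasterization matches the point-in-polygon oracle", {
  # full-coverage square
  full <- annotationSet(8, 8, list(list(label = "l",
    points = rbind(c(0, 0), c(7, 0), c(7, 7), c(0, 7)))))
  expect_true(all(rasterizeAnnotations(full) == 1L))

  # axis-aligned rectangle: count equals brute-force point-in-polygon count
  rect <- rbind(c(1, 1), c(5, 1), c(5, 3), c(1, 3))
  ann <- annotationSet(10, 10, list(list(label = "l", points = rect)))
  expect_identical(rasterizeAnnotations(ann),
                   pip_fill_oracle(10, 10, list(rect)))

  withr::local_seed(42)
  for (rep in 1:20) {
    poly <- random_polygon(16)
    ann <- annotationSet(16, 16, list(list(label = "l", points = poly)))
    expect_identical(rasterizeAnnotations(ann),
                     pip_fill_oracle(16, 16, list(poly)),
                     label = sprintf("random polygon %d", rep))
  }
})

test_that("out-of-bounds polygons are clipped and match the oracle", {
  tri <- rbind(c(-20, -20), c(10, 2), c(2, 10))
  ann <- annotationSet(16, 16, list(list(label = "l", points = tri)))
  m <- rasterizeAnnotations(ann)
  expect_equal(dim(m), c(16L, 16L))
  expect_identical(m, pip_fill_oracle(16, 16, list(tri)))
  withr::local_seed(7)
  for (rep in 1:5) {
    poly <- random_polygon(16)
    poly[, 1] <- poly[, 1] + sample(c(-12, 12), 1)
    poly[, 2] <- poly[, 2] + sample(c(-12, 12), 1)
    ann <- annotationSet(16, 16, list(list(label = "l", points = poly)))
    expect_identical(rasterizeAnnotations(ann),
                     pip_fill_oracle(16, 16, list(poly)))
  }
})

test_that("shapes merge by union and rasterization is shift-equivariant", {
  withr::local_seed(3)
  p1 <- random_polygon(20)
  p2 <- random_polygon(20)
  both <- rasterizeAnnotations(annotationSet(20, 20, list(
    list(label = "a", points = p1), list(label = "b", points = p2))))
  m1 <- rasterizeAnnotations(annotationSet(20, 20,
                                           list(list(label = "a",
                                                     points = p1))))
  m2 <- rasterizeAnnotations(annotationSet(20, 20,
                                           list(list(label = "b",
                                                     points = p2))))
  expect_identical(both, pmax(m1, m2))

  # integer shift of an interior polygon shifts the mask identically
  poly <- rbind(c(3, 3), c(8, 4), c(6, 9))
  a <- rasterizeAnnotations(annotationSet(20, 20,
                                          list(list(label = "l",
                                                    points = poly))))
  b <- rasterizeAnnotations(annotationSet(20, 20,
    list(list(label = "l", points = poly + matrix(rep(c(4, 5), each = 3),
                                                  ncol = 2)))))
  expect_identical(b[6:20, 5:20], a[1:15, 1:16])
})

test_that("convex polygon fill is close to the shoelace area", {
  withr::local_seed(11)
  for (rep in 1:5) {
    # convex polygon: points on an ellipse
    th <- sort(runif(8, 0, 2 * pi))
    poly <- cbind(15 + 9 * cos(th), 15 + 7 * sin(th))
    m <- rasterizeAnnotations(annotationSet(30, 30,
      list(list(label = "l", points = poly))))
    rp <- round(poly)
    area <- cervseg:::shoelace_area(rp)
    per <- sum(sqrt(rowSums((rp - rp[c(2:8, 1), ])^2)))
    expect_lt(abs(sum(m) - area), per + 4)
  }
})

test_that("degenerate zero-area shapes warn and contribute nothing", {
  ann <- annotationSet(8, 8, list(list(label = "l",
    points = rbind(c(1, 1), c(3, 3), c(5, 5)))))
  expect_warning(m <- rasterizeAnnotations(ann), "zero area")
  expect_true(all(m == 0L))
})

test_that("mask write/read round-trips bit-exactly", {
  f <- withr::local_tempfile(fileext = ".png")
  zero <- matrix(0L, 5, 7)
  writeMask(zero, f)
  expect_identical(readMask(f), zero)

  m <- matrix(0L, 6, 6)
  m[cbind(c(1, 2, 3, 4, 5, 6, 1), c(1, 3, 5, 2, 4, 6, 6))] <- 1L
  writeMask(m, f)
  back <- readMask(f)
  expect_identical(back, m)
  expect_equal(sum(back), 7)

  withr::local_seed(5)
  for (rep in 1:20) {
    poly <- random_polygon(12)
    ann <- annotationSet(12, 12, list(list(label = "l", points = poly)))
    msk <- rasterizeAnnotations(ann)
    writeMask(msk, f)
    expect_identical(readMask(f), msk)
  }
})

test_that("batch conversion counts successes and failures", {
  dir <- withr::local_tempdir()
  adir <- file.path(dir, "ann"); odir <- file.path(dir, "out")
  dir.create(adir, recursive = TRUE)
  for (i in 1:3) {
    writeAnnotations(annotationSet(8, 8, list(list(label = "l",
      points = rbind(c(1, 1), c(6, 1), c(3, 6))))),
      file.path(adir, sprintf("s%d.json", i)))
  }
  n <- batchConvert(adir, odir)
  expect_equal(as.integer(n), 3L)
  expect_equal(attr(n, "failures"), 0L)

  writeLines("corrupt", file.path(adir, "bad.json"))
  expect_message(n2 <- batchConvert(adir, file.path(dir, "out2")),
                 "skipping")
  expect_equal(as.integer(n2), 3L)
  expect_equal(attr(n2, "failures"), 1L)
})

test_that("grouped batch conversion sorts by class and conserves counts", {
  dir <- withr::local_tempdir()
  adir <- file.path(dir, "ann"); odir <- file.path(dir, "out")
  dir.create(adir, recursive = TRUE)
  classes <- rep(c("CIN1", "CIN2", "CIN3"), c(4, 3, 3))
  ids <- sprintf("img%02d", 1:10)
  for (i in 1:10) {
    writeAnnotations(annotationSet(8, 8, list(list(label = "l",
      points = rbind(c(1, 1), c(6, 1), c(3, 6))))),
      file.path(adir, paste0(ids[i], ".json")))
  }
  man <- datasetManifest(data.frame(id = ids, image_path = "x",
                                    mask_path = "x",
                                    class_label = classes))
  n <- batchConvert(adir, odir, groupByClass = TRUE, manifest = man)
  expect_equal(as.integer(n), 10L)
  per_class <- vapply(c("CIN1", "CIN2", "CIN3"), function(cl)
    length(list.files(file.path(odir, cl))), integer(1))
  expect_equal(unname(per_class), c(4L, 3L, 3L))
  expect_equal(sum(per_class), 10L)
})
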