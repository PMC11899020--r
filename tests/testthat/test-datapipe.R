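test_that("resize/normalize maps intensities to [0,1] and keeps masks binary", {
  img <- array(255, c(512, 512, 3))
  msk <- matrix(1L, 512, 512)
  pair <- resizeNormalize(img, msk, 256L)
  expect_equal(dim(pair@image), c(256L, 256L, 3L))
  expect_true(all(abs(pair@image - 1) < 1e-12))
  expect_true(all(pair@mask == 1L))

  # all-ones mask survives any resize
  m2 <- matrix(1L, 37, 91)
  p2 <- resizeNormalize(array(0.5, c(37, 91, 3)), m2, 64L)
  expect_true(all(p2@mask == 1L))

  # half-foreground mask keeps its area fraction through resizing
  m3 <- matrix(0L, 100, 80)
  m3[1:50, ] <- 1L
  p3 <- resizeNormalize(array(0.2, c(100, 80, 3)), m3, 64L)
  expect_lt(abs(mean(p3@mask) - 0.5), 0.02)
  expect_true(all(p3@mask %in% c(0L, 1L)))

  expect_error(resizeNormalize(array(0, c(0, 4, 3)), matrix(0L, 0, 4), 32L),
               "positive")
})

test_that("backbone standardization has the stated closed forms", {
  z <- array(0, c(4, 4, 3))
  out <- backboneStandardize(z, "resnet-branch")
  cst <- cervseg:::.STANDARDIZE[["resnet-branch"]]
  for (c in 1:3) expect_equal(out[1, 1, c], -cst$mean[c] / cst$sd[c])

  # image equal to the mean constants maps to zero
  at_mean <- array(rep(cst$mean / 255, each = 16), c(4, 4, 3))
  expect_true(all(abs(backboneStandardize(at_mean, "resnet-branch")) < 1e-12))

  # mobilenet convention maps [0,1] onto [-1,1]
  expect_equal(range(backboneStandardize(array(c(0, 1), c(2, 2, 3)),
                                         "mobilenet-branch")), c(-1, 1))

  withr::local_seed(1)
  img <- array(runif(4 * 4 * 3), c(4, 4, 3))
  for (bb in c("resnet-branch", "mobilenet-branch")) {
    back <- backboneUnstandardize(backboneStandardize(img, bb), bb)
    expect_lt(max(abs(back - img)), 1e-6)
  }
  expect_error(backboneStandardize(img, "vgg-branch"), "unknown backboneId")
})

test_that("augmentation keeps image and mask aligned", {
  withr::local_seed(2)
  ph <- generatePhantom(phantomSpec(size = 64, classLabel = "CIN3",
                                    lesionCount = 1L, noiseSigma = 0,
                                    specularArtifacts = 0L, seed = 4))
  pair <- ph$pair

  # identity policy is a no-op
  same <- augmentPair(pair, identityPolicy(), seed = 1)
  expect_identical(same@image, pair@image)
  expect_identical(same@mask, pair@mask)

  # horizontal flip only: involution, and mask equals column reversal
  flip_pol <- augmentationPolicy(rotationLimit = 0, flipHorizontal = TRUE,
                                 flipVertical = FALSE, brightnessLimit = 0,
                                 contrastLimit = 0, elasticAlpha = 0)
  flipped <- NULL
  for (sd in 1:20) {
    cand <- augmentPair(pair, flip_pol, seed = sd)
    if (!identical(cand@mask, pair@mask)) {
      flipped <- cand
      break
    }
  }
  expect_false(is.null(flipped))
  expect_identical(flipped@mask, pair@mask[, ncol(pair@mask):1])
  expect_identical(flipped@image[, , 1], pair@image[, 64:1, 1])

  # rotation moves image and mask centroids together
  rot_pol <- augmentationPolicy(rotationLimit = 90, flipHorizontal = FALSE,
                                flipVertical = FALSE, brightnessLimit = 0,
                                contrastLimit = 0, elasticAlpha = 0)
  rot <- augmentPair(pair, rot_pol, seed = 11)
  expect_true(all(rot@mask %in% c(0L, 1L)))
  gray <- (rot@image[, , 1] + rot@image[, , 2] + rot@image[, , 3]) / 3
  # brightest-region centroid (lesion is the brightest structure)
  bright <- gray >= stats::quantile(gray, 1 - mean(rot@mask))
  cen <- function(m) colMeans(which(m, arr.ind = TRUE))
  expect_lt(max(abs(cen(bright) - cen(rot@mask == 1L))), 2)

  # elastic deformation keeps the mask binary and roughly area-preserving
  el_pol <- augmentationPolicy(rotationLimit = 0, flipHorizontal = FALSE,
                               flipVertical = FALSE, brightnessLimit = 0,
                               contrastLimit = 0, elasticAlpha = 40,
                               elasticSigma = 6)
  el <- augmentPair(pair, el_pol, seed = 3)
  expect_true(all(el@mask %in% c(0L, 1L)))
  expect_lt(abs(sum(el@mask) - sum(pair@mask)) / sum(pair@mask), 0.3)
})

test_that("largest-remainder allocation is exact and within one unit", {
  expect_equal(proportionalAllocation(c(10, 10, 10), 60), c(20L, 20L, 20L))
  expect_equal(proportionalAllocation(c(1, 2, 3), 12), c(2L, 4L, 6L))
  al <- proportionalAllocation(c(278, 286, 296), 2000)
  expect_equal(sum(al), 2000L)
  expect_true(all(abs(al - 2000 * c(278, 286, 296) / 860) <= 1))
})

test_that("dataset expansion preserves originals and class proportions", {
  dir <- withr::local_tempdir()
  man <- generatePhantomDataset(c(2, 3, 4), file.path(dir, "base"),
                                size = 32L, seed = 5)
  out <- expandDataset(man, 18L, identityPolicy(),
                       outDir = file.path(dir, "aug"), seed = 1)
  expect_equal(manifestSize(out), 18L)
  expect_equal(unname(classCounts(out)), c(4L, 6L, 8L))
  expect_true(all(man@records$id %in% out@records$id))
  aug_ids <- setdiff(out@records$id, man@records$id)
  expect_true(all(grepl("_aug", aug_ids)))
  expect_true(all(file.exists(out@records$image_path)))
  expect_error(expandDataset(man, 5L), "targetTotal")
})

test_that("stratified split is disjoint, exhaustive and deterministic", {
  dir <- withr::local_tempdir()
  recs <- data.frame(
    id = sprintf("s%03d", 1:100),
    image_path = "x", mask_path = "x",
    class_label = rep(c("CIN1", "CIN2", "CIN3"), c(40, 30, 30)))
  man <- datasetManifest(recs)
  sp <- stratifiedSplit(man, splitSpec(seed = 7))
  sizes <- vapply(sp, manifestSize, integer(1))
  expect_equal(unname(sizes), c(80L, 10L, 10L))
  expect_equal(unname(classCounts(sp$train)), c(32L, 24L, 24L))
  all_ids <- unlist(lapply(sp, function(m) m@records$id))
  expect_setequal(all_ids, recs$id)
  expect_equal(anyDuplicated(all_ids), 0L)

  sp2 <- stratifiedSplit(man, splitSpec(seed = 7))
  expect_identical(lapply(sp, function(m) m@records$id),
                   lapply(sp2, function(m) m@records$id))
  sp3 <- stratifiedSplit(man, splitSpec(seed = 8))
  expect_false(identical(sp$train@records$id, sp3$train@records$id))

  # 2000 samples at 8:1:1 -> exact sizes
  big <- datasetManifest(data.frame(
    id = sprintf("b%04d", 1:2000), image_path = "x", mask_path = "x",
    class_label = rep(c("CIN1", "CIN2", "CIN3"), c(646, 665, 689))))
  sizes2 <- vapply(stratifiedSplit(big, splitSpec(seed = 1)), manifestSize,
                   integer(1))
  expect_equal(unname(sizes2), c(1600L, 200L, 200L))
})

test_that("class imbalance percentage matches hand calculations", {
  expect_equal(classImbalancePercent(c(278, 286, 296)), 2.09)
  expect_equal(classImbalancePercent(c(100, 100, 100)), 0)
  expect_equal(classImbalancePercent(c(1, 1, 2)), 25)
  expect_error(classImbalancePercent(integer(0)), "nonempty")
})
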