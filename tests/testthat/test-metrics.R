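mk <- function(v, h = 2, w = 2) {
  m <- matrix(as.integer(v), h, w, byrow = TRUE)
  storage.mode(m) <- "integer"
  m
}

test_that("confusion accumulation matches hand counts and commutes", {
  y <- matrix(0L, 8, 8); y[1, 1:10 %% 8 + 1] <- 1L
  y <- matrix(0L, 8, 8); y[1:10] <- 1L
  cc <- accumulateConfusion(y, y)
  expect_equal(cc@p, matrix(c(54, 0, 0, 10), 2, 2))

  a <- mk(c(0, 1, 1, 0), 1, 4); b <- mk(c(0, 1, 0, 0), 1, 4)
  cc2 <- accumulateConfusion(a, b)
  expect_equal(cc2@p, matrix(c(2, 1, 0, 1), 2, 2))

  # order of accumulation is irrelevant
  ab <- accumulateConfusion(a, b, accumulateConfusion(y, y))
  ba <- accumulateConfusion(y, y, accumulateConfusion(a, b))
  expect_equal(ab@p, ba@p)
  expect_error(accumulateConfusion(y, mk(c(0, 1), 1, 2)), "shapes differ")
})

test_that("region metrics match worked examples", {
  p <- matrix(c(2, 1, 0, 1), 2, 2)  # tn=2 fn=1 fp=0 tp=1
  expect_equal(pixelAccuracy(p), 0.75)
  expect_equal(meanPixelAccuracy(p), 0.75)
  expect_equal(meanIoU(p), 7 / 12)
  expect_equal(fwIoU(p), 7 / 12)
  expect_equal(diceCoefficient(p), 2 / 3)

  perfect <- matrix(c(5, 0, 0, 3), 2, 2)
  expect_equal(pixelAccuracy(perfect), 1)
  expect_equal(meanPixelAccuracy(perfect), 1)
  expect_equal(meanIoU(perfect), 1)
  expect_equal(fwIoU(perfect), 1)
  expect_equal(diceCoefficient(perfect), 1)

  # MPA/MIoU invariant under simultaneous class relabeling
  pswap <- p[2:1, 2:1]
  expect_equal(meanPixelAccuracy(pswap), meanPixelAccuracy(p))
  expect_equal(meanIoU(pswap), meanIoU(p))

  # FWIoU is a convex combination of per-class IoUs
  expect_gte(fwIoU(p), 1 / 2)
  expect_lte(fwIoU(p), 2 / 3)
})

test_that("metrics agree with a brute-force oracle on random masks", {
  withr::local_seed(20)
  for (rep in 1:40) {
    y <- random_mask(6, 6, runif(1, 0.1, 0.9))
    yh <- random_mask(6, 6, runif(1, 0.1, 0.9))
    o <- oracle_metrics(y, yh)
    cc <- accumulateConfusion(y, yh)
    expect_equal(pixelAccuracy(cc), o$pa)
    expect_equal(suppressWarnings(meanPixelAccuracy(cc)), o$mpa)
    expect_equal(suppressWarnings(meanIoU(cc)), o$miou)
    expect_equal(fwIoU(cc), o$fwiou)
    if (!is.na(o$dice)) expect_equal(diceCoefficient(cc), o$dice)
    # PA equals the mean per-pixel agreement indicator
    expect_equal(pixelAccuracy(cc), mean(y == yh))
  }
})

test_that("Hausdorff distance handles worked cases and is symmetric", {
  m <- random_mask(10, 10, 0.4)
  m[1, 1] <- 1L  # guarantee nonempty
  expect_equal(hausdorffDistance(m, m), 0)

  a <- matrix(0L, 8, 8); a[1, 1] <- 1L
  b <- matrix(0L, 8, 8); b[4, 5] <- 1L
  expect_equal(hausdorffDistance(a, b), 5)

  # asymmetric directed distances: max(10, 0)
  a2 <- matrix(0L, 12, 12); a2[1, 1] <- 1L; a2[11, 1] <- 1L
  b2 <- matrix(0L, 12, 12); b2[1, 1] <- 1L
  expect_equal(hausdorffDistance(a2, b2), 10)

  withr::local_seed(21)
  for (rep in 1:30) {
    x <- random_mask(9, 9, 0.3); x[5, 5] <- 1L
    z <- random_mask(9, 9, 0.3); z[3, 3] <- 1L
    expect_equal(hausdorffDistance(x, z), hausdorffDistance(z, x))
    expect_equal(hausdorffDistance(x, z), oracle_hausdorff(x, z))
  }

  empty <- matrix(0L, 5, 5)
  expect_error(hausdorffDistance(empty, a[1:5, 1:5]),
               class = "hausdorffUndefinedError")
})

test_that("Hausdorff satisfies triangle-inequality spot checks", {
  withr::local_seed(22)
  for (rep in 1:10) {
    a <- random_mask(8, 8, 0.4); a[4, 4] <- 1L
    b <- random_mask(8, 8, 0.4); b[5, 5] <- 1L
    c <- random_mask(8, 8, 0.4); c[3, 3] <- 1L
    expect_lte(hausdorffDistance(a, c),
               hausdorffDistance(a, b) + hausdorffDistance(b, c) + 1e-9)
  }
})

test_that("Cohen's kappa matches its chance-corrected definition", {
  withr::local_seed(23)
  m <- random_mask(10, 10, 0.5)
  m[1, 1] <- 1L; m[2, 1] <- 0L  # non-constant
  expect_equal(cohensKappa(m, m), 1)

  # po = 0.8, pe = 0.5 construction: kappa = 0.6
  a <- matrix(0L, 10, 10); a[1:50] <- 1L
  b <- matrix(0L, 10, 10); b[11:50] <- 1L; b[51:60] <- 1L
  expect_equal(mean(a == b), 0.8)
  expect_equal(cohensKappa(a, b), 0.6)

  # complementary balanced masks: kappa = -1
  comp <- 1L - a
  storage.mode(comp) <- "integer"
  expect_equal(cohensKappa(a, comp), -1)

  # invariant under simultaneous label swap
  x <- random_mask(8, 8, 0.4); z <- random_mask(8, 8, 0.4)
  sx <- 1L - x; sz <- 1L - z
  storage.mode(sx) <- "integer"; storage.mode(sz) <- "integer"
  expect_equal(cohensKappa(x, z), cohensKappa(sx, sz))

  # constant identical raters
  ones <- matrix(1L, 4, 4)
  expect_equal(cohensKappa(ones, ones), 1)
})

test_that("Dice exceeds IoU on random masks", {
  withr::local_seed(24)
  for (rep in 1:20) {
    y <- random_mask(7, 7, 0.5); y[1, 1] <- 1L
    yh <- random_mask(7, 7, 0.5); yh[1, 1] <- 1L
    cc <- accumulateConfusion(y, yh)
    p <- cc@p
    iou_fg <- p[2, 2] / (p[2, 2] + p[1, 2] + p[2, 1])
    expect_lte(1 - diceCoefficient(cc), 2 * (1 - iou_fg) + 1e-12)
  }
})

test_that("dataset evaluation pools confusion but averages HD and kappa", {
  withr::local_seed(25)
  y1 <- random_mask(8, 8, 0.4); y1[2, 2] <- 1L
  p1 <- random_mask(8, 8, 0.4); p1[2, 2] <- 1L
  y2 <- random_mask(8, 8, 0.7); y2[5, 5] <- 1L
  p2 <- random_mask(8, 8, 0.7); p2[5, 5] <- 1L
  rep1 <- evaluateDataset(list(list(truth = y1, prediction = p1),
                               list(truth = y2, prediction = p2)))
  # pooled PA = total correct / total pixels, not mean of per-image PAs
  expect_equal(rep1@pa, (sum(y1 == p1) + sum(y2 == p2)) / 128)
  expect_equal(rep1@hausdorff, mean(c(hausdorffDistance(y1, p1),
                                      hausdorffDistance(y2, p2))))
  expect_equal(rep1@kappa, mean(c(cohensKappa(y1, p1), cohensKappa(y2, p2))))

  # duplication leaves the pooled report unchanged
  rep2 <- evaluateDataset(list(list(truth = y1, prediction = p1),
                               list(truth = y2, prediction = p2),
                               list(truth = y1, prediction = p1),
                               list(truth = y2, prediction = p2)))
  expect_equal(rep2@pa, rep1@pa)
  expect_equal(rep2@miou, rep1@miou)
  expect_equal(rep2@dice, rep1@dice)

  # perfect single pair
  rep3 <- evaluateDataset(list(list(truth = y1, prediction = y1)))
  expect_equal(rep3@pa, 1)
  expect_equal(rep3@dice, 1)
  expect_equal(rep3@hausdorff, 0)

  # empty prediction: HD excluded, reported as missing when no pair defines it
  empty <- matrix(0L, 8, 8)
  rep4 <- evaluateDataset(list(list(truth = y1, prediction = empty)))
  expect_true(is.na(rep4@hausdorff))
  expect_equal(rep4@details$hd_excluded, 1L)
})

test_that("metric report JSON round-trips", {
  withr::local_seed(26)
  y <- random_mask(8, 8, 0.4); y[1, 1] <- 1L
  p <- random_mask(8, 8, 0.4); p[1, 1] <- 1L
  rep <- evaluateDataset(list(list(truth = y, prediction = p)))
  f <- withr::local_tempfile(fileext = ".json")
  writeMetricReport(rep, f)
  back <- readMetricReport(f)
  for (sl in c("pa", "mpa", "miou", "fwiou", "dice", "kappa"))
    expect_equal(slot(back, sl), slot(rep, sl))
  expect_equal(back@nImages, rep@nImages)
})
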