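test_that("Grad-CAM++ localizes a constructed single-source activation", {
  model <- toy_single_source_model(cell = c(5L, 9L))
  img <- array(0.9, c(16, 16, 3))
  hm <- gradCAMpp(model, img, layer = "resnet_tap4")
  expect_s4_class(hm, "Heatmap")
  expect_equal(dim(hm@values), c(16L, 16L))
  expect_gte(min(hm@values), 0)
  expect_lte(max(hm@values), 1)
  expect_equal(max(hm@values), 1)
  am <- which(hm@values == max(hm@values), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(5L, 9L))

  # scaling the input leaves the argmax unchanged
  hm2 <- gradCAMpp(model, img * 0.5, layer = "resnet_tap4")
  am2 <- which(hm2@values == max(hm2@values), arr.ind = TRUE)
  expect_equal(unname(am2[1, ]), c(5L, 9L))
})

test_that("Grad-CAM++ on a trained-size model yields normalized maps", {
  withr::local_seed(40)
  m <- suppressMessages(assembleModel(tiny_model_config(32L), seed = 4))
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  # with random weights sigmoid output hovers near 0.5; use a low threshold
  # so the target region is nonempty
  hm <- gradCAMpp(m, img, layer = "resnet_tap4", threshold = 0.1)
  expect_equal(dim(hm@values), c(32L, 32L))
  expect_gte(min(hm@values), 0)
  expect_lte(max(hm@values), 1)
  expect_error(gradCAMpp(m, img, layer = "nonexistent_layer"), "unknown")
  # threshold above every probability: all-zero heatmap with a warning
  expect_warning(z <- gradCAMpp(m, img, threshold = 1), "all-zero")
  expect_true(all(z@values == 0))
})

test_that("heatmap normalization is idempotent", {
  withr::local_seed(41)
  v <- matrix(runif(64), 8, 8)
  n1 <- normalize_heatmap(v)
  expect_identical(normalize_heatmap(n1), n1)
  expect_equal(max(n1), 1)
  expect_identical(normalize_heatmap(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("overlay blends by opacity and keeps dimensions", {
  withr::local_seed(42)
  img <- array(runif(12 * 10 * 3), c(12, 10, 3))
  hm <- matrix(runif(120), 12, 10)
  expect_equal(overlayHeatmap(img, hm, opacity = 0), img)
  pure <- overlayHeatmap(img, hm, opacity = 1)
  expect_equal(dim(pure), dim(img))
  # opacity-1 render is independent of the image
  img2 <- array(runif(12 * 10 * 3), c(12, 10, 3))
  expect_equal(overlayHeatmap(img2, hm, opacity = 1), pure)
  for (k in 1:5) {
    h <- sample(6:20, 1); w <- sample(6:20, 1)
    out <- overlayHeatmap(array(runif(h * w * 3), c(h, w, 3)),
                          matrix(runif(h * w), h, w), opacity = 0.4)
    expect_equal(dim(out), c(h, w, 3L))
  }
  expect_error(overlayHeatmap(img, matrix(0, 5, 5)), "differ")
})

test_that("heatmap/mask kappa agreement matches the hand formula", {
  withr::local_seed(43)
  mask <- random_mask(10, 10, 0.5)
  hm <- matrix(as.numeric(mask), 10, 10)
  expect_equal(heatmapAgreementKappa(hm, mask), 1)

  # uniformly zero heatmap against a non-empty mask: kappa at most 0
  expect_lte(heatmapAgreementKappa(matrix(0, 10, 10), mask), 0)

  # flipped pixels with balanced marginals: kappa equals the hand formula
  flip <- hm
  idx <- sample(100, 20)
  flip[idx] <- 1 - flip[idx]
  binz <- (flip >= 0.5) * 1L
  storage.mode(binz) <- "integer"
  po <- mean(binz == mask)
  fa <- c(mean(binz == 0), mean(binz == 1))
  fb <- c(mean(mask == 0), mean(mask == 1))
  pe <- sum(fa * fb)
  expect_equal(heatmapAgreementKappa(flip, mask), (po - pe) / (1 - pe),
               tolerance = 1e-10)
})

test_that("kappa agreement degrades under increasing heatmap noise", {
  withr::local_seed(44)
  mask <- random_mask(16, 16, 0.4)
  noise_kappa <- function(p_flip) {
    mean(replicate(40, {
      hm <- matrix(as.numeric(mask), 16, 16)
      idx <- which(stats::runif(256) < p_flip)
      hm[idx] <- 1 - hm[idx]
      heatmapAgreementKappa(hm, mask)
    }))
  }
  k <- vapply(c(0.05, 0.2, 0.4), noise_kappa, numeric(1))
  expect_gt(k[1], k[2])
  expect_gt(k[2], k[3])
})
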