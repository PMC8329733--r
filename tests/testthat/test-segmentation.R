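test_that("preprocess removes constant backgrounds and is an identity when disabled", {
  sp <- c(0.1, 0.1)
  flat <- preprocess(raster_image(list(actin = array(7, c(40, 40))), sp))
  expect_true(all(flat$channels$actin == 0))
  img <- raster_image(list(actin = matrix(runif(900), 30, 30)), sp)
  expect_identical(preprocess(img, smooth_sigma = 0, ball_radius = NULL)$channels$actin,
                   img$channels$actin)
  expect_error(preprocess(img, smooth_sigma = -1), "non-negative")
})

test_that("preprocess improves wall-to-background SNR on a noisy phantom", {
  ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 20,
                                  spacing = c(0.1, 0.1)))
  contrast <- 4000 - 100
  noisy <- add_noise(ph$image, list(noise_gaussian_sd = 0.5 * contrast), seed = 4)
  bg <- ph$image$channels$actin == 100
  snr <- function(r) {
    a <- r$channels$actin
    (quantile(a, 0.999) - median(a[bg])) / sd(a[bg])
  }
  expect_gt(snr(preprocess(noisy)), snr(noisy))
})

test_that("segmentation handles blank images and separates distinct objects", {
  blank <- raster_image(list(actin = array(100, c(50, 50))), c(1, 1))
  expect_equal(n_objects(segment_lumina(blank)), 0L)
  a <- array(10, c(60, 60))
  a[10:20, 10:20] <- 500
  a[40:50, 40:50] <- 500
  two <- segment_lumina(raster_image(list(actin = a), c(1, 1)), closing_radius = 1)
  expect_equal(n_objects(two), 2L)
  expect_error(segment_lumina(blank, method = "fixed"), "threshold")
})

test_that("phantom tubes segment with IoU >= 0.8 at SNR 10", {
  for (s in 1:2) {
    ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 20,
                                    spacing = c(0.1, 0.1), bulkhead_spacing = 2,
                                    seed = s))
    img <- add_noise(ph$image, list(noise_gaussian_sd = 390), seed = s,
                     quantize = TRUE)
    lab <- segment_lumina(preprocess(img))
    expect_equal(n_objects(lab), 1L)
    expect_gte(iou(lab$labels > 0, ph$truth$mask), 0.8)
  }
})

test_that("otsu-after-preprocess segmentation ignores constant offsets", {
  ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 10,
                                  spacing = c(0.1, 0.1)))
  im1 <- add_noise(ph$image, list(noise_gaussian_sd = 100), seed = 1)
  im2 <- im1
  im2$channels$actin <- im2$channels$actin + 500
  expect_identical(segment_lumina(preprocess(im1))$labels,
                   segment_lumina(preprocess(im2))$labels)
})

test_that("mask correction restricts, splits, and drops per contract", {
  l <- array(0L, c(20, 20))
  l[5:15, 5:15] <- 1L
  lm <- label_map(l, c(1, 1))
  expect_identical(apply_mask_correction(lm, array(TRUE, c(20, 20)))$labels,
                   lm$labels)
  expect_equal(n_objects(apply_mask_correction(lm, array(FALSE, c(20, 20)))), 0L)
  bisect <- array(TRUE, c(20, 20))
  bisect[, 10] <- FALSE
  expect_equal(n_objects(apply_mask_correction(lm, bisect)), 2L)
  expect_error(apply_mask_correction(lm, array(TRUE, c(10, 10))), "shape")
})

test_that("GFP rescue filter keeps objects at or above the 70% boundary", {
  l <- array(0L, c(12, 12))
  l[1:2, 1:5] <- 1L   # overlap 1.0
  l[5:6, 1:5] <- 2L   # overlap 0.0
  l[9:10, 1:5] <- 3L  # overlap exactly 0.70 (7 of 10 px)
  g <- array(0, c(12, 12))
  g[1:2, 1:5] <- 1
  g[9, 1:4] <- 1
  g[10, 1:3] <- 1
  lm <- label_map(l, c(1, 1))
  kept <- gfp_overlap_filter(lm, g, min_overlap = 0.7)
  expect_equal(n_objects(kept), 2L)
  expect_equal(unname(attr(kept, "overlap")), c(1, 0, 0.7))
  # labels of survivors are consecutive
  expect_setequal(setdiff(unique(as.vector(kept$labels)), 0L), c(1L, 2L))
  # monotone in min_overlap: lowering the bar never removes a kept object
  for (thr in c(0.69, 0.5, 0)) {
    expect_gte(n_objects(gfp_overlap_filter(lm, g, thr)), n_objects(kept))
  }
})

test_that("region statistics report A, w = A^(3/2), and overlaps", {
  l <- array(0L, c(10, 10))
  l[1:2, 1:2] <- 1L
  l[5:8, 5:8] <- 2L
  rs <- region_stats(label_map(l, c(1, 1)))
  expect_equal(rs$A, c(4, 16))
  expect_equal(rs$w, c(8, 64))
  expect_equal(rs$gfp_overlap, c(0, 0))
  empty <- region_stats(label_map(array(0L, c(5, 5)), c(1, 1)))
  expect_equal(nrow(empty), 0L)
  expect_error(object_weight(0), "domain")
})

test_that("relabelling conserves foreground pixels", {
  set.seed(3)
  a <- array(10, c(40, 40))
  a[5:15, 5:15] <- 500
  a[25:35, 25:35] <- 500
  lab <- segment_lumina(raster_image(list(actin = a), c(1, 1)), closing_radius = 0)
  n_before <- sum(lab$labels > 0)
  corrected <- apply_mask_correction(lab, array(TRUE, dim(lab$labels)))
  expect_equal(sum(corrected$labels > 0), n_before)
})
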