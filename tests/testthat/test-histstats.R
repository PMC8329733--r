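test_that("object histograms are unit-mass over half-open bins", {
  edges <- radius_bins()
  l <- array(0L, c(10, 10))
  l[1:2, 1:2] <- 1L
  l[5:8, 5:8] <- 2L
  r <- array(0, c(10, 10))
  r[l == 1L] <- 1.0
  r[l == 2L] <- rep(c(1, 3), each = 8)
  lm <- label_map(l, c(1, 1))
  h1 <- object_histogram(r, lm, 1L, edges)
  expect_equal(sum(h1$density), 1)
  expect_equal(h1$density[findInterval(1.0, edges)], 1) # all mass at radius 1
  h2 <- object_histogram(r, lm, 2L, edges)
  expect_equal(h2$density[findInterval(1, edges)], 0.5)
  expect_equal(h2$density[findInterval(3, edges)], 0.5)
  # single-pixel object is a valid histogram
  l[10, 10] <- 3L
  r[10, 10] <- 0.4
  h3 <- object_histogram(r, label_map(l, c(1, 1)), 3L, edges)
  expect_equal(sum(h3$density), 1)
  expect_error(object_histogram(r, lm, 99L, edges), "lookup")
  # top bin absorbs capped values at the last edge
  r[l == 1L] <- 10
  hc <- object_histogram(r, lm, 1L, edges)
  expect_equal(hc$density[length(edges) - 1L], 1)
})

test_that("volume weights follow A^(3/2)", {
  expect_equal(object_weight(1), 1)
  expect_equal(object_weight(4), 8)
  expect_equal(object_weight(16), 64)
})

test_that("image aggregation is the weight-normalized histogram sum", {
  edges <- radius_bins()
  l <- array(0L, c(10, 10))
  l[1:2, 1:2] <- 1L  # A = 4
  l[5:8, 5:8] <- 2L  # A = 16
  r <- array(0, c(10, 10))
  r[l == 1L] <- 0.75
  r[l == 2L] <- 7.2
  lm <- label_map(l, c(1, 1))
  hs <- lapply(1:2, function(id) object_histogram(r, lm, id, edges))
  ih <- aggregate_image(hs)
  expect_equal(ih$density[findInterval(0.75, edges)], 1 / 9)
  expect_equal(ih$density[findInterval(7.2, edges)], 8 / 9)
  expect_equal(sum(ih$density), 1, tolerance = 1e-9)
  # one object: identical to its own histogram
  expect_equal(aggregate_image(hs[1])$density, hs[[1]]$density)
  # identical histograms with any weights: unchanged
  expect_equal(aggregate_image(list(hs[[1]], hs[[1]]), weights = c(3, 11))$density,
               hs[[1]]$density)
  # empty image -> sentinel, with a message
  expect_message(out <- aggregate_image(list()), "empty")
  expect_null(out)
})

test_that("two-level averaging produces the documented means and SEMs", {
  sh <- average_histograms(list(split_histogram(0.2, 7.1),
                                split_histogram(0.4, 7.1)),
                           experiment = c("A", "B"))
  bin <- findInterval(7.1, sh$bin_edges)
  expect_equal(sh$density[bin], 0.3)
  expect_equal(sh$sem[bin], 0.1)
  expect_equal(sum(sh$density), 1, tolerance = 1e-9)
  # identical inputs -> SEM 0 everywhere
  sh0 <- average_histograms(list(split_histogram(0.3, 7.1),
                                 split_histogram(0.3, 7.1)), c("A", "B"))
  expect_true(all(sh0$sem == 0))
  # unbalanced design: single-image experiment carries full weight
  shu <- average_histograms(rep(list(split_histogram(0.2, 7.1)), 5)[1:5],
                            experiment = c(1, 1, 1, 1, 2))
  expect_equal(shu$density[bin], 0.2)
  shu2 <- average_histograms(list(split_histogram(0.2, 7.1),
                                  split_histogram(0.2, 7.1),
                                  split_histogram(0.2, 7.1),
                                  split_histogram(0.2, 7.1),
                                  split_histogram(0.5, 7.1)),
                             experiment = c(1, 1, 1, 1, 2))
  expect_equal(shu2$density[bin], 0.35)
  expect_warning(average_histograms(list(split_histogram(0.2, 7.1)), "A"),
                 "SEM")
})

test_that("fraction above a threshold works in mass and object mode", {
  sh <- average_histograms(list(split_histogram(0.2, 7.1),
                                split_histogram(0.4, 7.1)), c("A", "B"))
  f <- fraction_above(sh, 6, mode = "mass")
  expect_equal(f$per_experiment, c(A = 20, B = 40))
  expect_equal(f$mean, 30)
  expect_equal(f$sem, 10)
  # all mass below / above the threshold
  lo <- average_histograms(list(point_histogram(1), point_histogram(1)), c("A", "B"))
  expect_equal(fraction_above(lo, 6)$mean, 0)
  hi <- average_histograms(list(point_histogram(8), point_histogram(8)), c("A", "B"))
  expect_equal(fraction_above(hi, 6)$mean, 100)
  # unaligned threshold is realigned with a warning
  expect_warning(fr <- fraction_above(sh, 6.1, mode = "mass"), "realigned")
  expect_equal(fr$threshold, 6)
  # object mode
  obj <- data.frame(experiment = c(1, 1, 2, 2),
                    max_radius = c(7, 1, 1, 1))
  fo <- fraction_above(obj, 6, mode = "object")
  expect_equal(unname(fo$per_experiment), c(50, 0))
  expect_equal(fo$mean, 25)
})

test_that("densities and threshold fractions are scale-equivariant", {
  set.seed(5)
  edges <- radius_bins(10, 0.25)
  mk <- function(vals, edges) {
    l <- array(0L, c(6, 6))
    l[seq_along(vals)] <- 1L
    r <- array(0, c(6, 6))
    r[seq_along(vals)] <- vals
    object_histogram(r, label_map(l, c(1, 1)), 1L, edges)
  }
  vals <- runif(12, 0.3, 9.5)
  h1 <- mk(vals, edges)
  h2 <- mk(2 * vals, 2 * edges)
  expect_equal(h1$density, h2$density)
  s1 <- average_histograms(list(h1), "A") |> suppressWarnings()
  s2 <- average_histograms(list(h2), "A") |> suppressWarnings()
  expect_equal(fraction_above(s1, 6)$mean, fraction_above(s2, 12)$mean)
})

test_that("equal-sized objects reduce weighting to an unweighted mean", {
  edges <- radius_bins()
  l <- array(0L, c(8, 8))
  l[1:2, 1:2] <- 1L
  l[5:6, 5:6] <- 2L
  r <- array(0, c(8, 8))
  r[l == 1L] <- 1
  r[l == 2L] <- 3
  lm <- label_map(l, c(1, 1))
  hs <- lapply(1:2, function(id) object_histogram(r, lm, id, edges))
  ih <- aggregate_image(hs)
  expect_equal(ih$density, (hs[[1]]$density + hs[[2]]$density) / 2)
})
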