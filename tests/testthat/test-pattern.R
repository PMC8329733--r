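test_that("axis profiles span the tube and reject non-tubular objects", {
  fx <- tube_fixture(1, bulkhead_spacing = 0, noise_sd = 0, tube_length = 20)
  rmap <- radius_map(local_thickness(fx$truth$mask, c(0.1, 0.1)))
  pr <- extract_axis_profile(fx$labels, fx$image, rmap, 1L)
  expect_true(pr$tubular)
  expect_lt(abs(max(pr$arclength) - 20), 1) # medial axis of a capsule spans its segment
  expect_true(all(diff(pr$arclength) > 0))
  # uniform tube: intensity constant along the lumen (away from the caps)
  core <- pr$intensity[pr$arclength > 2 & pr$arclength < 18]
  expect_lt(sd(core) / mean(core), 0.05)
  # cyst: not tubular
  phc <- make_phantom(phantom_spec("cyst", cyst_radius = 8, spacing = c(0.2, 0.2)))
  lmc <- label_map(array(as.integer(phc$truth$mask), dim(phc$truth$mask)),
                   c(0.2, 0.2))
  rc <- radius_map(local_thickness(phc$truth$mask, c(0.2, 0.2)))
  prc <- extract_axis_profile(lmc, phc$image, rc, 1L)
  expect_false(prc$tubular)
  st <- measure_periodicity(prc)
  expect_false(st$has_stripes)
  expect_equal(st$status, "not_tubular")
})

test_that("periodicity measurement is invariant to constant intensity offsets", {
  fx <- tube_fixture(2, bulkhead_spacing = 2)
  rmap <- radius_map(local_thickness(fx$truth$mask, c(0.1, 0.1)))
  pr <- extract_axis_profile(fx$labels, fx$image, rmap, 1L)
  p1 <- measure_periodicity(pr)
  pr2 <- pr
  pr2$intensity <- pr2$intensity + 1234
  p2 <- measure_periodicity(pr2)
  expect_equal(p1$dominant_spacing, p2$dominant_spacing)
  expect_equal(p1$peak_prominence, p2$peak_prominence)
})

test_that("bulkhead spacing is recovered across jitter levels", {
  rec <- unlist(lapply(c(0, 0.1, 0.2), function(j) {
    vapply(1:6, function(s) {
      periodicity_of(tube_fixture(s, bulkhead_spacing = 2, jitter = j))$dominant_spacing
    }, 0)
  }))
  expect_lte(median(abs(rec - 2), na.rm = TRUE), 0.1 + 1e-9) # one sample step
  # and jitter-free tubes individually
  expect_true(all(abs(rec[1:6] - 2) <= 0.1 + 1e-9))
})

test_that("stripe-free tubes are not flagged and spacing scales with diameter", {
  flags <- vapply(1:20, function(s) {
    periodicity_of(tube_fixture(s, bulkhead_spacing = 0))$has_stripes
  }, TRUE)
  expect_lte(mean(flags), 0.05)
  p <- periodicity_of(tube_fixture(3, bulkhead_spacing = 2))
  expect_true(p$has_stripes)
  expect_lt(abs(p$spacing_over_diameter - 1), 0.25)
})

test_that("short profiles return the insufficient-length sentinel", {
  pr <- structure(list(object_id = 1L, arclength = (0:9) / 10,
                       intensity = rnorm(10), local_radius = rep(1, 10),
                       tubular = TRUE, n_branches = 0L),
                  class = "axis_profile")
  p <- measure_periodicity(pr)
  expect_false(p$has_stripes)
  expect_equal(p$status, "too_short")
})
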