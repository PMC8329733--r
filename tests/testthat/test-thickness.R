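test_that("efficient transform matches the brute-force definition bit for bit", {
  set.seed(101)
  # random 2D masks at unit, dyadic and generic anisotropic spacings
  spacings <- list(c(1, 1), c(0.5, 0.5), c(0.3, 0.7), c(0.13, 0.41))
  for (i in 1:40) {
    m <- random_mask(c(16, 16), runif(1, 0.2, 0.8))
    sp <- spacings[[1L + (i %% length(spacings))]]
    expect_identical(local_thickness(m, sp)$values,
                     brute_force_thickness(m, sp)$values)
  }
  # 3D
  for (i in 1:6) {
    m <- random_mask(c(8, 8, 8), runif(1, 0.3, 0.7))
    sp <- list(c(1, 1, 1), c(0.5, 1, 2), c(0.37, 0.52, 0.71))[[1L + (i %% 3)]]
    expect_identical(local_thickness(m, sp)$values,
                     brute_force_thickness(m, sp)$values)
  }
})

test_that("single pixels, empty masks, and unbounded objects behave per contract", {
  m <- array(FALSE, c(5, 5))
  expect_identical(local_thickness(m, c(1, 1))$values, array(0, c(5, 5)))
  m[3, 3] <- TRUE
  t1 <- local_thickness(m, c(1, 1))
  expect_equal(t1$values[3, 3], 2) # r = 1 to the adjacent background centre
  expect_identical(t1$values > 0, m) # positive exactly on foreground
  expect_error(local_thickness(array(TRUE, c(4, 4)), c(1, 1)), "background")
})

test_that("values scale exactly with isotropic dyadic spacing", {
  set.seed(7)
  m <- random_mask(c(16, 16))
  base <- local_thickness(m, c(1, 1))$values
  expect_identical(local_thickness(m, c(0.5, 0.5))$values, 0.5 * base)
  expect_identical(local_thickness(m, c(2, 2))$values, 2 * base)
})

test_that("thickness is at least twice the EDT radius everywhere", {
  set.seed(11)
  for (i in 1:10) {
    m <- random_mask(c(16, 16))
    sp <- c(0.4, 0.9)
    d <- dim(m)
    r2 <- lumenmorph:::.edt_sq_cpp(lumenmorph:::as_int_mask(m), d, sp)
    tv <- local_thickness(m, sp)$values
    expect_true(all(tv[m] >= 2 * sqrt(r2[m]) - 1e-12))
  }
})

test_that("adding foreground pixels never decreases existing thickness", {
  set.seed(13)
  for (i in 1:10) {
    m <- random_mask(c(16, 16))
    t1 <- local_thickness(m, c(1, 1))$values
    m2 <- m
    m2[sample(which(!m2), 4L)] <- TRUE
    if (all(m2)) m2[1] <- FALSE
    t2 <- local_thickness(m2, c(1, 1))$values
    keep <- m & m2
    expect_true(all(t2[keep] >= t1[keep] - 1e-12))
  }
})

test_that("digital disk centres approach the closed-form diameter", {
  for (R in c(5, 10, 20)) {
    b <- digital_ball(R, 2L)
    tv <- local_thickness(b$mask, c(1, 1))$values
    centre <- tv[b$centre[1L], b$centre[2L]]
    expect_lt(abs(centre - 2 * R) / (2 * R), 2 / R)
  }
})

test_that("radius cap clips candidate radii and commutes with the min", {
  set.seed(17)
  for (i in 1:8) {
    m <- random_mask(c(16, 16))
    un <- local_thickness(m, c(1, 1))$values
    cp <- local_thickness(m, c(1, 1), max_radius = 2)$values
    expect_identical(cp, pmin(un, 4))
    expect_lte(max(cp), 4)
  }
  ph <- make_phantom(phantom_spec("cyst", cyst_radius = 8, spacing = c(0.2, 0.2)))
  capped <- local_thickness(ph$truth$mask, c(0.2, 0.2), max_radius = 5)
  expect_lte(max(capped$values), 10)
  expect_true(capped$capped)
})

test_that("the border flag controls whether disks may leave the image", {
  m <- array(FALSE, c(11, 11))
  m[, 1:5] <- TRUE # half-plane strip touching three borders
  closed <- local_thickness(m, c(1, 1))$values
  open <- local_thickness(m, c(1, 1), border_background = FALSE)$values
  expect_true(all(open[m] >= closed[m]))
  expect_gt(max(open), max(closed)) # disks extend past the replicated border
})

test_that("radius_map halves thickness and keeps background at zero", {
  m <- random_mask(c(12, 12))
  t1 <- local_thickness(m, c(1, 1))
  r <- radius_map(t1)
  expect_identical(r, t1$values / 2)
  expect_true(all(r[!m] == 0))
  t0 <- local_thickness(array(FALSE, c(5, 5)), c(1, 1))
  expect_identical(radius_map(t0), array(0, c(5, 5)))
})
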