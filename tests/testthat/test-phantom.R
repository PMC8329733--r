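test_that("straight tube truth matches its nominal geometry", {
  ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 20,
                                  spacing = c(0.1, 0.1)))
  tr <- ph$truth
  expect_true(all(tr$radius_field[tr$mask] == 1))
  expect_length(tr$bulkhead_positions, 0L)
  # centerline spans the tube length
  span <- (max(tr$centerline[, 2L]) - min(tr$centerline[, 2L])) * 0.1
  expect_lt(abs(span - 20), 0.5)
  # one connected component
  lab <- lumenmorph:::.label_components_cpp(
    lumenmorph:::as_int_mask(tr$mask), dim(tr$mask))
  expect_equal(max(lab), 1L)
})

test_that("bulkhead positions follow the requested lattice and jitter", {
  ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 20,
                                  spacing = c(0.1, 0.1), bulkhead_spacing = 2))
  expect_equal(ph$truth$bulkhead_positions, seq(2, 18, by = 2))
  # jittered gaps keep the requested mean within sampling error
  gaps <- unlist(lapply(1:12, function(s) {
    p <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 40,
                                   spacing = c(0.1, 0.1), bulkhead_spacing = 2,
                                   bulkhead_jitter = 0.1, seed = s))
    diff(p$truth$bulkhead_positions)
  }))
  expect_lt(abs(mean(gaps) - 2), 3 * 0.2 / sqrt(length(gaps)) + 0.02)
})

test_that("bulkheads carve the lumen but never seal it", {
  for (depth in c(0.3, 0.6, 0.9)) {
    ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 20,
                                    spacing = c(0.1, 0.1), bulkhead_spacing = 2,
                                    bulkhead_depth = depth))
    lab <- lumenmorph:::.label_components_cpp(
      lumenmorph:::as_int_mask(ph$truth$mask), dim(ph$truth$mask))
    expect_equal(max(lab), 1L)
  }
  expect_error(phantom_spec("tube", bulkhead_depth = 1), "seal")
})

test_that("cyst truth has the nominal radius everywhere incl. the centre", {
  ph <- make_phantom(phantom_spec("cyst", cyst_radius = 8, spacing = c(0.1, 0.1)))
  cen <- round(dim(ph$truth$mask) / 2)
  expect_true(ph$truth$mask[cen[1L], cen[2L]])
  expect_equal(ph$truth$radius_field[cen[1L], cen[2L]], 8)
  expect_length(ph$truth$bulkhead_positions, 0L)
})

test_that("ground truth is consistent with the brute-force thickness oracle", {
  sp <- c(0.25, 0.25)
  tol <- sqrt(2) * 0.25
  pht <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 4,
                                   spacing = sp))
  bt <- brute_force_thickness(pht$truth$mask, sp)
  expect_lt(max(abs(bt$values[pht$truth$mask] / 2 -
                      pht$truth$radius_field[pht$truth$mask])), tol)
  phc <- make_phantom(phantom_spec("cyst", cyst_radius = 3, spacing = sp))
  bc <- brute_force_thickness(phc$truth$mask, sp)
  expect_lt(max(abs(bc$values[phc$truth$mask] / 2 - 3)), tol)
})

test_that("sizing errors name the offending axis", {
  expect_error(phantom_spec("tube", tube_length = 30, image_size = c(30, 100),
                            spacing = c(0.1, 0.1)),
               "axis 2")
})

test_that("noise model: identity, determinism, and Poisson mean", {
  ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 5,
                                  spacing = c(0.2, 0.2)))
  none <- add_noise(ph$image, list(noise_gaussian_sd = 0, noise_poisson_scale = 0))
  expect_identical(none$channels$actin, ph$image$channels$actin)
  n1 <- add_noise(ph$image, list(noise_gaussian_sd = 50, noise_poisson_scale = 1),
                  seed = 4)
  n2 <- add_noise(ph$image, list(noise_gaussian_sd = 50, noise_poisson_scale = 1),
                  seed = 4)
  expect_identical(n1$channels$actin, n2$channels$actin)
  expect_error(add_noise(ph$image, list(noise_gaussian_sd = -1)), "parameter")
  # law of large numbers on a constant field
  flat <- raster_image(list(actin = array(100, c(100, 100))), c(1, 1))
  noisy <- add_noise(flat, list(noise_gaussian_sd = 0, noise_poisson_scale = 1),
                     seed = 8)
  se <- sqrt(100 / 1e4)
  expect_lt(abs(mean(noisy$channels$actin) - 100), 3 * se)
})

test_that("rescue-marker channel marks round(n * fraction) dilated objects", {
  masks <- lapply(1:10, function(k) {
    m <- array(FALSE, c(30, 40))
    m[(3 * k - 2):(3 * k), 5:10] <- TRUE
    list(mask = m)
  })
  g1 <- make_gfp_channel(masks, 1, seed = 2)
  expect_true(all(vapply(masks, function(t) all(g1$channel[t$mask] == 1), TRUE)))
  g0 <- make_gfp_channel(masks, 0, seed = 2)
  expect_true(all(g0$channel == 0))
  gh <- make_gfp_channel(masks, 0.5, seed = 2)
  expect_equal(sum(gh$positive), 5L)
})

test_that("datasets are a pure function of design and master seed", {
  des <- phantom_design(n_experiments = 3L, images_per_condition = 4L,
                        objects_per_image = 3L, master_seed = 5L)
  ds1 <- make_dataset(des)
  expect_equal(nrow(ds1$manifest), 3L * 4L * length(des$conditions))
  expect_false(anyDuplicated(ds1$manifest$seed) > 0)
  ds2 <- make_dataset(des)
  expect_identical(ds1$manifest, ds2$manifest)
  expect_identical(ds1$images[[5L]]$image$channels, ds2$images[[5L]]$image$channels)
  # realized mixtures match the design within rounding
  kd <- subset(ds1$manifest, condition == "knockdown")
  expect_true(all(kd$n_cysts == round(0.2 * des$objects_per_image)))
  expect_error(phantom_design(conditions = list()), "configuration")
})
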