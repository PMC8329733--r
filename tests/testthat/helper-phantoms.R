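# Shared fixtures: all synthetic, built in code at test time.

iou <- function(a, b) sum(a & b) / sum(a | b)

# random binary mask guaranteed to contain background
random_mask <- function(dim, p = 0.5) {
  m <- array(runif(prod(dim)) < p, dim = dim)
  if (all(m)) m[1] <- FALSE
  m
}

# digital disk/sphere of radius R px in an n^d grid (centre pixel returned too)
digital_ball <- function(R, nd = 2L, margin = 3L) {
  n <- 2L * R + 2L * margin + 1L
  cen <- (n + 1L) / 2
  xs <- seq_len(n) - cen
  if (nd == 2L) {
    m <- outer(xs, xs, function(a, b) sqrt(a^2 + b^2)) <= R + 0.5
  } else {
    m <- array(FALSE, c(n, n, n))
    for (k in seq_len(n)) m[, , k] <- sqrt(outer(xs^2, xs^2, "+") + xs[k]^2) <= R + 0.5
  }
  list(mask = m, centre = rep(as.integer(cen), nd))
}

# noisy bulkheaded (or stripe-free) tube, preprocessed, with truth labels
tube_fixture <- function(seed, bulkhead_spacing = 2, jitter = 0,
                         noise_sd = 200, tube_length = 40,
                         spacing = c(0.1, 0.1)) {
  spec <- phantom_spec("tube", tube_radius = 1, tube_length = tube_length,
                       spacing = spacing, bulkhead_spacing = bulkhead_spacing,
                       bulkhead_jitter = jitter, seed = seed)
  ph <- make_phantom(spec)
  img <- add_noise(ph$image, list(noise_gaussian_sd = noise_sd),
                   seed = seed, quantize = TRUE)
  img <- preprocess(img)
  labels <- label_map(array(as.integer(ph$truth$mask), dim(ph$truth$mask)),
                      spacing)
  list(spec = spec, truth = ph$truth, image = img, labels = labels)
}

periodicity_of <- function(fx) {
  rmap <- radius_map(local_thickness(fx$truth$mask, fx$labels$spacing))
  pr <- extract_axis_profile(fx$labels, fx$image, rmap, 1L)
  measure_periodicity(pr)
}

# single-bin image-level histogram: all mass in the bin containing `at`
point_histogram <- function(mass_bin_at, edges = radius_bins()) {
  d <- numeric(length(edges) - 1L)
  d[findInterval(mass_bin_at, edges)] <- 1
  structure(list(density = d, bin_edges = edges, level = "image",
                 n_contributors = 1L, sem = NULL),
            class = "radius_histogram")
}

# image-level histogram with given mass in the bin containing `at`,
# remainder in the first bin
split_histogram <- function(mass, at, edges = radius_bins()) {
  d <- numeric(length(edges) - 1L)
  d[findInterval(at, edges)] <- mass
  d[1L] <- d[1L] + (1 - mass)
  structure(list(density = d, bin_edges = edges, level = "image",
                 n_contributors = 1L, sem = NULL),
            class = "radius_histogram")
}
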