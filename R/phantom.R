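#' Specification of a synthetic lumen phantom
#'
#' Describes one synthetic object: a straight tube, a branched tube, or a
#' spherical cyst, rendered into an actin-like intensity channel with bright
#' walls and, for tubes, quasi-periodic transverse bulkhead stripes. The
#' geometry emulates bile canaliculi: tubes of ~1 um radius whose bulkhead
#' stripes repeat at a spacing on the order of the lumen diameter, versus
#' cysts of several micrometres radius without stripes. Intensities are in
#' camera ADU (arbitrary fluorescence units).
#'
#' @param shape_kind one of `"tube"`, `"branched_tube"`, `"cyst"`.
#' @param image_size integer pixels per axis (length 2 or 3); `NULL` sizes the
#'   image to fit the object plus a margin.
#' @param spacing micrometres per pixel per axis.
#' @param tube_radius,tube_length tube caliber and length, micrometres.
#' @param branch_count number of side branches (branched_tube only).
#' @param cyst_radius cyst radius, micrometres.
#' @param bulkhead_spacing mean stripe spacing along the tube axis in
#'   micrometres; 0 disables bulkheads.
#' @param bulkhead_jitter fractional standard deviation of the spacing
#'   (consecutive gaps are `spacing * (1 + jitter * z)`, z standard normal).
#' @param bulkhead_depth fraction in `[0, 1)` of the lumen cross-section
#'   occluded by each bulkhead plate; must stay below 1 so bulkheads never
#'   seal the lumen into separate chambers.
#' @param wall_intensity,stripe_intensity,interior_intensity,background_intensity
#'   rendering intensities (ADU).
#' @param noise_gaussian_sd Gaussian read-noise standard deviation (ADU).
#' @param noise_poisson_scale photons per ADU for Poisson shot noise
#'   (0 = off).
#' @param gfp_fraction fraction of objects marked rescue-positive when a GFP
#'   channel is generated.
#' @param seed integer seed controlling bulkhead jitter (and, via
#'   [add_noise()], the noise realization).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_kind = c("tube", "branched_tube", "cyst"),
                         image_size = NULL,
                         spacing = c(0.1, 0.1),
                         tube_radius = 1,
                         tube_length = 20,
                         branch_count = 2L,
                         cyst_radius = 8,
                         bulkhead_spacing = 0,
                         bulkhead_jitter = 0,
                         bulkhead_depth = 0.6,
                         wall_intensity = 4000,
                         stripe_intensity = 4000,
                         interior_intensity = 3000,
                         background_intensity = 100,
                         noise_gaussian_sd = 0,
                         noise_poisson_scale = 0,
                         gfp_fraction = 0,
                         seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  nd <- length(spacing)
  if (!nd %in% c(2L, 3L)) stop("`spacing` must have 2 or 3 axes")
  stopifnot_scalar_pos(tube_radius, "tube_radius")
  stopifnot_scalar_pos(tube_length, "tube_length")
  stopifnot_scalar_pos(cyst_radius, "cyst_radius")
  stopifnot_scalar_pos(bulkhead_spacing, "bulkhead_spacing", strict = FALSE)
  stopifnot_scalar_pos(bulkhead_jitter, "bulkhead_jitter", strict = FALSE)
  stopifnot_scalar_pos(noise_gaussian_sd, "noise_gaussian_sd", strict = FALSE)
  stopifnot_scalar_pos(noise_poisson_scale, "noise_poisson_scale",
                       strict = FALSE)
  if (bulkhead_depth < 0 || bulkhead_depth >= 1) {
    stop("`bulkhead_depth` must be in [0, 1): a bulkhead may not seal the lumen")
  }
  if (gfp_fraction < 0 || gfp_fraction > 1) {
    stop("`gfp_fraction` must be in [0, 1]")
  }
  spec <- structure(
    list(shape_kind = shape_kind, image_size = image_size,
         spacing = as.double(spacing), tube_radius = tube_radius,
         tube_length = tube_length, branch_count = as.integer(branch_count),
         cyst_radius = cyst_radius, bulkhead_spacing = bulkhead_spacing,
         bulkhead_jitter = bulkhead_jitter, bulkhead_depth = bulkhead_depth,
         wall_intensity = wall_intensity, stripe_intensity = stripe_intensity,
         interior_intensity = interior_intensity,
         background_intensity = background_intensity,
         noise_gaussian_sd = noise_gaussian_sd,
         noise_poisson_scale = noise_poisson_scale,
         gfp_fraction = gfp_fraction, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  if (is.null(spec$image_size)) {
    spec$image_size <- default_image_size(spec)
  } else {
    spec$image_size <- as.integer(image_size)
    if (length(spec$image_size) != nd) {
      stop("`image_size` must have one entry per spacing axis")
    }
  }
  check_fits(spec)
  spec
}

# physical extent (um) the object needs along each axis, excluding margin
object_extent <- function(spec) {
  nd <- length(spec$spacing)
  r <- spec$tube_radius
  switch(spec$shape_kind,
    cyst = rep(2 * spec$cyst_radius, nd),
    tube = {
      e <- rep(2 * r, nd)
      e[2L] <- spec$tube_length + 2 * r
      e
    },
    branched_tube = {
      # branches leave the main axis at +-45 degrees, length tube_length / 3
      b <- spec$tube_length / 3
      e <- rep(2 * r + 2 * (b / sqrt(2) + r), nd)
      e[2L] <- spec$tube_length + 2 * r
      e
    }
  )
}

default_image_size <- function(spec, margin_px = 4L) {
  as.integer(ceiling(object_extent(spec) / spec$spacing)) + 2L * margin_px
}

check_fits <- function(spec, margin_px = 2L) {
  need <- ceiling(object_extent(spec) / spec$spacing) + 2L * margin_px
  short <- which(spec$image_size < need)
  if (length(short)) {
    stop(sprintf(
      "object does not fit in image_size along axis %d (%d px needed, %d given)",
      short[1L], need[short[1L]], spec$image_size[short[1L]]))
  }
  invisible(TRUE)
}

#' Render a synthetic lumen phantom
#'
#' Rasterizes the object described by a [phantom_spec()] into a noiseless
#' actin channel and returns it together with exact ground truth. The actin
#' channel is `background_intensity` everywhere, `interior_intensity` inside
#' the lumen, `wall_intensity` on a 1-2 px shell just outside the lumen
#' boundary, and `stripe_intensity` on the bulkhead plates. Bulkhead plates
#' are one-pixel-thick transverse cuts occluding the outer `bulkhead_depth`
#' fraction of the cross-section, alternating the side they project from;
#' plate pixels are removed from the ground-truth lumen mask (they are
#' membrane, not lumen) but never disconnect it. Noise is *not* applied here;
#' see [add_noise()].
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [raster_image()] with channel `actin`) and
#'   `truth`: list with `mask` (logical lumen interior), `radius_field`
#'   (per-interior-pixel inscribed radius, um; the nominal caliber, exact for
#'   unbulkheaded tubes and cysts), `bulkhead_positions` (arc-length um),
#'   `centerline` (pixel-coordinate matrix along the main axis), `object_id`.
#' @examples
#' ph <- make_phantom(phantom_spec("tube", tube_radius = 1, tube_length = 10))
#' range(ph$truth$radius_field[ph$truth$mask])
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_fits(spec)
  nd <- length(spec$spacing)
  d <- spec$image_size
  sp <- spec$spacing
  ax <- lapply(seq_len(nd), function(a) axis_coords(d[a], sp[a]))
  centre <- vapply(seq_len(nd), function(a) d[a] * sp[a] / 2, 0)

  geom <- switch(spec$shape_kind,
    cyst = cyst_geometry(spec, ax, centre),
    tube = tube_geometry(spec, ax, centre, branches = FALSE),
    branched_tube = tube_geometry(spec, ax, centre, branches = TRUE)
  )
  capsule <- geom$capsule # full lumen incl. space occupied by plates
  plates <- geom$plates   # logical, bulkhead plate pixels (subset of capsule)
  mask <- capsule & !plates

  # wall: 1-2 px shell of non-lumen pixels adjacent to the capsule boundary
  inv <- array(as.integer(!capsule), dim = d)
  dist2_to_capsule <- array(.edt_sq_cpp(inv, d, rep(1, nd)), dim = d)
  shell <- !capsule & dist2_to_capsule <= 1.5^2

  actin <- array(spec$background_intensity, dim = d)
  actin[capsule] <- spec$interior_intensity
  actin[plates] <- spec$stripe_intensity
  actin[shell] <- spec$wall_intensity

  radius_field <- array(0, dim = d)
  radius_field[mask] <- geom$nominal_radius

  img <- raster_image(list(actin = actin), spacing = sp,
                      provenance = sprintf("phantom:%s seed=%d",
                                           spec$shape_kind, spec$seed))
  truth <- list(mask = mask, radius_field = radius_field,
                bulkhead_positions = geom$bulkhead_positions,
                centerline = geom$centerline, object_id = 1L)
  list(image = img, truth = truth)
}

cyst_geometry <- function(spec, ax, centre) {
  d <- spec$image_size
  nd <- length(d)
  R2 <- spec$cyst_radius^2
  dist2 <- coord_dist2(ax, centre)
  capsule <- array(dist2 <= R2, dim = d)
  list(capsule = capsule, plates = array(FALSE, dim = d),
       nominal_radius = spec$cyst_radius,
       bulkhead_positions = numeric(0),
       centerline = matrix(numeric(0), ncol = nd))
}

# squared distance of every pixel centre to a point, accumulated per axis
coord_dist2 <- function(ax, pt) {
  nd <- length(ax)
  d <- vapply(ax, length, 0L)
  acc <- array(0, dim = d)
  for (a in seq_len(nd)) {
    da <- (ax[[a]] - pt[a])^2
    perm <- rep(1L, nd)
    perm[a] <- d[a]
    acc <- acc + array(rep(da, each = prod(d[seq_len(a - 1L)])), dim = d)
  }
  acc
}

tube_geometry <- function(spec, ax, centre, branches = FALSE) {
  d <- spec$image_size
  nd <- length(d)
  sp <- spec$spacing
  r <- spec$tube_radius
  L <- spec$tube_length
  x0 <- centre[2L] - L / 2
  x1 <- centre[2L] + L / 2

  # capsule distance for the main segment (axis 2 is the tube axis)
  X <- ax[[2L]]
  axdist <- pmax(pmax(x0 - X, X - x1), 0) # distance along axis beyond the segment
  # cross-axis squared distance (axes != 2)
  cross_axes <- setdiff(seq_len(nd), 2L)
  cross2 <- coord_dist2(ax[cross_axes], centre[cross_axes])
  # expand to full grid: dims ordered (axis1[, axis3]) for cross2
  seg2 <- expand_axis(axdist^2, axis = 2L, dims = d) +
    expand_cross(cross2, cross_axes, d)
  capsule <- array(seg2 <= r^2, dim = d)

  if (branches && spec$branch_count > 0L) {
    blen <- L / 3
    for (k in seq_len(spec$branch_count)) {
      t0 <- x0 + L * k / (spec$branch_count + 1)
      side <- if (k %% 2L == 1L) -1 else 1 # alternate up/down (axis 1)
      p0 <- centre
      p0[2L] <- t0
      p1 <- p0
      p1[2L] <- t0 + blen / sqrt(2)
      p1[1L] <- centre[1L] + side * blen / sqrt(2)
      capsule <- capsule | segment_capsule(ax, p0, p1, r, d)
    }
  }

  # bulkhead plates along the main axis
  plates <- array(FALSE, dim = d)
  positions <- numeric(0)
  if (spec$bulkhead_spacing > 0) {
    positions <- with_seed(spec$seed, bulkhead_arclengths(spec))
    u <- expand_axis_vals(ax[[1L]] - centre[1L], axis = 1L, dims = d)
    xg <- expand_axis_vals(ax[[2L]], axis = 2L, dims = d)
    half_th <- 0.6 * sp[2L] # one-pixel-thick plate
    u0 <- r * (1 - 2 * spec$bulkhead_depth)
    for (i in seq_along(positions)) {
      s <- positions[i]
      slab <- abs(xg - (x0 + s)) <= half_th
      occl <- if (i %% 2L == 1L) u >= u0 else u <= -u0
      plates <- plates | (slab & occl & capsule)
    }
  }

  # centerline pixel coordinates along the main axis
  jx <- which(X >= x0 & X <= x1)
  ic <- round(centre[1L] / sp[1L] + 0.5)
  cl <- cbind(rep(ic, length(jx)), jx)
  if (nd == 3L) cl <- cbind(cl, rep(round(centre[3L] / sp[3L] + 0.5), length(jx)))

  list(capsule = capsule, plates = plates, nominal_radius = r,
       bulkhead_positions = positions, centerline = cl)
}

bulkhead_arclengths <- function(spec) {
  L <- spec$tube_length
  bs <- spec$bulkhead_spacing
  out <- numeric(0)
  s <- bs
  if (spec$bulkhead_jitter > 0) {
    s <- bs * max(0.2, 1 + spec$bulkhead_jitter * rnorm(1))
  }
  while (s <= L - bs / 2) {
    out <- c(out, s)
    gap <- bs
    if (spec$bulkhead_jitter > 0) {
      gap <- bs * max(0.2, 1 + spec$bulkhead_jitter * rnorm(1))
    }
    s <- s + gap
  }
  out
}

# distance-to-segment capsule for an arbitrary segment (used for branches)
segment_capsule <- function(ax, p0, p1, r, d) {
  nd <- length(d)
  v <- p1 - p0
  vv <- sum(v^2)
  grids <- lapply(seq_len(nd), function(a) expand_axis_vals(ax[[a]], a, d))
  tpar <- array(0, dim = d)
  for (a in seq_len(nd)) tpar <- tpar + (grids[[a]] - p0[a]) * v[a]
  tpar <- pmin(pmax(tpar / vv, 0), 1)
  d2 <- array(0, dim = d)
  for (a in seq_len(nd)) d2 <- d2 + (grids[[a]] - (p0[a] + tpar * v[a]))^2
  array(d2 <= r^2, dim = d)
}

# broadcast a per-axis vector over the full grid
expand_axis_vals <- function(vals, axis, dims) {
  nd <- length(dims)
  before <- prod(dims[seq_len(axis - 1L)])
  after <- prod(dims[seq_len(nd)[-seq_len(axis)]])
  array(rep(rep(vals, each = before), times = after), dim = dims)
}

expand_axis <- function(vals, axis, dims) expand_axis_vals(vals, axis, dims)

# broadcast an array over the axes in `cross_axes` to the full grid
expand_cross <- function(arr, cross_axes, dims) {
  nd <- length(dims)
  if (length(cross_axes) == 1L) {
    return(expand_axis_vals(as.vector(arr), cross_axes, dims))
  }
  # cross_axes = c(1, 3) with tube axis 2: arr has dims (d1, d3)
  out <- array(0, dim = dims)
  out[] <- as.vector(aperm(
    array(rep(as.vector(arr), times = dims[2L]),
          dim = c(dims[1L], dims[3L], dims[2L])),
    c(1L, 3L, 2L)))
  out
}

#' Apply a Poisson-Gaussian camera noise model
#'
#' Intensities are Poisson-resampled (shot noise, `noise_poisson_scale`
#' photons per ADU) and Gaussian read noise of standard deviation
#' `noise_gaussian_sd` is added. With both parameters 0 the image is returned
#' unchanged. Deterministic under a fixed seed. Optionally the result is
#' digitized to the 16-bit ADU lattice (round and clip to [0, 65535]), as a
#' camera ADC would do and as [write_stack()] requires for exact round-trips.
#'
#' @param image a [raster_image()] with non-negative intensities.
#' @param spec a [phantom_spec()] carrying the noise parameters, or a list
#'   with elements `noise_gaussian_sd`, `noise_poisson_scale`.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param channels channels to perturb (default `"actin"`; binary marker
#'   channels are left untouched).
#' @param quantize digitize to integer ADU in [0, 65535] (default `FALSE`).
#' @return the noisy [raster_image()].
#' @export
add_noise <- function(image, spec, seed = spec$seed, channels = "actin",
                      quantize = FALSE) {
  stopifnot(inherits(image, "raster_image"))
  gsd <- spec$noise_gaussian_sd %||% 0
  psc <- spec$noise_poisson_scale %||% 0
  if (gsd < 0 || psc < 0) stop("noise parameters must be non-negative (parameter error)")
  with_seed(seed, {
    for (ch in intersect(channels, names(image$channels))) {
      x <- image$channels[[ch]]
      if (any(x < 0)) stop("intensities must be non-negative")
      if (psc > 0) {
        x[] <- rpois(length(x), as.vector(x) * psc) / psc
      }
      if (gsd > 0) {
        x[] <- x + rnorm(length(x), sd = gsd)
      }
      if (quantize) {
        x[] <- pmin(pmax(round(x), 0), 65535)
      }
      image$channels[[ch]] <- x
    }
  })
  append_log(image, sprintf("noise: gaussian_sd=%g poisson_scale=%g", gsd, psc))
}

#' Binary rescue-marker (GFP) channel for a set of phantom objects
#'
#' Marks a randomly chosen `round(n * gfp_fraction)` of the objects as
#' rescue-positive: their lumen masks, dilated by one pixel, are set to 1.
#' Emulates images where only cells expressing a rescue construct carry the
#' marker, feeding the 70%-overlap rescue filter.
#'
#' @param truth_list list of phantom truths (each with a `mask`), all on one
#'   grid.
#' @param gfp_fraction fraction of objects to mark, in `[0, 1]`.
#' @param seed RNG seed for the choice of objects.
#' @return list with `channel` (0/1 array) and `positive` (logical per
#'   object).
#' @export
make_gfp_channel <- function(truth_list, gfp_fraction, seed = 1L) {
  if (gfp_fraction < 0 || gfp_fraction > 1) {
    stop("`gfp_fraction` must be in [0, 1]")
  }
  stopifnot(length(truth_list) >= 1L)
  d <- dim(truth_list[[1L]]$mask)
  n <- length(truth_list)
  npos <- round(n * gfp_fraction)
  chosen <- with_seed(seed, sample.int(n, npos))
  channel <- array(0, dim = d)
  for (k in chosen) {
    m <- truth_list[[k]]$mask
    inv <- array(as.integer(!m), dim = d)
    dist2 <- .edt_sq_cpp(inv, d, rep(1, length(d)))
    channel[m | (dist2 <= 1.5^2)] <- 1
  }
  list(channel = channel, positive = seq_len(n) %in% chosen)
}
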