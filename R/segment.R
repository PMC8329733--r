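#' Preprocess an actin channel for lumen segmentation
#'
#' Gaussian smoothing (sigma given in micrometres, converted to pixels via
#' the in-plane spacing) followed by a background correction implemented as a
#' grayscale white top-hat (image minus its morphological opening) with a
#' square structuring element of half-width `ball_radius` micrometres — a
#' rolling-ball-style flat-field stand-in computed with O(n) sliding
#' min/max filters, so the radius can safely exceed the largest lumen (it
#' must: structures larger than the element are treated as background). A
#' constant image therefore maps to all zeros, and adding a constant offset
#' to the input does not change the output. Intensities are clipped at 0.
#' For 3D stacks both operators are applied plane by plane.
#'
#' @param image a [raster_image()].
#' @param channel channel to process (default `"actin"`).
#' @param smooth_sigma Gaussian sigma in micrometres; 0 disables smoothing.
#' @param ball_radius disk radius in micrometres for background subtraction;
#'   `NULL` or `Inf` disables it.
#' @return the processed [raster_image()] (other channels untouched), with
#'   the processing log appended.
#' @export
preprocess <- function(image, channel = "actin", smooth_sigma = 0.2,
                       ball_radius = 20) {
  stopifnot(inherits(image, "raster_image"))
  if (smooth_sigma < 0) stop("`smooth_sigma` must be non-negative")
  x <- get_channel(image, channel)
  d <- dim(x)
  sp_inplane <- mean(image$spacing[1:2])
  sigma_px <- smooth_sigma / sp_inplane
  do_ball <- !is.null(ball_radius) && is.finite(ball_radius)
  if (do_ball && ball_radius <= 0) stop("`ball_radius` must be positive")
  half <- if (do_ball) max(1L, as.integer(ceiling(ball_radius / sp_inplane))) else 0L
  plane_op <- function(m) {
    if (sigma_px > 0) m <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma_px))
    if (do_ball) {
      # opening = dilate(erode); replicate-pad so the border sees no
      # artificial background
      dm <- dim(m)
      mp <- pad_replicate(m, half)
      er <- .sliding_extremum_cpp(mp, dim(mp), half, TRUE)
      op <- .sliding_extremum_cpp(er, dim(mp), half, FALSE)
      m <- m - unpad(array(op, dim = dim(mp)), half, dm)
    }
    m
  }
  if (length(d) == 2L) {
    x <- plane_op(x)
  } else {
    for (k in seq_len(d[3L])) x[, , k] <- plane_op(x[, , k])
  }
  x[x < 0] <- 0
  image$channels[[channel]] <- array(x, dim = d)
  append_log(image, sprintf("preprocess: sigma=%g um, ball=%s um", smooth_sigma,
                            if (do_ball) format(ball_radius) else "off"))
}

#' Segment lumen objects from the actin channel
#'
#' Thresholds the (ideally preprocessed) actin channel, applies morphological
#' closing with a disk/ball of `closing_radius` micrometres (computed via the
#' exact Euclidean distance transform, so it honours anisotropic spacing),
#' fills interior holes, labels connected components (8-connectivity in 2D,
#' 26 in 3D), and removes objects smaller than `min_size` (um^2 in 2D, um^3
#' in 3D). Deterministic; an empty image yields an empty label map.
#'
#' @param image a [raster_image()].
#' @param channel channel holding the actin/membrane signal.
#' @param method `"otsu"` (Otsu's threshold on the intensity histogram) or
#'   `"fixed"` (absolute `threshold` in intensity units).
#' @param threshold intensity threshold, required for `method = "fixed"`.
#' @param min_size minimum object measure in um^2 (2D) / um^3 (3D).
#' @param closing_radius closing radius in micrometres (0 disables).
#' @return a [label_map()].
#' @export
segment_lumina <- function(image, channel = "actin",
                           method = c("otsu", "fixed"), threshold = NULL,
                           min_size = 1, closing_radius = 0.3) {
  stopifnot(inherits(image, "raster_image"))
  method <- match.arg(method)
  x <- get_channel(image, channel)
  d <- dim(x)
  sp <- image$spacing
  rng <- range(x)
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method requires `threshold`")
    th <- threshold
  } else {
    if (rng[2L] <= rng[1L]) {
      # flat image: nothing to segment
      return(label_map(array(0L, dim = d), sp))
    }
    x01 <- (x - rng[1L]) / (rng[2L] - rng[1L])
    th01 <- EBImage::otsu(EBImage::Image(matrix(as.vector(x01), ncol = 1L)),
                          range = c(0, 1), levels = 256L)
    th <- rng[1L] + th01 * (rng[2L] - rng[1L])
  }
  mask <- array(x > th, dim = d)
  if (closing_radius > 0 && any(mask)) {
    mask <- binary_closing(mask, sp, closing_radius)
  }
  if (any(mask)) {
    mask <- array(.fill_holes_cpp(as_int_mask(mask), d) != 0L, dim = d)
  }
  lab <- array(.label_components_cpp(as_int_mask(mask), d), dim = d)
  lab <- drop_small_objects(lab, sp, min_size)
  label_map(lab, sp)
}

# closing = erosion-after-dilation with a Euclidean ball of radius r (um)
binary_closing <- function(mask, spacing, radius) {
  d <- dim(mask)
  r2 <- radius^2
  # dilation: pixels within r of the foreground
  dist2_to_fg <- .edt_sq_cpp(array(as.integer(!mask), dim = d), d, spacing)
  dil <- array(mask | dist2_to_fg <= r2, dim = d)
  # erosion: pixels farther than r from the (dilated) background
  dist2_to_bg <- .edt_sq_cpp(as_int_mask(dil), d, spacing)
  array(dil & dist2_to_bg > r2, dim = d)
}

drop_small_objects <- function(lab, spacing, min_size) {
  if (min_size <= 0 || !any(lab > 0L)) return(relabel_consecutive(lab))
  px <- pixel_measure(spacing)
  tab <- tabulate(lab[lab > 0L])
  small <- which(tab * px < min_size)
  if (length(small)) lab[lab %in% small] <- 0L
  relabel_consecutive(lab)
}

#' Restrict a segmentation by an externally supplied correction mask
#'
#' Replaces the interactive verification step of a manual workflow: label
#' pixels outside `correction_mask` are dropped, objects split by the
#' restriction are relabelled as separate components, and objects falling
#' below `min_size` are removed.
#'
#' @param labels a [label_map()].
#' @param correction_mask logical/0-1 array on the same grid.
#' @param min_size minimum surviving object measure (um^2 / um^3).
#' @return the corrected [label_map()].
#' @export
apply_mask_correction <- function(labels, correction_mask, min_size = 1) {
  stopifnot(inherits(labels, "label_map"))
  check_same_grid(labels, correction_mask)
  d <- dim(labels$labels)
  kept <- array(labels$labels > 0L & (correction_mask != 0), dim = d)
  lab <- array(.label_components_cpp(as_int_mask(kept), d), dim = d)
  lab <- drop_small_objects(lab, labels$spacing, min_size)
  label_map(lab, labels$spacing)
}

#' GFP-overlap rescue filter
#'
#' Keeps only lumen objects whose pixel overlap with the positive part of a
#' marker channel is at least `min_overlap` (inclusive boundary: an object
#' with overlap exactly 0.70 is kept under the default). Survivors are
#' relabelled consecutively.
#'
#' @param labels a [label_map()].
#' @param gfp binary (0/1) marker raster on the same grid.
#' @param min_overlap minimum overlap fraction in `[0, 1]`; default 0.7.
#' @return a [label_map()] of the surviving objects, with attribute
#'   `"overlap"` recording each original object's overlap fraction.
#' @export
gfp_overlap_filter <- function(labels, gfp, min_overlap = 0.7) {
  stopifnot(inherits(labels, "label_map"))
  check_same_grid(labels, gfp)
  if (min_overlap < 0 || min_overlap > 1) stop("`min_overlap` must be in [0, 1]")
  lab <- labels$labels
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) return(labels)
  gfp_pos <- gfp != 0
  ov <- vapply(ids, function(id) {
    sel <- lab == id
    sum(gfp_pos[sel]) / sum(sel)
  }, 0)
  drop <- ids[ov < min_overlap]
  if (length(drop)) lab[lab %in% drop] <- 0L
  out <- label_map(relabel_consecutive(lab), labels$spacing)
  attr(out, "overlap") <- setNames(ov, ids)
  out
}

#' Per-object region statistics
#'
#' One row per object: pixel count `A`, the volume-proportional histogram
#' weight `w = A^(3/2)` (an area-to-volume scaling for objects measured in a
#' 2D section), centroid and bounding box in pixel coordinates, and the
#' overlap fraction with a marker channel (0 when absent).
#'
#' @param labels a [label_map()].
#' @param gfp optional binary marker raster on the same grid.
#' @return a `data.frame` with columns `label`, `A`, `w`,
#'   `centroid_1..centroid_k`, `bbox_min_1..`, `bbox_max_1..`, `gfp_overlap`.
#' @export
region_stats <- function(labels, gfp = NULL) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  d <- dim(lab)
  nd <- length(d)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  cols <- c("label", "A", "w",
            paste0("centroid_", seq_len(nd)),
            paste0("bbox_min_", seq_len(nd)), paste0("bbox_max_", seq_len(nd)),
            "gfp_overlap")
  if (length(ids) == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  if (!is.null(gfp)) check_same_grid(labels, gfp)
  rows <- lapply(ids, function(id) {
    sel <- which(lab == id)
    co <- arrayInd(sel, d)
    a <- length(sel)
    ovl <- if (is.null(gfp)) 0 else sum(gfp[sel] != 0) / a
    c(id, a, a^1.5, colMeans(co), apply(co, 2L, min), apply(co, 2L, max), ovl)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- cols
  out
}
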