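# TIFF + sidecar I/O. Intensity rasters are stored as 16-bit pages (value /
# 65535); label maps as 16-bit integers; float maps (radius, thickness) as
# 32-bit pages divided by a recorded scale. Spacing, channel names and scale
# live in a JSON sidecar (<path>.json) because the tiff package cannot write
# resolution tags.

#' Write a multi-channel raster to a multi-page TIFF (+ JSON sidecar)
#'
#' Channels become pages. Intensities must lie in `[0, 65535]` ADU and are
#' stored as 16-bit samples, so integer-valued ADU data round-trips exactly.
#'
#' @param image a [raster_image()] (2D channels).
#' @param path output file path (`.tif`).
#' @return invisibly, `path`.
#' @export
write_stack <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  pages <- lapply(image$channels, function(ch) {
    if (length(dim(ch)) != 2L) stop("write_stack stores 2D channels as pages")
    if (any(ch < 0 | ch > 65535)) stop("intensities must be in [0, 65535] ADU")
    ch / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(spacing = image$spacing, channels = names(image$channels),
                  scale = 65535, kind = "intensity",
                  provenance = image$provenance)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multi-page TIFF stack into a raster image
#'
#' Pages are mapped to channels by the sidecar (or `channel_names`);
#' `spacing` from the sidecar can be overridden.
#'
#' @param path TIFF path.
#' @param channel_names optional channel names (overrides sidecar).
#' @param spacing optional spacing override (um per axis).
#' @return a [raster_image()].
#' @export
read_stack <- function(path, channel_names = NULL, spacing = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s' (format error)", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop(sprintf(
                      "cannot read '%s' (format error): %s", path,
                      conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  scale <- meta$scale %||% 65535
  nm <- channel_names %||% meta$channels %||% paste0("ch", seq_along(pages))
  if (length(nm) != length(pages)) {
    stop(sprintf("'%s' has %d page(s) but %d channel name(s) (format error)",
                 path, length(pages), length(nm)))
  }
  sp <- spacing %||% meta$spacing
  if (is.null(sp)) stop(sprintf("no spacing for '%s': supply `spacing`", path))
  chans <- lapply(pages, function(p) {
    m <- p * scale
    array(m, dim = dim(p))
  })
  names(chans) <- nm
  raster_image(chans, spacing = as.double(sp),
               provenance = sprintf("read_stack:%s", basename(path)))
}

#' Write a label map as a 16-bit TIFF (+ sidecar)
#' @param labels a [label_map()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  if (max(labels$labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(spacing = labels$spacing, scale = 65535,
                            kind = "labels"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label map written by [write_labels()]
#' @param path TIFF path.
#' @param spacing optional spacing override.
#' @return a [label_map()].
#' @export
read_labels <- function(path, spacing = NULL) {
  p <- tiff::readTIFF(path)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  sp <- spacing %||% meta$spacing
  if (is.null(sp)) stop(sprintf("no spacing for '%s': supply `spacing`", path))
  lab <- array(as.integer(round(p * (meta$scale %||% 65535))), dim = dim(p))
  label_map(lab, as.double(sp))
}

#' Write a float map (radius/thickness) as a 32-bit TIFF (+ sidecar)
#'
#' Values are divided by `scale` (default: the map's maximum, recorded in the
#' sidecar) to fit the writer's `[0, 1]` range; 32-bit float storage limits
#' the round-trip to single precision.
#'
#' @param values numeric 2D array (um).
#' @param spacing um per axis.
#' @param path output path.
#' @param scale divisor; default `max(values)` (or 1 for an all-zero map).
#' @return invisibly, `path`.
#' @export
write_float_map <- function(values, spacing, path, scale = NULL) {
  scale <- scale %||% max(values, 1e-12)
  tiff::writeTIFF(values / scale, path, bits.per.sample = 32L,
                  compression = "none")
  jsonlite::write_json(list(spacing = spacing, scale = scale, kind = "float"),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the analysis with their defaults: the 70%
#' GFP-overlap rescue threshold, the 10 um radius cap used for 3D in vivo
#' data (uncapped in 2D by default), 0.25 um bins over 0-10 um, and the 6 um
#' (in vitro) / 2 um (in vivo) reporting thresholds. Round-trips losslessly
#' through YAML.
#'
#' @param ... overrides of the defaults (nested lists are merged).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    channel = "actin",
    gfp_channel = "gfp",
    preprocess = list(smooth_sigma = 0.2, ball_radius = 20),
    segment = list(method = "otsu", threshold = NULL, min_size = 1,
                   closing_radius = 0.3),
    gfp = list(enabled = FALSE, min_overlap = 0.7),
    thickness = list(max_radius = NULL),
    bins = list(max_radius = 10, width = 0.25),
    thresholds = 6,
    fraction_mode = "mass",
    pattern = list(enabled = FALSE, min_prominence = 0.2, min_elongation = 2),
    spacing = NULL
  )
  over <- list(...)
  cfg <- modifyList(base, over, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
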