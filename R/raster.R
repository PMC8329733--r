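#' Multi-channel intensity raster with physical spacing
#'
#' The pipeline's image container: a 2D matrix or 3D array per channel, a
#' per-axis physical pixel spacing in micrometres, and a processing log.
#' Channels are stored as a named list of arrays sharing one grid.
#'
#' @param channels named list of numeric arrays (all with identical `dim`);
#'   typical names are `"actin"` and `"gfp"`.
#' @param spacing numeric vector, micrometres per pixel along each axis (same
#'   length as `dim` of the channel arrays). Must be strictly positive.
#' @param provenance character vector; free-text processing log.
#' @return an object of class `raster_image`.
#' @examples
#' img <- raster_image(list(actin = matrix(0, 8, 8)), spacing = c(0.1, 0.1))
#' img
#' @export
raster_image <- function(channels, spacing, provenance = character()) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)) ||
      any(names(channels) == "") || anyDuplicated(names(channels))) {
    stop("`channels` must be a non-empty uniquely named list of arrays")
  }
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  if (length(unique(dims)) != 1L) stop("all channels must share one grid")
  d <- dims[[1L]]
  if (length(d) < 2L || length(d) > 3L) stop("rasters must be 2D or 3D")
  if (!is.numeric(spacing) || length(spacing) != length(d) || any(spacing <= 0)) {
    stop("`spacing` must be positive, one value per axis (unit error)")
  }
  structure(
    list(channels = channels, spacing = as.double(spacing),
         provenance = as.character(provenance)),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<raster_image> %s px, spacing %s um, channels: %s\n",
              paste(d, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  if (length(x$provenance)) {
    cat("  log:", paste(x$provenance, collapse = " | "), "\n")
  }
  invisible(x)
}

#' Extract a channel from a raster image
#'
#' @param image a [raster_image()].
#' @param name channel name.
#' @return the channel array.
#' @export
get_channel <- function(image, name) {
  stopifnot(inherits(image, "raster_image"))
  if (!name %in% names(image$channels)) {
    stop(sprintf("channel '%s' not present (channel error)", name))
  }
  image$channels[[name]]
}

append_log <- function(image, msg) {
  image$provenance <- c(image$provenance, msg)
  image
}

#' Integer-labelled segmentation on a raster grid
#'
#' Background is 0; object labels are consecutive positive integers assigned
#' in raster-scan order of each object's first pixel.
#'
#' @param labels integer array (2D/3D), 0 = background.
#' @param spacing micrometres per pixel along each axis.
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, spacing) {
  d <- dim(labels)
  if (is.null(d) || length(d) < 2L || length(d) > 3L) stop("labels must be 2D or 3D")
  if (!is.numeric(spacing) || length(spacing) != length(d) || any(spacing <= 0)) {
    stop("`spacing` must be positive, one value per axis (unit error)")
  }
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop("labels must be non-negative")
  structure(list(labels = labels, spacing = as.double(spacing)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s px, %d object(s)\n",
              paste(dim(x$labels), collapse = "x"), n_objects(x)))
  invisible(x)
}

#' Number of objects in a label map
#' @param labels a [label_map()].
#' @return integer count of distinct positive labels.
#' @export
n_objects <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  length(setdiff(unique(as.vector(labels$labels)), 0L))
}

# Relabel positive regions consecutively, preserving raster-scan order of
# first occurrence. Keeps per-pixel membership intact (label conservation).
relabel_consecutive <- function(arr) {
  v <- as.vector(arr)
  ids <- unique(v[v > 0L])
  if (length(ids) == 0L) return(arr)
  out <- arr
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out[arr > 0L] <- lut[v[v > 0L]]
  out
}

# grid compatibility check used by operations combining rasters
check_same_grid <- function(a, b) {
  da <- if (is.list(a)) dim(a$labels %||% a$channels[[1L]]) else dim(a)
  db <- if (is.list(b)) dim(b$labels %||% b$channels[[1L]]) else dim(b)
  if (!identical(da, db)) stop("rasters are on different grids (shape error)")
  invisible(TRUE)
}
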