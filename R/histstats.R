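#' Radius histogram bin edges
#'
#' Uniform bins over `[0, max_radius]`; default width 0.25 um over 0-10 um.
#' Bins are half-open `[lo, hi)`; when `capped = TRUE` downstream, values at
#' or above the last edge are absorbed into the top bin.
#'
#' @param max_radius upper edge in micrometres.
#' @param width bin width in micrometres.
#' @return numeric vector of edges.
#' @export
radius_bins <- function(max_radius = 10, width = 0.25) {
  stopifnot_scalar_pos(max_radius, "max_radius")
  stopifnot_scalar_pos(width, "width")
  seq(0, max_radius, by = width)
}

new_radius_histogram <- function(density, bin_edges, level, n_contributors,
                                 sem = NULL, extra = list()) {
  structure(
    c(list(density = density, bin_edges = bin_edges, level = level,
           n_contributors = n_contributors, sem = sem), extra),
    class = "radius_histogram"
  )
}

#' @export
print.radius_histogram <- function(x, ...) {
  cat(sprintf("<radius_histogram> level=%s, %d bins over [%g, %g] um, n=%d\n",
              x$level, length(x$density), min(x$bin_edges), max(x$bin_edges),
              x$n_contributors))
  cat(sprintf("  mass=%.6f, mean radius=%.3f um%s\n", sum(x$density),
              sum(bin_mid(x$bin_edges) * x$density),
              if (!is.null(x$sem)) sprintf(", max per-bin SEM=%.4f", max(x$sem))
              else ""))
  invisible(x)
}

bin_mid <- function(edges) (edges[-1L] + edges[-length(edges)]) / 2

# histogram of radius values over half-open bins [lo, hi); values >= last
# edge land in the top bin (cap semantics)
bin_counts <- function(values, edges) {
  idx <- findInterval(values, edges, left.open = FALSE)
  idx[idx >= length(edges)] <- length(edges) - 1L # absorb capped values
  idx[idx < 1L] <- 1L
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Normalized per-object radius histogram
#'
#' Histogram of one object's per-pixel local radius values, normalized to
#' unit mass.
#'
#' @param radius per-pixel radius array (from [radius_map()]).
#' @param labels a [label_map()] on the same grid.
#' @param object_id positive object label.
#' @param bin_edges uniform bin edges (see [radius_bins()]).
#' @return a `radius_histogram` at level `"object"` with the pixel count `A`
#'   attached.
#' @export
object_histogram <- function(radius, labels, object_id,
                             bin_edges = radius_bins()) {
  stopifnot(inherits(labels, "label_map"))
  check_same_grid(labels, radius)
  sel <- labels$labels == object_id
  if (!any(sel)) stop(sprintf("object %s not present (lookup error)", object_id))
  vals <- radius[sel]
  cnt <- bin_counts(vals, bin_edges)
  new_radius_histogram(cnt / sum(cnt), bin_edges, "object", 1L,
                       extra = list(A = sum(sel), object_id = object_id))
}

#' Volume-proportional object weight
#'
#' The weight applied to each object's normalized histogram before per-image
#' summation: `w = A^(3/2)` where `A` is the object's pixel count, an
#' area-to-volume scaling proportional to the object's estimated volume.
#'
#' @param A integer pixel count, `A >= 1`.
#' @return `A^(3/2)`.
#' @examples
#' object_weight(4)  # 8
#' object_weight(16) # 64
#' @export
object_weight <- function(A) {
  if (any(A < 1) || any(A != round(A))) {
    stop("`A` must be a positive integer pixel count (domain error)")
  }
  A^1.5
}

#' Weighted per-image aggregation of object histograms
#'
#' Sums the objects' normalized histograms with weights `w_i = A_i^(3/2)` and
#' renormalizes to unit mass, discarding differences in the total amount of
#' apical membrane between images.
#'
#' @param object_histograms list of `radius_histogram`s at level `"object"`
#'   sharing one set of bin edges.
#' @param weights numeric weights, one per object; by default `A^(3/2)` from
#'   each histogram's pixel count.
#' @return a `radius_histogram` at level `"image"`, or an empty-image
#'   sentinel (`NULL` with a message) when there are no objects.
#' @export
aggregate_image <- function(object_histograms,
                            weights = vapply(object_histograms,
                                             function(h) object_weight(h$A), 0)) {
  if (length(object_histograms) == 0L) {
    message("empty image: no objects to aggregate (excluded from averaging)")
    return(NULL)
  }
  edges <- object_histograms[[1L]]$bin_edges
  for (h in object_histograms) {
    if (!isTRUE(all.equal(h$bin_edges, edges))) {
      stop("object histograms must share bin edges")
    }
  }
  dens <- vapply(object_histograms, function(h) h$density,
                 numeric(length(edges) - 1L))
  dens <- if (is.null(dim(dens))) matrix(dens, ncol = 1L) else dens
  num <- as.vector(dens %*% weights)
  new_radius_histogram(num / sum(weights), edges, "image",
                       length(object_histograms))
}

#' Two-level replicate averaging of image histograms
#'
#' Image histograms are first averaged (unweighted) within each experiment,
#' then the experiment means are averaged into the study histogram; the
#' per-bin SEM is the sample standard deviation across experiments divided by
#' `sqrt(n)`. Because means of unit-mass histograms keep unit mass, every
#' level sums to 1. With a single experiment the SEM is omitted with a
#' warning. Empty images (`NULL`) are excluded.
#'
#' @param image_histograms list of level-`"image"` `radius_histogram`s.
#' @param experiment vector (same length) assigning each image to an
#'   experiment.
#' @return a `radius_histogram` at level `"study"` with `sem` per bin and the
#'   per-experiment histograms in `$experiments` (a named list of
#'   level-`"experiment"` histograms).
#' @export
average_histograms <- function(image_histograms, experiment) {
  stopifnot(length(image_histograms) == length(experiment))
  keep <- !vapply(image_histograms, is.null, TRUE)
  image_histograms <- image_histograms[keep]
  experiment <- experiment[keep]
  if (length(image_histograms) == 0L) stop("no non-empty images to average")
  edges <- image_histograms[[1L]]$bin_edges
  nb <- length(edges) - 1L
  exps <- unique(experiment)
  exp_hists <- lapply(exps, function(e) {
    dens <- vapply(image_histograms[experiment == e], function(h) h$density,
                   numeric(nb))
    dens <- if (is.null(dim(dens))) matrix(dens, ncol = 1L) else dens
    new_radius_histogram(rowMeans(dens), edges, "experiment", ncol(dens))
  })
  names(exp_hists) <- as.character(exps)
  emat <- vapply(exp_hists, function(h) h$density, numeric(nb))
  emat <- if (is.null(dim(emat))) matrix(emat, ncol = 1L) else emat
  n <- ncol(emat)
  study <- rowMeans(emat)
  sem <- NULL
  if (n >= 2L) {
    sem <- apply(emat, 1L, sd) / sqrt(n)
  } else {
    warning("single experiment: per-bin SEM omitted")
  }
  new_radius_histogram(study, edges, "study", n, sem = sem,
                       extra = list(experiments = exp_hists))
}

#' Fraction of lumen mass (or objects) above a radius threshold
#'
#' Mass mode (default): for each experiment, 100 times the summed histogram
#' mass in bins whose lower edge is at or above the threshold — the
#' "percentage of lumina above r um" readout of a weighted radius histogram.
#' Object mode: 100 times the fraction of objects whose maximum local radius
#' exceeds the threshold. The result is reported per experiment with mean and
#' SEM (sample SD / sqrt(n)) across experiments.
#'
#' @param x for `mode = "mass"`, a level-`"study"` `radius_histogram` from
#'   [average_histograms()] (its `$experiments` are used); for
#'   `mode = "object"`, a `data.frame` with columns `experiment` and
#'   `max_radius` (one row per object).
#' @param threshold radius threshold in micrometres. For mass mode it is
#'   realigned to the nearest bin edge (with a warning if not aligned).
#' @param mode `"mass"` or `"object"`.
#' @return an object of class `threshold_stat`: list with `threshold`,
#'   `mode`, `per_experiment` (%), `mean`, `sem`.
#' @export
fraction_above <- function(x, threshold, mode = c("mass", "object")) {
  mode <- match.arg(mode)
  if (mode == "mass") {
    stopifnot(inherits(x, "radius_histogram"), x$level == "study")
    edges <- x$bin_edges
    if (threshold < min(edges) || threshold > max(edges)) {
      stop("threshold outside the histogram bin range")
    }
    near <- edges[which.min(abs(edges - threshold))]
    if (abs(near - threshold) > 1e-9) {
      warning(sprintf("threshold %g um realigned to bin edge %g um",
                      threshold, near))
      threshold <- near
    }
    lower <- edges[-length(edges)]
    sel <- lower >= threshold - 1e-12
    per <- vapply(x$experiments, function(h) 100 * sum(h$density[sel]), 0)
  } else {
    stopifnot(is.data.frame(x), all(c("experiment", "max_radius") %in% names(x)))
    per <- vapply(split(x, x$experiment),
                  function(df) 100 * mean(df$max_radius > threshold), 0)
  }
  n <- length(per)
  structure(
    list(threshold = threshold, mode = mode, per_experiment = per,
         mean = mean(per), sem = if (n >= 2L) sd(per) / sqrt(n) else NA_real_),
    class = "threshold_stat"
  )
}

#' @export
print.threshold_stat <- function(x, ...) {
  cat(sprintf("Percentage of lumina > %g um (%s mode): %.2f%% +/- %.2f%% (n = %d)\n",
              x$threshold, x$mode, x$mean, x$sem, length(x$per_experiment)))
  invisible(x)
}

#' Plot a study-level radius histogram with SEM error bars
#'
#' @param x a level-`"study"` `radius_histogram`.
#' @param y ignored.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.radius_histogram <- function(x, y, ...) {
  mids <- bin_mid(x$bin_edges)
  plot(mids, x$density, type = "s", xlab = "local lumen radius (um)",
       ylab = "weighted frequency", ...)
  if (!is.null(x$sem)) {
    segments(mids, x$density - x$sem, mids, x$density + x$sem)
  }
  invisible(x)
}
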