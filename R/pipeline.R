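#' Run the full lumen morphometry pipeline on a manifest of images
#'
#' For every image: read, preprocess, segment, optionally apply the
#' GFP-overlap rescue filter, compute the local thickness and radius maps,
#' build weighted per-image radius histograms; then, per condition, average
#' over images and experiments (SEM per bin) and compute the
#' fraction-above-threshold statistics in both mass and object mode. All
#' intermediate rasters and final tables are written under `out_dir`;
#' re-running on unchanged inputs reproduces byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @param manifest `data.frame` with columns `image_id`, `path`,
#'   `experiment`, `condition` (optional: `mask_path` for a correction mask
#'   restricting the segmentation, `spacing` override).
#' @param out_dir output directory.
#' @return invisibly, a result bundle: list with `histograms` (per condition,
#'   level-`"study"` [average_histograms()] results), `thresholds`
#'   (data.frame), `regions` (per-object table), `pattern` (data.frame or
#'   `NULL`), `files` (paths written).
#' @export
run_pipeline <- function(config, manifest, out_dir) {
  stopifnot(inherits(config, "pipeline_config"), is.data.frame(manifest))
  need <- c("image_id", "path", "experiment", "condition")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns image_id, path, experiment, condition")
  }
  missing_files <- manifest$path[!file.exists(manifest$path)]
  if (length(missing_files)) {
    stop(sprintf("manifest file missing: %s", missing_files[1L]))
  }
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "radius"), recursive = TRUE, showWarnings = FALSE)

  edges <- radius_bins(config$bins$max_radius, config$bins$width)
  log_lines <- c("lumenmorph pipeline run",
                 paste0("images: ", nrow(manifest)))
  per_image <- vector("list", nrow(manifest))

  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    stage <- "read"
    result <- tryCatch({
      img <- read_stack(row$path,
                        spacing = if ("spacing" %in% names(row) &&
                                      !is.na(row$spacing)) {
                          rep(row$spacing, 2L)
                        } else NULL)
      stage <- "preprocess"
      img <- preprocess(img, channel = config$channel,
                        smooth_sigma = config$preprocess$smooth_sigma,
                        ball_radius = config$preprocess$ball_radius)
      stage <- "segment"
      labels <- segment_lumina(img, channel = config$channel,
                               method = config$segment$method,
                               threshold = config$segment$threshold,
                               min_size = config$segment$min_size,
                               closing_radius = config$segment$closing_radius)
      if ("mask_path" %in% names(row) && !is.na(row$mask_path) &&
          nzchar(row$mask_path) && file.exists(row$mask_path) &&
          isTRUE(config$use_correction_mask)) {
        stage <- "mask_correction"
        cm <- read_labels(row$mask_path, spacing = labels$spacing)
        labels <- apply_mask_correction(labels, cm$labels > 0L,
                                        min_size = config$segment$min_size)
      }
      gfp_raster <- NULL
      if (isTRUE(config$gfp$enabled)) {
        stage <- "gfp_filter"
        gfp_raster <- get_channel(img, config$gfp_channel)
        labels <- gfp_overlap_filter(labels, gfp_raster,
                                     min_overlap = config$gfp$min_overlap)
      }
      stage <- "thickness"
      d <- dim(labels$labels)
      tmap <- if (any(labels$labels > 0L)) {
        local_thickness(labels$labels > 0L, labels$spacing,
                        max_radius = config$thickness$max_radius)
      } else {
        structure(list(values = array(0, dim = d), spacing = labels$spacing,
                       capped = FALSE, max_radius = NULL),
                  class = "thickness_map")
      }
      rmap <- radius_map(tmap)
      stage <- "histograms"
      regions <- region_stats(labels, gfp = gfp_raster)
      ids <- regions$label
      ohists <- lapply(ids, function(id) {
        object_histogram(rmap, labels, id, bin_edges = edges)
      })
      regions$max_radius <- vapply(ids, function(id) {
        max(rmap[labels$labels == id])
      }, 0)
      regions$mean_radius <- vapply(ids, function(id) {
        mean(rmap[labels$labels == id])
      }, 0)
      ih <- aggregate_image(ohists)
      stage <- "write"
      write_labels(labels, file.path(out_dir, "labels",
                                     paste0(row$image_id, "_labels.tif")))
      write_float_map(rmap, labels$spacing,
                      file.path(out_dir, "radius",
                                paste0(row$image_id, "_radius.tif")),
                      scale = config$bins$max_radius)
      pat <- NULL
      if (isTRUE(config$pattern$enabled) && length(ids)) {
        stage <- "pattern"
        pat <- do.call(rbind, lapply(ids, function(id) {
          pr <- extract_axis_profile(labels, img, rmap, id,
                                     min_elongation = config$pattern$min_elongation)
          pe <- measure_periodicity(pr,
                                    min_prominence = config$pattern$min_prominence)
          data.frame(image_id = row$image_id, object_id = id,
                     has_stripes = pe$has_stripes,
                     dominant_spacing_um = pe$dominant_spacing,
                     spacing_over_diameter = pe$spacing_over_diameter,
                     prominence = pe$peak_prominence, status = pe$status,
                     stringsAsFactors = FALSE)
        }))
      }
      list(image_hist = ih, regions = regions, pattern = pat)
    }, error = function(e) {
      stop(sprintf("stage '%s' failed on image '%s': %s", stage, row$image_id,
                   conditionMessage(e)), call. = FALSE)
    })
    per_image[[k]] <- result
    log_lines <- c(log_lines,
                   sprintf("%s [%s/%s]: %d object(s)", row$image_id,
                           row$experiment, row$condition,
                           nrow(result$regions)))
  }

  # condition-level aggregation
  conditions <- unique(manifest$condition)
  hist_rows <- list()
  thr_rows <- list()
  study <- list()
  for (cond in conditions) {
    sel <- which(manifest$condition == cond)
    ih <- lapply(per_image[sel], `[[`, "image_hist")
    sh <- average_histograms(ih, manifest$experiment[sel])
    study[[cond]] <- sh
    lower <- sh$bin_edges[-length(sh$bin_edges)]
    upper <- sh$bin_edges[-1L]
    for (en in names(sh$experiments)) {
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        condition = cond, level = "experiment", experiment = en,
        bin_lo = lower, bin_hi = upper,
        density = sh$experiments[[en]]$density, sem = NA_real_,
        stringsAsFactors = FALSE)
    }
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      condition = cond, level = "study", experiment = "all",
      bin_lo = lower, bin_hi = upper, density = sh$density,
      sem = sh$sem %||% NA_real_, stringsAsFactors = FALSE)

    # per-object table for object-mode fractions
    obj <- do.call(rbind, lapply(sel, function(k) {
      r <- per_image[[k]]$regions
      if (nrow(r) == 0L) return(NULL)
      data.frame(experiment = manifest$experiment[k], max_radius = r$max_radius)
    }))
    for (th in config$thresholds) {
      fm <- fraction_above(sh, th, mode = "mass")
      thr_rows[[length(thr_rows) + 1L]] <- threshold_rows(cond, fm)
      if (!is.null(obj)) {
        fo <- fraction_above(obj, th, mode = "object")
        thr_rows[[length(thr_rows) + 1L]] <- threshold_rows(cond, fo)
      }
    }
  }

  regions_all <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(k) {
    r <- per_image[[k]]$regions
    if (nrow(r) == 0L) return(NULL)
    cbind(data.frame(image_id = manifest$image_id[k],
                     experiment = manifest$experiment[k],
                     condition = manifest$condition[k],
                     stringsAsFactors = FALSE), r)
  }))
  pattern_all <- do.call(rbind, lapply(per_image, `[[`, "pattern"))

  files <- c(histograms = file.path(out_dir, "histograms.csv"),
             thresholds = file.path(out_dir, "thresholds.csv"),
             regions = file.path(out_dir, "regions.csv"),
             config = file.path(out_dir, "effective_config.yaml"),
             log = file.path(out_dir, "run_log.txt"))
  write.csv(do.call(rbind, hist_rows), files[["histograms"]], row.names = FALSE)
  write.csv(do.call(rbind, thr_rows), files[["thresholds"]], row.names = FALSE)
  if (!is.null(regions_all)) {
    write.csv(regions_all, files[["regions"]], row.names = FALSE)
  }
  if (!is.null(pattern_all)) {
    files[["pattern"]] <- file.path(out_dir, "pattern.csv")
    write.csv(pattern_all, files[["pattern"]], row.names = FALSE)
  }
  write_config(config, files[["config"]])
  writeLines(log_lines, files[["log"]])

  invisible(list(histograms = study,
                 thresholds = do.call(rbind, thr_rows),
                 regions = regions_all, pattern = pattern_all, files = files))
}

threshold_rows <- function(cond, ts) {
  rbind(
    data.frame(condition = cond, threshold_um = ts$threshold, mode = ts$mode,
               stat = names(ts$per_experiment) %||%
                 as.character(seq_along(ts$per_experiment)),
               percent = unname(ts$per_experiment), stringsAsFactors = FALSE),
    data.frame(condition = cond, threshold_um = ts$threshold, mode = ts$mode,
               stat = c("mean", "sem"), percent = c(ts$mean, ts$sem),
               stringsAsFactors = FALSE)
  )
}
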