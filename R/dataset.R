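#' Design of a replicated phantom dataset
#'
#' Describes a multi-condition, multi-experiment synthetic study: each
#' condition is a mixture of object kinds (by object count) rendered into
#' images of several objects each, replicated as `images_per_condition`
#' images within each of `n_experiments` independent experiments — the
#' replicate structure of an in vitro knockdown experiment (3 experiments
#' with four images per condition). Every image receives a seed derived
#' deterministically from the master seed, so the full dataset is a pure
#' function of (design, master seed).
#'
#' @param conditions named list; each entry a named numeric mixture over
#'   `c(tube = , cyst = )` summing to 1 (e.g. `list(control = c(tube = 1),
#'   knockdown = c(tube = 0.8, cyst = 0.2))`).
#' @param n_experiments,images_per_condition,objects_per_image replicate
#'   structure.
#' @param spacing um per pixel (2D).
#' @param tube_radius,tube_length,bulkhead_spacing,bulkhead_jitter,bulkhead_depth
#'   tube geometry (um; jitter and depth are fractions).
#' @param cyst_radius_range cysts draw their radius uniformly from this range
#'   (um).
#' @param wall_intensity,stripe_intensity,interior_intensity,background_intensity
#'   rendering intensities (ADU).
#' @param noise_gaussian_sd,noise_poisson_scale camera noise model (ADU;
#'   photons/ADU).
#' @param gfp_fraction fraction of objects marked rescue-positive (0 disables
#'   the GFP channel).
#' @param master_seed default master seed for [make_dataset()].
#' @return an object of class `phantom_design`.
#' @export
phantom_design <- function(conditions = list(control = c(tube = 1),
                                             knockdown = c(tube = 0.8,
                                                           cyst = 0.2)),
                           n_experiments = 3L,
                           images_per_condition = 4L,
                           objects_per_image = 6L,
                           spacing = c(0.1, 0.1),
                           tube_radius = 1,
                           tube_length = 20,
                           bulkhead_spacing = 2,
                           bulkhead_jitter = 0.1,
                           bulkhead_depth = 0.6,
                           cyst_radius_range = c(7, 9),
                           wall_intensity = 4000,
                           stripe_intensity = 4000,
                           interior_intensity = 3000,
                           background_intensity = 100,
                           noise_gaussian_sd = 390,
                           noise_poisson_scale = 0,
                           gfp_fraction = 0,
                           master_seed = 1L) {
  if (!is.list(conditions) || length(conditions) == 0L ||
      is.null(names(conditions)) || any(names(conditions) == "")) {
    stop("`conditions` must be a non-empty named list (configuration error)")
  }
  for (nm in names(conditions)) {
    mx <- conditions[[nm]]
    if (!is.numeric(mx) || is.null(names(mx)) ||
        !all(names(mx) %in% c("tube", "cyst")) ||
        abs(sum(mx) - 1) > 1e-9 || any(mx < 0)) {
      stop(sprintf("condition '%s': mixture must be named over tube/cyst and sum to 1",
                   nm))
    }
  }
  structure(mget(names(formals(phantom_design)), envir = environment()),
            class = "phantom_design")
}

#' Generate a replicated phantom dataset
#'
#' Renders every image of the design: objects are laid out on disjoint tiles,
#' composited over a common background, camera noise is applied and the
#' result digitized to integer ADU. Ground truth per image is an object
#' label map plus an object table (kind, true radius, bulkhead spacing, GFP
#' flag). Identical (design, master seed) reproduce the dataset bit for bit.
#'
#' @param design a [phantom_design()].
#' @param master_seed master seed; defaults to `design$master_seed`.
#' @return an object of class `phantom_dataset`: list with `design`,
#'   `master_seed`, `images` (named list: `image` a [raster_image()], `truth`
#'   with `$labels` and `$objects`, `experiment`, `condition`, `seed`),
#'   `manifest` (one row per image) and `objects` (one row per object).
#' @export
make_dataset <- function(design, master_seed = design$master_seed) {
  stopifnot(inherits(design, "phantom_design"))
  images <- list()
  man <- list()
  objs <- list()
  for (e in seq_len(design$n_experiments)) {
    for (ci in seq_along(design$conditions)) {
      cond <- names(design$conditions)[ci]
      for (i in seq_len(design$images_per_condition)) {
        seed_img <- derive_seed(master_seed, e, ci, i)
        id <- sprintf("e%d_%s_i%d", e, cond, i)
        entry <- render_image(design, design$conditions[[ci]], seed_img)
        entry$experiment <- e
        entry$condition <- cond
        entry$seed <- seed_img
        images[[id]] <- entry
        man[[id]] <- data.frame(
          image_id = id, experiment = e, condition = cond, seed = seed_img,
          n_objects = nrow(entry$truth$objects),
          n_tubes = sum(entry$truth$objects$kind == "tube"),
          n_cysts = sum(entry$truth$objects$kind == "cyst"),
          stringsAsFactors = FALSE)
        ot <- entry$truth$objects
        ot$image_id <- id
        ot$experiment <- e
        ot$condition <- cond
        objs[[id]] <- ot
      }
    }
  }
  structure(
    list(design = design, master_seed = master_seed, images = images,
         manifest = do.call(rbind, c(man, list(make.row.names = FALSE))),
         objects = do.call(rbind, c(objs, list(make.row.names = FALSE)))),
    class = "phantom_dataset"
  )
}

# one composite image: objects on disjoint tiles over a shared background
render_image <- function(design, mixture, seed_img) {
  n_obj <- design$objects_per_image
  n_cyst <- round(n_obj * (mixture["cyst"] %||% 0))
  n_cyst <- if (is.na(n_cyst)) 0L else as.integer(n_cyst)
  kinds <- c(rep("tube", n_obj - n_cyst), rep("cyst", n_cyst))

  specs <- lapply(seq_len(n_obj), function(o) {
    sd_o <- derive_seed(seed_img, o)
    if (kinds[o] == "cyst") {
      r <- with_seed(sd_o, runif(1, design$cyst_radius_range[1L],
                                 design$cyst_radius_range[2L]))
      phantom_spec("cyst", spacing = design$spacing, cyst_radius = r,
                   wall_intensity = design$wall_intensity,
                   stripe_intensity = design$stripe_intensity,
                   interior_intensity = design$interior_intensity,
                   background_intensity = design$background_intensity,
                   seed = sd_o)
    } else {
      phantom_spec("tube", spacing = design$spacing,
                   tube_radius = design$tube_radius,
                   tube_length = design$tube_length,
                   bulkhead_spacing = design$bulkhead_spacing,
                   bulkhead_jitter = design$bulkhead_jitter,
                   bulkhead_depth = design$bulkhead_depth,
                   wall_intensity = design$wall_intensity,
                   stripe_intensity = design$stripe_intensity,
                   interior_intensity = design$interior_intensity,
                   background_intensity = design$background_intensity,
                   seed = sd_o)
    }
  })

  tiles <- lapply(specs, function(s) s$image_size)
  tile <- c(max(vapply(tiles, `[`, 0L, 1L)), max(vapply(tiles, `[`, 0L, 2L)))
  ncol_t <- ceiling(sqrt(n_obj))
  nrow_t <- ceiling(n_obj / ncol_t)
  d <- c(nrow_t * tile[1L], ncol_t * tile[2L])

  actin <- array(design$background_intensity, dim = d)
  labels <- array(0L, dim = d)
  masks <- vector("list", n_obj)
  orows <- list()
  for (o in seq_len(n_obj)) {
    ph <- make_phantom(specs[[o]])
    ti <- (o - 1L) %/% ncol_t
    tj <- (o - 1L) %% ncol_t
    sz <- dim(ph$truth$mask)
    r0 <- ti * tile[1L] + (tile[1L] - sz[1L]) %/% 2L
    c0 <- tj * tile[2L] + (tile[2L] - sz[2L]) %/% 2L
    rows <- r0 + seq_len(sz[1L])
    cols <- c0 + seq_len(sz[2L])
    actin[rows, cols] <- ph$image$channels$actin
    lab_tile <- labels[rows, cols]
    lab_tile[ph$truth$mask] <- o
    labels[rows, cols] <- lab_tile
    m <- array(FALSE, dim = d)
    m[rows, cols] <- ph$truth$mask
    masks[[o]] <- m
    orows[[o]] <- data.frame(
      object_id = o, kind = specs[[o]]$shape_kind,
      true_radius_um = if (kinds[o] == "cyst") specs[[o]]$cyst_radius
                       else specs[[o]]$tube_radius,
      bulkhead_spacing_um = if (kinds[o] == "tube") design$bulkhead_spacing else 0,
      gfp = FALSE, stringsAsFactors = FALSE)
  }

  img <- raster_image(list(actin = actin), spacing = design$spacing,
                      provenance = sprintf("phantom_dataset seed=%d", seed_img))
  objects <- do.call(rbind, orows)

  if (design$gfp_fraction > 0) {
    gfp <- make_gfp_channel(lapply(masks, function(m) list(mask = m)),
                            design$gfp_fraction,
                            seed = derive_seed(seed_img, 999))
    img$channels$gfp <- gfp$channel
    objects$gfp <- gfp$positive
  }

  img <- add_noise(img, list(noise_gaussian_sd = design$noise_gaussian_sd,
                             noise_poisson_scale = design$noise_poisson_scale),
                   seed = seed_img, quantize = TRUE)

  list(image = img, truth = list(labels = labels, objects = objects))
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d image(s): %d experiment(s) x %d image(s) x {%s}\n",
              length(x$images), x$design$n_experiments,
              x$design$images_per_condition,
              paste(names(x$design$conditions), collapse = ", ")))
  invisible(x)
}

#' Write a phantom dataset to disk
#'
#' One multi-page TIFF per image (channels as pages) under `images/`, the
#' ground-truth label map under `masks/`, plus `manifest.csv`, `objects.csv`
#' and `design.yaml`.
#'
#' @param ds a [make_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest `data.frame` with `path` and `mask_path`
#'   columns, as consumed by [run_pipeline()].
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  man <- ds$manifest
  man$path <- file.path(dir, "images", paste0(man$image_id, ".tif"))
  man$mask_path <- file.path(dir, "masks", paste0(man$image_id, "_mask.tif"))
  for (k in seq_len(nrow(man))) {
    entry <- ds$images[[man$image_id[k]]]
    write_stack(entry$image, man$path[k])
    write_labels(label_map(entry$truth$labels, entry$image$spacing),
                 man$mask_path[k])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(ds$objects, file.path(dir, "objects.csv"), row.names = FALSE)
  dsn <- ds$design
  dsn$conditions <- lapply(dsn$conditions, as.list)
  yaml::write_yaml(unclass(dsn), file.path(dir, "design.yaml"))
  invisible(man)
}
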