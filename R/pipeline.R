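#' Run configuration for batch processing
#'
#' Bundles everything a batch run needs: input/output locations, filter
#' settings, calibration, exclusion bound, channel file-name patterns, the
#' fraction of nuclei sampled during batch optimisation and the seed used
#' only for that sampling. The resolved configuration is written next to the
#' outputs of every run for provenance.
#'
#' @param input_root folder whose sub-folders are fields of view (one TIFF
#'   z-series per channel per field).
#' @param output_dir folder for result tables, previews and logs.
#' @param settings a [filter_settings()].
#' @param calibration `list(pixel_scale_um, z_step_um)`.
#' @param min_nucleus_px nucleus size exclusion bound (see
#'   [segment_nuclei()]).
#' @param nuclear_pattern,focus_pattern case-insensitive file-name substrings
#'   identifying each channel's TIFFs.
#' @param optimisation_fraction fraction of nuclei batch-tested by
#'   [optimise_batch()], in (0, 1].
#' @param seed integer seed for batch sampling (the pipeline itself is
#'   deterministic).
#' @return object of class `run_config`.
#' @export
run_config <- function(input_root, output_dir,
                       settings = filter_settings(),
                       calibration = list(pixel_scale_um = 0.07,
                                          z_step_um = 0.5),
                       min_nucleus_px = 1000L,
                       nuclear_pattern = "dapi", focus_pattern = "rif",
                       optimisation_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(settings, "filter_settings"),
            optimisation_fraction > 0, optimisation_fraction <= 1)
  structure(list(input_root = input_root, output_dir = output_dir,
                 settings = settings, calibration = calibration,
                 min_nucleus_px = as.integer(min_nucleus_px),
                 nuclear_pattern = nuclear_pattern,
                 focus_pattern = focus_pattern,
                 optimisation_fraction = optimisation_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

field_folders <- function(input_root) {
  subs <- list.dirs(input_root, recursive = FALSE)
  keep <- vapply(subs, function(d)
    length(list.files(d, pattern = "\\.tiff?$", ignore.case = TRUE)) > 0,
    logical(1))
  subs[keep]
}

# full single-nucleus analysis: detect, measure (coordinates shifted to the
# field frame), reconstruct, size and distances
analyse_nucleus <- function(focus_stack, nucleus, settings,
                            external_histogram = NULL, pad_px = 0L) {
  crop <- crop_nucleus(focus_stack, nucleus, pad_px = pad_px)
  det <- detect_foci_masks(crop$stack, crop$mask, settings,
                           external_histogram = external_histogram)
  sf <- measure_slice_foci(det$masks, crop$stack, nucleus$label)
  sf <- lapply(sf, shift_slice_focus,
               du = crop$origin[["col_min"]], dv = crop$origin[["row_min"]])
  foci <- discard_small_foci(reconstruct_3d(sf), settings$min_focus_px)
  list(foci = foci, masks = det$masks, threshold = det$threshold,
       origin = crop$origin, filtered = det$filtered, mask = crop$mask)
}

shift_slice_focus <- function(f, du, dv) {
  f$pixels[, 1L] <- f$pixels[, 1L] + du
  f$pixels[, 2L] <- f$pixels[, 2L] + dv
  f$centroid_px[1L] <- f$centroid_px[1L] + du
  f$centroid_px[2L] <- f$centroid_px[2L] + dv
  f
}

#' Process a whole experiment
#'
#' For every field folder under the input root: reads both channels, segments
#' nuclei on the nuclear-channel MIP, and for each retained nucleus detects,
#' measures and 3D-reconstructs foci, categorises them by size and computes
#' all inter-focus and focus-to-centre distances. With
#' `settings$histogram_scope = "folder"` one combined histogram over all
#' nuclei of a field sets the threshold for every nucleus of that field.
#' Unreadable folders are skipped with a logged error; fields whose nuclei
#' are all excluded produce empty rows, not failures. The run is fully
#' deterministic.
#'
#' @param config a [run_config()].
#' @param write logical: write CSV tables, the log and the resolved config
#'   into `config$output_dir` (see [write_reports()]).
#' @return (invisibly when `write = TRUE`) list with data frames `foci`,
#'   `nuclei`, `distances`, and `log` (character vector).
#' @export
run_experiment <- function(config, write = TRUE) {
  stopifnot(inherits(config, "run_config"))
  fields <- field_folders(config$input_root)
  if (length(fields) == 0L)
    stop("no field folders with TIFF series under ", config$input_root,
         call. = FALSE)
  if (write) {
    if (!dir.exists(config$output_dir) &&
        !dir.create(config$output_dir, recursive = TRUE,
                    showWarnings = FALSE))
      stop("cannot create output dir: ", config$output_dir, call. = FALSE)
  }
  foci_rows <- list(); nuc_rows <- list(); dist_rows <- list()
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  for (field in fields) {
    fname <- basename(field)
    res <- tryCatch({
      nuclear <- read_stack(field, "nuclear", config$calibration,
                            pattern = config$nuclear_pattern)
      focus <- read_stack(field, "focus", config$calibration,
                          pattern = config$focus_pattern)
      list(nuclear = nuclear, focus = focus)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logf("field %s: skipped (%s)", fname, conditionMessage(res))
      next
    }
    regions <- withCallingHandlers(
      segment_nuclei(res$nuclear, config$min_nucleus_px),
      warning = function(w) {
        logf("field %s: %s", fname, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    for (r in regions)
      if (r$excluded)
        logf("field %s: nucleus at (%.0f, %.0f) excluded: %s", fname,
             r$centroid_xy[1], r$centroid_xy[2], r$exclusion_reason)
    kept <- Filter(function(r) !r$excluded, regions)
    logf("field %s: %d nucleus/nuclei retained, %d excluded", fname,
         length(kept), length(regions) - length(kept))
    folder_hist <- NULL
    if (config$settings$histogram_scope == "folder" && length(kept) > 0) {
      crops <- lapply(kept, function(r)
        crop_nucleus(res$focus, r, pad_px = 0L))
      filtered <- lapply(crops, function(cr)
        lapply(cr$stack$slices, focus_response, settings = config$settings))
      folder_hist <- build_global_histogram(
        filtered, scope = "folder",
        nucleus_masks = lapply(crops, function(cr)
          guard_mask(cr$mask, config$settings$mask_guard_px)))
    }
    nslices <- length(res$focus$slices)
    for (r in kept) {
      ana <- withCallingHandlers(
        analyse_nucleus(res$focus, r, config$settings,
                        external_histogram = folder_hist),
        warning = function(w) {
          logf("field %s nucleus %d: %s", fname, r$label,
               conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      cal <- config$calibration
      centre_um <- c(r$centroid_xy[["x"]] * cal$pixel_scale_um,
                     r$centroid_xy[["y"]] * cal$pixel_scale_um,
                     (nslices - 1) / 2 * cal$z_step_um)
      n_cat <- c(small = 0L, medium = 0L, large = 0L)
      cent_mat <- matrix(numeric(0), 0, 3)
      for (fc in ana$foci) {
        ctr <- weighted_centroid_3d(fc, cal)
        vs <- volume_and_size(fc, cal)
        n_cat[vs$size_category] <- n_cat[vs$size_category] + 1L
        cent_mat <- rbind(cent_mat, ctr)
        big <- fc$members[[which.max(
          vapply(fc$members, function(m) m$area_px, numeric(1)))]]
        all_vals_mean <- stats::weighted.mean(
          vapply(fc$members, function(m) m$mean_intensity, numeric(1)),
          vapply(fc$members, function(m) m$area_px, numeric(1)))
        foci_rows[[length(foci_rows) + 1L]] <- data.frame(
          field = fname, nucleus_label = r$label, focus_id = fc$focus_id,
          x_um = ctr[["x_um"]], y_um = ctr[["y_um"]], z_um = ctr[["z_um"]],
          z_extent = fc$z_extent,
          area_px_max = vs$max_slice_area_px,
          volume_um3 = vs$volume_um3,
          volume_ellipsoid_um3 = vs$volume_ellipsoid_um3,
          equivalent_diameter_um = vs$equivalent_diameter_um,
          size_category = vs$size_category,
          theta_rad = big$theta_rad,
          ecc_ratio = big$ecc_ratio,
          axis_ratio = big$axis_ratio,
          r_a_um = big$r_a_px * cal$pixel_scale_um,
          r_b_um = big$r_b_px * cal$pixel_scale_um,
          mean_intensity = all_vals_mean,
          integrated_intensity = sum(vapply(
            fc$members, function(m) m$integrated_intensity, numeric(1))),
          junction = fc$junction,
          stringsAsFactors = FALSE)
      }
      nuc_rows[[length(nuc_rows) + 1L]] <- data.frame(
        field = fname, nucleus_label = r$label, area_px = r$area_px,
        centroid_x_um = centre_um[1], centroid_y_um = centre_um[2],
        n_foci = length(ana$foci),
        n_small = n_cat[["small"]], n_medium = n_cat[["medium"]],
        n_large = n_cat[["large"]],
        threshold = ana$threshold,
        stringsAsFactors = FALSE)
      d <- pairwise_distances(cent_mat, centre_um, r$label)
      if (nrow(d) > 0) {
        d <- cbind(field = fname, d, stringsAsFactors = FALSE)
        dist_rows[[length(dist_rows) + 1L]] <- d
      }
    }
  }
  results <- list(
    foci = bind_or_empty(foci_rows, foci_schema()),
    nuclei = bind_or_empty(nuc_rows, nuclei_schema()),
    distances = bind_or_empty(dist_rows, distances_schema()),
    log = log_lines)
  if (write) {
    write_reports(results, config$output_dir)
    write_resolved_config(config)
    return(invisible(results))
  }
  results
}

bind_or_empty <- function(rows, schema) {
  if (length(rows) == 0L) return(schema)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

foci_schema <- function() data.frame(
  field = character(0), nucleus_label = integer(0), focus_id = integer(0),
  x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
  z_extent = integer(0), area_px_max = numeric(0), volume_um3 = numeric(0),
  volume_ellipsoid_um3 = numeric(0), equivalent_diameter_um = numeric(0),
  size_category = character(0), theta_rad = numeric(0),
  ecc_ratio = numeric(0), axis_ratio = numeric(0), r_a_um = numeric(0),
  r_b_um = numeric(0), mean_intensity = numeric(0),
  integrated_intensity = numeric(0), junction = logical(0),
  stringsAsFactors = FALSE)

nuclei_schema <- function() data.frame(
  field = character(0), nucleus_label = integer(0), area_px = integer(0),
  centroid_x_um = numeric(0), centroid_y_um = numeric(0),
  n_foci = integer(0), n_small = integer(0), n_medium = integer(0),
  n_large = integer(0), threshold = numeric(0), stringsAsFactors = FALSE)

distances_schema <- function() data.frame(
  field = character(0), nucleus_label = integer(0),
  focus_id_a = character(0), focus_id_b = character(0),
  distance_um = numeric(0), stringsAsFactors = FALSE)

#' Write result tables
#'
#' Writes `foci.csv`, `nuclei.csv`, `distances.csv` (RFC 4180 quoting,
#' UTF-8) and `run.log` into `output_dir`. Empty results produce header-only
#' files.
#'
#' @param results list as returned by [run_experiment()].
#' @param output_dir output folder (created if absent).
#' @return invisibly, the written paths.
#' @export
write_reports <- function(results, output_dir) {
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output dir: ", output_dir, call. = FALSE)
  paths <- c(foci = file.path(output_dir, "foci.csv"),
             nuclei = file.path(output_dir, "nuclei.csv"),
             distances = file.path(output_dir, "distances.csv"))
  for (nm in names(paths))
    utils::write.csv(results[[nm]], paths[nm], row.names = FALSE,
                     fileEncoding = "UTF-8")
  log_path <- file.path(output_dir, "run.log")
  writeLines(results$log %||% character(0), log_path)
  invisible(c(paths, log = log_path))
}

write_resolved_config <- function(config) {
  cfg <- unclass(config)
  cfg$settings <- unclass(cfg$settings)
  jsonlite::write_json(cfg, file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Batch optimisation of filter settings
#'
#' Samples the configured fraction of nuclei (seeded, at least one per
#' field), runs detection under every grid point, and scores each setting
#' by: the salt-and-pepper score (mean count of single-pixel binary
#' components per nucleus, the signature of under-filtering) and a
#' morphology-distortion proxy (mean absolute change in focus count versus
#' the lightest setting in the grid). Settings are ranked by minimal total
#' iterations among those whose salt-and-pepper score is at most `salt_cap`;
#' settings above the cap rank below all settings under it. Binary preview
#' images of the central slice are written per grid point for visual review.
#'
#' @param config a [run_config()].
#' @param grid list with `pre_iterations`, `post_iterations`,
#'   `sensitivity` vectors; the grid is their cross product.
#' @param salt_cap maximum acceptable salt-and-pepper score.
#' @param write_previews write per-setting binary preview TIFFs under
#'   `output_dir/previews`.
#' @return data frame of grid points with `salt_score`, `count_distortion`,
#'   `mean_foci`, `rank` (1 = recommended), ordered by rank.
#' @export
optimise_batch <- function(config,
                           grid = list(pre_iterations = c(0L, 1L, 3L, 5L),
                                       post_iterations = c(0L, 3L),
                                       sensitivity = "medium"),
                           salt_cap = 5, write_previews = TRUE) {
  stopifnot(inherits(config, "run_config"))
  fields <- field_folders(config$input_root)
  if (length(fields) == 0L)
    stop("no field folders under ", config$input_root, call. = FALSE)
  # collect (field, nucleus) units, then sample the configured fraction
  units <- list()
  for (field in fields) {
    nuclear <- read_stack(field, "nuclear", config$calibration,
                          pattern = config$nuclear_pattern)
    focus <- read_stack(field, "focus", config$calibration,
                        pattern = config$focus_pattern)
    regions <- suppressWarnings(
      segment_nuclei(nuclear, config$min_nucleus_px))
    for (r in Filter(function(r) !r$excluded, regions))
      units[[length(units) + 1L]] <- list(field = basename(field),
                                          focus = focus, region = r)
  }
  if (length(units) == 0L) stop("no nuclei found", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  n_sample <- max(1L, ceiling(config$optimisation_fraction * length(units)))
  sampled <- units[sort(sample.int(length(units), n_sample))]
  gridpoints <- expand.grid(pre_iterations = grid$pre_iterations,
                            post_iterations = grid$post_iterations,
                            sensitivity = grid$sensitivity,
                            stringsAsFactors = FALSE)
  lightest <- which.min(gridpoints$pre_iterations +
                          gridpoints$post_iterations)
  salt <- numeric(nrow(gridpoints))
  mean_foci <- numeric(nrow(gridpoints))
  preview_dir <- file.path(config$output_dir, "previews")
  if (write_previews)
    dir.create(preview_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in seq_len(nrow(gridpoints))) {
    st <- filter_settings(
      pre_iterations = gridpoints$pre_iterations[g],
      post_iterations = gridpoints$post_iterations[g],
      laplacian_sensitivity = gridpoints$sensitivity[g],
      normalisation_value = config$settings$normalisation_value,
      histogram_scope = "stack")
    salt_g <- numeric(length(sampled))
    nfoci_g <- numeric(length(sampled))
    for (u in seq_along(sampled)) {
      unit <- sampled[[u]]
      ana <- suppressWarnings(
        analyse_nucleus(unit$focus, unit$region, st))
      # salt score from the ungated masks: the signal-presence gates of the
      # production path would hide exactly the noise this score measures
      crop <- crop_nucleus(unit$focus, unit$region)
      raw_det <- suppressWarnings(
        detect_foci_masks(crop$stack, crop$mask, st, gates = FALSE))
      singles <- sum(vapply(raw_det$masks, function(m) {
        lab <- label_regions(m)
        if (lab$count == 0L) return(0L)
        sum(tabulate(lab$labels[lab$labels > 0L], lab$count) == 1L)
      }, integer(1)))
      salt_g[u] <- singles
      nfoci_g[u] <- length(ana$foci)
      if (write_previews && u == 1L) {
        mid <- ceiling(length(raw_det$masks) / 2)
        tiff::writeTIFF(raw_det$masks[[mid]] * 1.0,
                        file.path(preview_dir, sprintf(
                          "pre%d_post%d_%s.tif",
                          st$pre_iterations, st$post_iterations,
                          st$laplacian_sensitivity)),
                        bits.per.sample = 8, compression = "none")
      }
    }
    salt[g] <- mean(salt_g)
    mean_foci[g] <- mean(nfoci_g)
  }
  out <- cbind(gridpoints,
               salt_score = salt,
               count_distortion = abs(mean_foci - mean_foci[lightest]),
               mean_foci = mean_foci)
  total_iters <- out$pre_iterations + out$post_iterations
  # a setting is acceptable when it is clean (salt under the cap) and not
  # degenerate (detecting nothing while other settings do detect foci)
  ok <- out$salt_score <= salt_cap &
    (out$mean_foci > 0 | all(out$mean_foci == 0))
  ord <- order(!ok, total_iters, out$salt_score, out$count_distortion)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a synthetic experiment to disk
#'
#' Renders `n_fields` synthetic fields (see [sample_ground_truth()] and
#' [render_field()]) and writes each as a field folder of two TIFF z-series
#' (`dapi_z*.tif`, `rif_z*.tif`) plus a `truth.json` ground-truth sidecar,
#' i.e. exactly the on-disk layout [run_experiment()] consumes.
#'
#' @param root output root; field folders `field01`, ... are created inside.
#' @param n_fields number of fields.
#' @param seed base seed; field `i` uses `seed + i`.
#' @param shape `c(slices, rows, cols)` per field.
#' @param ... passed to [sample_ground_truth()].
#' @return invisibly, the list of `ground_truth` objects.
#' @export
synth_experiment <- function(root, n_fields = 2L, seed = 1L,
                             shape = c(22L, 320L, 320L), ...) {
  truths <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    truth <- sample_ground_truth(shape = shape, seed = seed + i, ...)
    field_dir <- file.path(root, sprintf("field%02d", i))
    dir.create(field_dir, recursive = TRUE, showWarnings = FALSE)
    rendered <- render_field(truth, shape)
    write_stack(rendered$nuclear, field_dir)
    write_stack(rendered$focus, field_dir)
    write_ground_truth(truth, file.path(field_dir, "truth.json"))
    truths[[i]] <- truth
  }
  invisible(truths)
}
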