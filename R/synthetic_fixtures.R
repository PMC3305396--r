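#' Ground truth for a synthetic two-channel field
#'
#' Describes everything needed to render and to score a synthetic field of
#' view: elliptical nuclei, 3D Gaussian foci inside them, the noise model and
#' the physical calibration. The object serialises losslessly to JSON
#' ([write_ground_truth()]) so rendered stacks can be scored later.
#'
#' Coordinates are 0-based pixels: focus centres are `(x, y, z)` with z in
#' slice units. A focus "diameter" in ground truth is the lateral full width
#' at half maximum, `fwhm_um = 2 sqrt(2 log 2) * sigma_xy_px * pixel_scale_um`,
#' so size-category truth uses the same small/medium/large bin edges (0.5 and
#' 1.0 um) as the detector's equivalent diameter.
#'
#' @param nuclei list of nuclei, each `list(centre_px = c(x, y),
#'   semi_axes_px = c(a, b), orientation_rad)`.
#' @param foci list of foci, each `list(nucleus_index, centre_3d_px =
#'   c(x, y, z), sigma_xy_px, sigma_z_slices, peak_intensity)`; every centre
#'   must lie inside its nucleus footprint.
#' @param noise_model `list(gaussian_sd, poisson, background_level,
#'   background_gradient, nuclear_level)`; `background_gradient` is the
#'   left-to-right linear intensity ramp in counts.
#' @param calibration `list(pixel_scale_um, z_step_um)`.
#' @param seed integer seed making rendering deterministic.
#' @param bit_depth container bit depth of the rendered stacks.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(nuclei, foci = list(),
                         noise_model = list(gaussian_sd = 20, poisson = TRUE,
                                            background_level = 500,
                                            background_gradient = 0,
                                            nuclear_level = 4000),
                         calibration = list(pixel_scale_um = 0.07,
                                            z_step_um = 0.5),
                         seed = 1L, bit_depth = 14L) {
  stopifnot(is.list(nuclei), length(nuclei) >= 1L, is.list(foci))
  defaults <- list(gaussian_sd = 20, poisson = TRUE, background_level = 500,
                   background_gradient = 0, nuclear_level = 4000)
  noise_model <- utils::modifyList(defaults, noise_model)
  for (f in foci) {
    ni <- f$nucleus_index
    if (ni < 1L || ni > length(nuclei))
      stop("focus refers to nucleus ", ni, " which does not exist",
           call. = FALSE)
    if (!point_in_ellipse(f$centre_3d_px[1:2], nuclei[[ni]]))
      stop("focus centre lies outside its nucleus footprint", call. = FALSE)
  }
  structure(list(nuclei = nuclei, foci = foci, noise_model = noise_model,
                 calibration = calibration, seed = as.integer(seed),
                 bit_depth = as.integer(bit_depth)),
            class = "ground_truth")
}

point_in_ellipse <- function(xy, nucleus) {
  d <- c(xy[1] - nucleus$centre_px[1], xy[2] - nucleus$centre_px[2])
  th <- nucleus$orientation_rad %||% 0
  u <- d[1] * cos(th) + d[2] * sin(th)
  v <- -d[1] * sin(th) + d[2] * cos(th)
  (u / nucleus$semi_axes_px[1])^2 + (v / nucleus$semi_axes_px[2])^2 <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname ground_truth
#' @param truth a `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  nuclei <- lapply(x$nuclei, function(n)
    list(centre_px = as.numeric(n$centre_px),
         semi_axes_px = as.numeric(n$semi_axes_px),
         orientation_rad = as.numeric(n$orientation_rad %||% 0)))
  foci <- lapply(x$foci, function(f)
    list(nucleus_index = as.integer(f$nucleus_index),
         centre_3d_px = as.numeric(f$centre_3d_px),
         sigma_xy_px = as.numeric(f$sigma_xy_px),
         sigma_z_slices = as.numeric(f$sigma_z_slices),
         peak_intensity = as.numeric(f$peak_intensity)))
  ground_truth(nuclei, foci, noise_model = x$noise_model,
               calibration = x$calibration, seed = x$seed,
               bit_depth = x$bit_depth %||% 14L)
}

fwhm_factor <- 2 * sqrt(2 * log(2))

#' Convert between lateral FWHM in micrometres and Gaussian sigma in pixels
#' @param fwhm_um focus full width at half maximum in micrometres.
#' @param pixel_scale_um micrometres per pixel.
#' @export
fwhm_to_sigma_px <- function(fwhm_um, pixel_scale_um = 0.07) {
  fwhm_um / fwhm_factor / pixel_scale_um
}

#' Render a synthetic two-channel field
#'
#' Renders the nuclear channel (filled ellipses, constant across z) and the
#' focus channel (sum of 3D Gaussian blobs over a flat or linearly ramped
#' background) as calibrated [image_stack()]s, applies Poisson shot noise on
#' the signal and additive Gaussian read noise when enabled, and quantises to
#' the container bit depth. Rendering is deterministic given `truth$seed`
#' (the caller's RNG state is preserved).
#'
#' @param truth a [ground_truth()].
#' @param shape `c(slices, rows, cols)`.
#' @return list with `nuclear` and `focus` [image_stack()]s.
#' @export
render_field <- function(truth, shape = c(9L, 256L, 256L)) {
  stopifnot(inherits(truth, "ground_truth"), length(shape) == 3L)
  nslices <- shape[1]; nr <- shape[2]; nc <- shape[3]
  nm <- truth$noise_model
  maxv <- 2^truth$bit_depth - 1
  base <- matrix(nm$background_level, nr, nc)
  if (nm$background_gradient != 0)
    base <- base + matrix(rep(seq(0, nm$background_gradient, length.out = nc),
                              each = nr), nr, nc)
  nuc_footprint <- matrix(FALSE, nr, nc)
  for (n in truth$nuclei)
    nuc_footprint <- nuc_footprint | ellipse_mask(nr, nc, n)
  nuclear_base <- base + nm$nuclear_level * nuc_footprint
  focus_base <- lapply(seq_len(nslices) - 1L, function(z) {
    s <- base
    for (f in truth$foci) s <- add_blob(s, f, z)
    s
  })
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(truth$seed)
  noisify <- function(s) {
    v <- as.numeric(s)
    if (isTRUE(nm$poisson)) v <- stats::rpois(length(v), pmax(v, 0))
    if (nm$gaussian_sd > 0) v <- v + stats::rnorm(length(v), 0, nm$gaussian_sd)
    matrix(pmin(pmax(round(v), 0), maxv), nrow(s), ncol(s))
  }
  nuclear <- lapply(seq_len(nslices), function(z) noisify(nuclear_base))
  focus <- lapply(focus_base, noisify)
  cal <- truth$calibration
  list(nuclear = image_stack(nuclear, bit_depth = truth$bit_depth,
                             pixel_scale_um = cal$pixel_scale_um,
                             z_step_um = cal$z_step_um,
                             channel_tag = "nuclear",
                             source_path = "<synthetic>"),
       focus = image_stack(focus, bit_depth = truth$bit_depth,
                           pixel_scale_um = cal$pixel_scale_um,
                           z_step_um = cal$z_step_um,
                           channel_tag = "focus",
                           source_path = "<synthetic>"))
}

ellipse_mask <- function(nr, nc, nucleus) {
  x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1L), nc), nr, nc)
  th <- nucleus$orientation_rad %||% 0
  dx <- x - nucleus$centre_px[1]; dy <- y - nucleus$centre_px[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / nucleus$semi_axes_px[1])^2 + (v / nucleus$semi_axes_px[2])^2 <= 1
}

# add one 3D Gaussian blob's contribution at slice z, evaluated only on a
# +/- 4 sigma window around the centre for speed
add_blob <- function(s, f, z) {
  zfac <- exp(-(z - f$centre_3d_px[3])^2 / (2 * f$sigma_z_slices^2))
  if (zfac < 1e-4) return(s)
  nr <- nrow(s); nc <- ncol(s)
  cx <- f$centre_3d_px[1]; cy <- f$centre_3d_px[2]
  w <- ceiling(4 * f$sigma_xy_px)
  cols <- max(1L, floor(cx) - w + 1L):min(nc, ceiling(cx) + w + 1L)
  rows <- max(1L, floor(cy) - w + 1L):min(nr, ceiling(cy) + w + 1L)
  gx <- exp(-((cols - 1L) - cx)^2 / (2 * f$sigma_xy_px^2))
  gy <- exp(-((rows - 1L) - cy)^2 / (2 * f$sigma_xy_px^2))
  s[rows, cols] <- s[rows, cols] +
    f$peak_intensity * zfac * (gy %o% gx)
  s
}

#' Sample a random ground truth with well-separated foci
#'
#' Places `n_nuclei` elliptical nuclei away from the frame edges and, inside
#' each, `foci_per_nucleus` Gaussian foci by rejection sampling: focus
#' centres lie within 85% of the nucleus ellipse, z within the central
#' slices, and any two foci in a field keep a lateral distance of at least
#' `min_sep_factor` times the larger of the two focus radii (radius =
#' FWHM / 2, so the default of 3 also guarantees 3 sigma). If a
#' placement attempt cannot satisfy the separation constraint the whole
#' field is re-drawn from a derived seed, so the result is still
#' deterministic in `seed`.
#'
#' Default focus sizes are drawn from lateral FWHMs of 0.3, 0.7 and 1.5 um
#' (the small / medium / large regimes) with weights 0.25 / 0.55 / 0.20,
#' approximating the size mix of a low-LET gamma-ray exposure a few hours
#' after irradiation.
#'
#' @param shape `c(slices, rows, cols)` of the field to be rendered.
#' @param n_nuclei nuclei per field.
#' @param foci_per_nucleus foci per nucleus (may be 0 for sham fields).
#' @param fwhm_um lateral FWHMs (um) to draw focus sizes from.
#' @param fwhm_weights sampling weights for `fwhm_um`.
#' @param peak_intensity blob peak amplitude above background, in counts.
#' @param semi_axes_px nucleus semi-axis range, `c(min, max)` pixels.
#' @param noise_model,calibration,bit_depth see [ground_truth()].
#' @param min_sep_factor lateral separation multiplier (see above).
#' @param seed integer; sampling and rendering both derive from it.
#' @return a [ground_truth()].
#' @export
sample_ground_truth <- function(shape = c(22L, 384L, 384L),
                                n_nuclei = 1L, foci_per_nucleus = 5L,
                                fwhm_um = c(0.3, 0.7, 1.5),
                                fwhm_weights = c(0.25, 0.55, 0.20),
                                peak_intensity = 10000,
                                semi_axes_px = c(95, 120),
                                noise_model = list(),
                                calibration = list(pixel_scale_um = 0.07,
                                                   z_step_um = 0.5),
                                bit_depth = 14L,
                                min_sep_factor = 3,
                                seed = 1L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  for (attempt in 0:24) {
    res <- tryCatch(
      sample_ground_truth_once(
        shape, n_nuclei, foci_per_nucleus, fwhm_um, fwhm_weights,
        peak_intensity, semi_axes_px, noise_model, calibration, bit_depth,
        min_sep_factor, seed, placement_seed = seed + attempt * 100003L),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  stop(conditionMessage(res), call. = FALSE)
}

sample_ground_truth_once <- function(shape, n_nuclei, foci_per_nucleus,
                                     fwhm_um, fwhm_weights, peak_intensity,
                                     semi_axes_px, noise_model, calibration,
                                     bit_depth, min_sep_factor, seed,
                                     placement_seed) {
  set.seed(placement_seed)
  nslices <- shape[1]; nr <- shape[2]; nc <- shape[3]
  nuclei <- list()
  for (i in seq_len(n_nuclei)) {
    for (try in 1:500) {
      a <- stats::runif(1, semi_axes_px[1], semi_axes_px[2])
      b <- stats::runif(1, semi_axes_px[1] * 0.8, a)
      th <- stats::runif(1, 0, pi)
      margin <- a + 3
      if (2 * margin >= min(nr, nc))
        stop("field too small for the requested nucleus size", call. = FALSE)
      cx <- stats::runif(1, margin, nc - 1 - margin)
      cy <- stats::runif(1, margin, nr - 1 - margin)
      ok <- TRUE
      for (n2 in nuclei) {
        if (sqrt((cx - n2$centre_px[1])^2 + (cy - n2$centre_px[2])^2) <
            a + max(n2$semi_axes_px) + 10) { ok <- FALSE; break }
      }
      if (ok) {
        nuclei[[i]] <- list(centre_px = c(cx, cy), semi_axes_px = c(a, b),
                            orientation_rad = th)
        break
      }
      if (try == 500) stop("could not place nuclei", call. = FALSE)
    }
  }
  scale <- calibration$pixel_scale_um
  foci <- list()
  placed_xy <- matrix(numeric(0), 0, 2)
  placed_r <- numeric(0)
  zmid <- (nslices - 1) / 2
  zspan <- max(1, (nslices - 1) / 2 - 2.5)
  for (i in seq_len(n_nuclei)) {
    nuc <- nuclei[[i]]
    for (k in seq_len(foci_per_nucleus)) {
      fw <- sample(fwhm_um, 1, prob = fwhm_weights)
      sig <- fwhm_to_sigma_px(fw, scale)
      r_px <- fw / 2 / scale   # focus radius; 3x this also satisfies >= 3 sigma
      placed <- FALSE
      for (try in 1:2000) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1))
        u <- 0.85 * rad * cos(ang) * nuc$semi_axes_px[1]
        v <- 0.85 * rad * sin(ang) * nuc$semi_axes_px[2]
        th <- nuc$orientation_rad
        cx <- nuc$centre_px[1] + u * cos(th) - v * sin(th)
        cy <- nuc$centre_px[2] + u * sin(th) + v * cos(th)
        cz <- stats::runif(1, zmid - zspan, zmid + zspan)
        if (nrow(placed_xy) > 0) {
          d <- sqrt((placed_xy[, 1] - cx)^2 + (placed_xy[, 2] - cy)^2)
          if (any(d < min_sep_factor * pmax(placed_r, r_px))) next
        }
        foci[[length(foci) + 1L]] <- list(
          nucleus_index = i, centre_3d_px = c(cx, cy, cz),
          sigma_xy_px = sig, sigma_z_slices = 1.0,
          peak_intensity = peak_intensity)
        placed_xy <- rbind(placed_xy, c(cx, cy))
        placed_r <- c(placed_r, r_px)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place ", foci_per_nucleus,
             " separated foci in nucleus ", i, call. = FALSE)
    }
  }
  ground_truth(nuclei, foci, noise_model = noise_model,
               calibration = calibration, seed = seed, bit_depth = bit_depth)
}

#' Canonical two-slice linking cases
#'
#' Returns the three canonical cases that pin down the centre-containment
#' linking rule: (A) two overlapping discs on adjacent slices with the upper
#' centre inside the lower region, which must reconstruct as one 3D focus;
#' (B) two overlapping discs whose centres each lie outside the other region,
#' which must stay two foci; and the z-gap case, two coaxial discs separated
#' by an empty slice, which must also stay two foci.
#'
#' @return named list of cases, each `list(masks, expected_count)` where
#'   `masks` is a list of per-slice logical matrices.
#' @export
render_fig4_cases <- function() {
  frame <- function() matrix(FALSE, 24L, 24L)
  disc <- function(m, cx, cy, r) {
    x <- matrix(rep(0:(ncol(m) - 1L), each = nrow(m)), nrow(m))
    y <- matrix(rep(0:(nrow(m) - 1L), ncol(m)), nrow(m))
    m | ((x - cx)^2 + (y - cy)^2 <= r^2)
  }
  list(
    centre_inside = list(
      masks = list(disc(frame(), 11, 11, 4), disc(frame(), 13, 11, 4)),
      expected_count = 1L),
    centre_outside = list(
      masks = list(disc(frame(), 9, 11, 3), disc(frame(), 14, 11, 3)),
      expected_count = 2L),
    z_gap = list(
      masks = list(disc(frame(), 11, 11, 4), frame(),
                   disc(frame(), 11, 11, 4)),
      expected_count = 2L))
}

#' Score detection results against ground truth
#'
#' Greedy nearest-neighbour matching of detected 3D foci to ground-truth
#' foci within `match_radius_um`, per nucleus. Reports per-nucleus count
#' error (detected minus true), the RMSE of matched centroid positions
#' (`localisation_rmse_um`: 3D radial; `rmse_xy_um`: per-axis lateral, x and
#' y errors pooled; `rmse_z_um`: axial) and a 3x3
#' small/medium/large confusion matrix (rows = truth, columns = detected).
#'
#' @param results list over detected nuclei; element `k` is the list of
#'   `focus_3d` objects of that nucleus, with member coordinates in the full
#'   field frame.
#' @param truth the [ground_truth()] the field was rendered from.
#' @param match_radius_um maximum truth-to-detection distance to accept a
#'   match.
#' @param nucleus_centres_px optional n x 2 matrix of detected nucleus
#'   centroids `(x, y)` used to map detected nuclei to truth nuclei by
#'   nearest centre; by default detected nucleus k maps to truth nucleus k.
#' @return list with `per_nucleus` (data frame: `truth_nucleus`, `n_true`,
#'   `n_detected`, `count_error`), `localisation_rmse_um`, `rmse_xy_um`,
#'   `rmse_z_um`, `size_confusion`, `n_matched`, `n_missed`, `n_spurious`.
#' @export
score_against_truth <- function(results, truth, match_radius_um = 0.5,
                                nucleus_centres_px = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  cal <- truth$calibration
  n_truth_nuc <- length(truth$nuclei)
  nucleus_map <- seq_along(results)
  if (!is.null(nucleus_centres_px) && length(results) > 0) {
    tc <- t(vapply(truth$nuclei, function(n) n$centre_px, numeric(2)))
    nucleus_map <- apply(nucleus_centres_px, 1L, function(p)
      which.min((tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2))
  }
  if (length(results) > 0 && max(nucleus_map) > n_truth_nuc)
    stop("detected nuclei do not map into the ground truth", call. = FALSE)
  cats <- c("small", "medium", "large")
  confusion <- matrix(0L, 3, 3, dimnames = list(truth = cats, detected = cats))
  sq_err <- matrix(numeric(0), 0, 3)
  per_nuc <- data.frame(truth_nucleus = seq_len(n_truth_nuc),
                        n_true = 0L, n_detected = 0L, count_error = 0L)
  n_matched <- 0L; n_missed <- 0L; n_spurious <- 0L
  for (ni in seq_len(n_truth_nuc)) {
    tf <- Filter(function(f) f$nucleus_index == ni, truth$foci)
    det <- unlist(lapply(which(nucleus_map == ni),
                         function(k) results[[k]]), recursive = FALSE)
    per_nuc$n_true[ni] <- length(tf)
    per_nuc$n_detected[ni] <- length(det)
    per_nuc$count_error[ni] <- length(det) - length(tf)
    if (length(tf) == 0L && length(det) == 0L) next
    t_pos <- t(vapply(tf, function(f)
      c(f$centre_3d_px[1] * cal$pixel_scale_um,
        f$centre_3d_px[2] * cal$pixel_scale_um,
        f$centre_3d_px[3] * cal$z_step_um), numeric(3)))
    t_cat <- vapply(tf, function(f)
      size_category(f$sigma_xy_px * fwhm_factor * cal$pixel_scale_um),
      character(1))
    d_pos <- if (length(det)) t(vapply(det, weighted_centroid_3d,
                                       numeric(3), calibration = cal))
      else matrix(numeric(0), 0, 3)
    d_cat <- vapply(det, function(f)
      volume_and_size(f, cal)$size_category, character(1))
    used_t <- logical(length(tf)); used_d <- logical(length(det))
    if (length(tf) && length(det)) {
      dm <- as.matrix(stats::dist(rbind(t_pos, d_pos)))
      dm <- dm[seq_along(tf), length(tf) + seq_along(det), drop = FALSE]
      repeat {
        if (all(used_t) || all(used_d)) break
        dm2 <- dm
        dm2[used_t, ] <- Inf; dm2[, used_d] <- Inf
        mi <- which.min(dm2)
        if (!length(mi) || dm2[mi] > match_radius_um) break
        ti <- (mi - 1L) %% length(tf) + 1L
        di <- (mi - 1L) %/% length(tf) + 1L
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        n_matched <- n_matched + 1L
        sq_err <- rbind(sq_err, (t_pos[ti, ] - d_pos[di, ])^2)
        confusion[t_cat[ti], d_cat[di]] <- confusion[t_cat[ti], d_cat[di]] + 1L
      }
    }
    n_missed <- n_missed + sum(!used_t)
    n_spurious <- n_spurious + sum(!used_d)
  }
  list(per_nucleus = per_nuc,
       localisation_rmse_um = if (nrow(sq_err)) sqrt(mean(rowSums(sq_err)))
         else NA_real_,
       rmse_xy_um = if (nrow(sq_err)) sqrt(mean(sq_err[, 1:2]))
         else NA_real_,
       rmse_z_um = if (nrow(sq_err)) sqrt(mean(sq_err[, 3])) else NA_real_,
       size_confusion = confusion,
       n_matched = n_matched, n_missed = n_missed, n_spurious = n_spurious)
}
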