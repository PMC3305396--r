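#' Focus-detection filter settings
#'
#' Tunable parameters of the per-slice focus detection chain. The chain is:
#' `pre_iterations` of 3x3 mean smoothing, a Laplacian whose kernel is chosen
#' by `laplacian_sensitivity`, `post_iterations` of Crimmins speckle removal,
#' a maximum-entropy threshold computed on one global histogram per stack (or
#' per folder), and a fixed 3x3 morphological closing.
#'
#' Defaults follow a typical optimised setting for widefield 53BP1 stacks:
#' 3 pre-Laplacian smoothing iterations, medium Laplacian sensitivity, 3
#' post-Laplacian Crimmins iterations, and a normalisation offset of 1500
#' added after the Laplacian so focus troughs do not fall below zero.
#'
#' Sensitivity maps to kernels of increasing neighbourhood (hence increasing
#' response to broader structures): `low` is the 4-neighbour Laplacian,
#' `medium` the 8-neighbour Laplacian, `high` a 5x5 Laplacian-of-Gaussian.
#'
#' @param pre_iterations smoothing iterations before the Laplacian (>= 0).
#' @param post_iterations Crimmins iterations after the Laplacian (>= 0).
#' @param laplacian_sensitivity `"low"`, `"medium"` or `"high"`.
#' @param normalisation_value offset added after the Laplacian (>= 0).
#' @param histogram_scope `"stack"` (one histogram per nucleus stack) or
#'   `"folder"` (one histogram combined over all nuclei of a folder).
#' @param min_focus_px minimum largest-slice area (pixels) for a
#'   reconstructed 3D focus to be reported; smaller components are
#'   sub-resolution specks (a diffraction-limited focus of ~0.25 um diameter
#'   covers ~10 pixels at 0.07 um/pixel).
#' @param mask_guard_px width of the rim eroded off the nucleus mask before
#'   histogramming and thresholding. Zeroing pixels outside the nucleus
#'   creates an artificial intensity step at the mask edge to which the
#'   smoothing and Laplacian kernels respond; the guard rim excludes that
#'   self-inflicted response. `NULL` (default) uses `pre_iterations + 1`,
#'   the reach of the iterated 3x3 smoothing.
#' @param max_foreground_fraction sanity cap: foci are sparse peaks, so a
#'   global threshold that marks more than this fraction of in-mask pixels
#'   as foreground indicates there is no separable signal class (e.g. a
#'   sham nucleus); the stack is then reported as focus-free.
#' @param min_threshold_snr signal-to-noise gate: a focus is a peak of
#'   signal distinct from the background, so the global threshold must lie
#'   at least this many robust standard deviations (1.4826 MAD) above the
#'   median of the in-mask focus response. A threshold inside the noise
#'   distribution means the maximum-entropy split merely divided the noise
#'   into strong and weak, and the stack is reported focus-free.
#' @return an object of class `filter_settings`.
#' @export
filter_settings <- function(pre_iterations = 3L, post_iterations = 3L,
                            laplacian_sensitivity = c("medium", "low", "high"),
                            normalisation_value = 1500L,
                            histogram_scope = c("stack", "folder"),
                            min_focus_px = 5L,
                            mask_guard_px = NULL,
                            max_foreground_fraction = 0.2,
                            min_threshold_snr = 10) {
  laplacian_sensitivity <- match.arg(laplacian_sensitivity)
  histogram_scope <- match.arg(histogram_scope)
  stopifnot(pre_iterations >= 0L, post_iterations >= 0L,
            normalisation_value >= 0, min_focus_px >= 0L,
            max_foreground_fraction > 0, max_foreground_fraction <= 1,
            min_threshold_snr >= 0)
  if (is.null(mask_guard_px)) mask_guard_px <- pre_iterations + 1L
  structure(
    list(pre_iterations = as.integer(pre_iterations),
         post_iterations = as.integer(post_iterations),
         laplacian_sensitivity = laplacian_sensitivity,
         normalisation_value = as.numeric(normalisation_value),
         histogram_scope = histogram_scope,
         min_focus_px = as.integer(min_focus_px),
         mask_guard_px = as.integer(mask_guard_px),
         max_foreground_fraction = max_foreground_fraction,
         min_threshold_snr = min_threshold_snr),
    class = "filter_settings")
}

# robust location and scale of a gl_hist (median and 1.4826 * MAD)
hist_location_scale <- function(h) {
  cum <- cumsum(h$counts)
  tot <- cum[length(cum)]
  med <- h$levels[which(cum >= tot / 2)[1L]]
  dev <- abs(h$levels - med)
  ord <- order(dev)
  cum2 <- cumsum(h$counts[ord])
  mad <- dev[ord][which(cum2 >= tot / 2)[1L]]
  c(median = med, scale = max(1.4826 * mad, 1))
}

# erode the nucleus mask by n pixels (iterated 3x3 erosion with foreground
# padding so the frame border itself does not erode)
guard_mask <- function(mask, n) {
  for (i in seq_len(n)) mask <- binary_erode3(mask)
  mask
}

#' @export
print.filter_settings <- function(x, ...) {
  cat(sprintf(
    "filter_settings: pre=%d, post=%d, sensitivity=%s, norm=%g, scope=%s\n",
    x$pre_iterations, x$post_iterations, x$laplacian_sensitivity,
    x$normalisation_value, x$histogram_scope))
  invisible(x)
}

laplacian_kernel <- function(sensitivity) {
  switch(sensitivity,
    low = matrix(c(0, 1, 0,
                   1, -4, 1,
                   0, 1, 0), 3, 3, byrow = TRUE),
    medium = matrix(c(1, 1, 1,
                      1, -8, 1,
                      1, 1, 1), 3, 3, byrow = TRUE),
    # 5x5 Laplacian of Gaussian, oriented so peaks become troughs
    high = matrix(c(0, 0, 1, 0, 0,
                    0, 1, 2, 1, 0,
                    1, 2, -16, 2, 1,
                    0, 1, 2, 1, 0,
                    0, 0, 1, 0, 0), 5, 5, byrow = TRUE),
    stop("unknown sensitivity: ", sensitivity, call. = FALSE))
}

#' Pre-Laplacian smoothing
#'
#' Iterated 3x3 uniform-mean convolution with reflective borders, used to
#' remove high-frequency noise spikes before the Laplacian so that focus
#' dimensions can be extracted accurately. Arithmetic is floating point;
#' `iterations = 0` returns the input unchanged.
#'
#' @param slice numeric matrix.
#' @param iterations number of smoothing passes (>= 0).
#' @return numeric matrix of the same dimensions.
#' @export
presmooth <- function(slice, iterations = 1L) {
  stopifnot(is.matrix(slice), iterations >= 0L)
  k <- matrix(1 / 9, 3, 3)
  for (i in seq_len(iterations)) slice <- convolve2d_reflect(slice, k)
  slice
}

#' Laplacian enhancement
#'
#' Applies a discrete Laplacian (kernel per `sensitivity`, reflective
#' borders), turning intensity peaks into troughs, then adds
#' `normalisation_value` (default 1500) so focus troughs do not fall below
#' zero. Values still negative after the offset are clamped to 0 with a
#' warning. A flat field maps to `normalisation_value` everywhere.
#'
#' @param slice numeric matrix (typically the pre-smoothed slice).
#' @param sensitivity `"low"`, `"medium"` or `"high"` (see
#'   [filter_settings()]).
#' @param normalisation_value offset added after the convolution.
#' @return numeric matrix; signed arithmetic internally, clamped at 0.
#' @export
laplacian <- function(slice, sensitivity = "medium",
                      normalisation_value = 1500) {
  stopifnot(is.matrix(slice))
  out <- convolve2d_reflect(slice, laplacian_kernel(sensitivity)) +
    normalisation_value
  n_neg <- sum(out < 0)
  if (n_neg > 0) {
    warning(sprintf(
      "%d pixel(s) below zero after normalisation offset %g; clamped to 0",
      n_neg, normalisation_value), call. = FALSE)
    out[out < 0] <- 0
  }
  out
}

#' Crimmins speckle removal
#'
#' The classic Crimmins geometric filter: each iteration makes one dark-pixel
#' pass (brightening pixels significantly darker than their neighbours) and
#' one light-pixel pass (darkening pixels lighter than their neighbours),
#' each consisting of four conditional +/-1 adjustments along the four
#' directions N-S, E-W, NW-SE and NE-SW. Out-of-frame neighbours are taken by
#' reflection, so border comparisons are inert. `iterations = 0` is the
#' identity.
#'
#' @param slice numeric matrix.
#' @param iterations number of full dark+light iterations (>= 0).
#' @return numeric matrix of the same dimensions.
#' @export
crimmins <- function(slice, iterations = 1L) {
  stopifnot(is.matrix(slice), iterations >= 0L)
  dirs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (i in seq_len(iterations)) {
    for (pass in c("dark", "light")) {
      s <- if (pass == "dark") 1 else -1
      for (d in dirs) {
        a <- shift_reflect(slice, -d[1L], -d[2L])
        cc <- shift_reflect(slice, d[1L], d[2L])
        slice <- slice + s * (s * (a - slice) >= 2)
        a <- shift_reflect(slice, -d[1L], -d[2L])
        cc <- shift_reflect(slice, d[1L], d[2L])
        slice <- slice + s * (s * (a - slice) > 0 & s * (cc - slice) >= 0)
        a <- shift_reflect(slice, -d[1L], -d[2L])
        cc <- shift_reflect(slice, d[1L], d[2L])
        slice <- slice + s * (s * (cc - slice) > 0 & s * (a - slice) >= 0)
        a <- shift_reflect(slice, -d[1L], -d[2L])
        cc <- shift_reflect(slice, d[1L], d[2L])
        slice <- slice + s * (s * (cc - slice) >= 2)
      }
    }
  }
  slice
}

# full per-slice filter chain up to the signed focus response, in which foci
# are peaks (the Laplacian trough image is negated so that "above threshold"
# always means "focus")
focus_response <- function(slice, settings) {
  f <- presmooth(slice, settings$pre_iterations)
  f <- suppressWarnings(
    laplacian(f, settings$laplacian_sensitivity,
              settings$normalisation_value))
  f <- crimmins(f, settings$post_iterations)
  -f
}

#' Accumulate the global focus-response histogram
#'
#' Builds one integer-binned histogram from the in-mask pixels of every slice
#' of the given scope: a single nucleus stack (`scope = "stack"`) or all
#' nucleus stacks of a folder (`scope = "folder"`). Thresholding every slice
#' with this one global threshold prevents noise from being segmented as
#' signal in slices that contain no true foci.
#'
#' @param filtered_stacks for `scope = "stack"`, a list of filtered slice
#'   matrices for one nucleus; for `scope = "folder"`, a list of such lists
#'   (one per nucleus).
#' @param scope `"stack"` or `"folder"`.
#' @param nucleus_masks a single logical matrix (stack scope) or a list of
#'   them aligned with `filtered_stacks` (folder scope).
#' @return a `gl_hist` (see [pixel_histogram()]).
#' @export
build_global_histogram <- function(filtered_stacks,
                                   scope = c("stack", "folder"),
                                   nucleus_masks = NULL) {
  scope <- match.arg(scope)
  if (scope == "stack") {
    filtered_stacks <- list(filtered_stacks)
    nucleus_masks <- list(nucleus_masks)
  }
  if (!is.null(nucleus_masks) &&
      length(nucleus_masks) != length(filtered_stacks))
    stop("one nucleus mask per stack is required", call. = FALSE)
  hs <- vector("list", 0L)
  for (i in seq_along(filtered_stacks)) {
    slices <- filtered_stacks[[i]]
    m <- if (is.null(nucleus_masks)) NULL else
      mask_as_logical(nucleus_masks[[i]])
    for (s in slices) {
      if (!is.null(m) && !identical(dim(m), dim(s)))
        stop("nucleus mask does not align with filtered slices",
             call. = FALSE)
      v <- if (is.null(m)) as.numeric(s) else s[m]
      if (length(v)) hs[[length(hs) + 1L]] <- pixel_histogram(v)
    }
  }
  if (length(hs) == 0L) stop("no in-mask pixels to histogram", call. = FALSE)
  combine_histograms(hs)
}

#' Threshold a filtered slice and close gaps
#'
#' Binarises one filtered slice against the global threshold and applies one
#' 3x3 morphological closing to fill small gaps inside foci. With
#' `polarity_inverted = TRUE` (the pipeline default) the slice is the negated
#' Laplacian response, so focus pixels are those strictly above the
#' threshold; with `FALSE` focus pixels are those strictly below it.
#'
#' @param filtered_slice numeric matrix (values are binned to integers by
#'   round-half-away-from-zero before comparison).
#' @param threshold gray level from [max_entropy_threshold()] on the matching
#'   scope's global histogram.
#' @param polarity_inverted logical, see above.
#' @return logical matrix.
#' @export
binarize_and_close <- function(filtered_slice, threshold,
                               polarity_inverted = TRUE) {
  v <- round_half_away(filtered_slice)
  B <- if (polarity_inverted) v > threshold else v < threshold
  binary_close3(B)
}

#' Detect per-slice focus masks for one nucleus
#'
#' Runs the full detection chain on a cropped, masked nucleus stack of the
#' focus channel: per slice pre-smoothing, Laplacian with normalisation,
#' Crimmins speckle removal and polarity inversion; then one maximum-entropy
#' threshold on the global histogram of all in-mask filtered pixels (or on a
#' supplied folder-level histogram); then per-slice binarisation with 3x3
#' closing. Pixels outside the nucleus mask are always `FALSE`. The chain
#' contains no randomness: identical inputs give bit-identical masks.
#'
#' @param nucleus_stack an [image_stack()] cropped to one nucleus (see
#'   [crop_nucleus()]).
#' @param mask logical matrix, the nucleus mask aligned with the crop.
#' @param settings a [filter_settings()].
#' @param external_histogram optional `gl_hist` accumulated at folder scope;
#'   when supplied it replaces the stack-scope histogram.
#' @param gates apply the signal-presence gates (`min_threshold_snr`,
#'   `max_foreground_fraction`)? Disabled by [optimise_batch()] when scoring
#'   salt-and-pepper noise, which the gates would otherwise hide.
#' @return list with `masks` (per-slice logical matrices), `threshold`,
#'   `histogram`, and `filtered` (the per-slice focus-response matrices).
#' @export
detect_foci_masks <- function(nucleus_stack, mask, settings = filter_settings(),
                              external_histogram = NULL, gates = TRUE) {
  stopifnot(inherits(nucleus_stack, "image_stack"),
            inherits(settings, "filter_settings"))
  mask <- mask_as_logical(mask)
  if (!identical(dim(mask), dim(nucleus_stack$slices[[1]])))
    stop("nucleus mask does not align with the stack slices", call. = FALSE)
  gmask <- guard_mask(mask, settings$mask_guard_px)
  filtered <- lapply(nucleus_stack$slices, focus_response, settings = settings)
  empty_masks <- function()
    lapply(filtered, function(s) matrix(FALSE, nrow(s), ncol(s)))
  if (!any(gmask)) {
    warning("nucleus vanished under the mask guard rim; no foci detected",
            call. = FALSE)
    return(list(masks = empty_masks(), threshold = NA_integer_,
                histogram = NULL, filtered = filtered))
  }
  hist <- if (is.null(external_histogram))
    build_global_histogram(filtered, scope = "stack", nucleus_masks = gmask)
  else external_histogram
  # Threshold selection runs on the peak side of the response distribution
  # (levels at or above the median): foci only ever add response above the
  # background, while the Laplacian's side lobes around bright peaks populate
  # the opposite half and would otherwise compete for the entropy split.
  ls <- hist_location_scale(hist)
  keep <- hist$levels >= ls[["median"]]
  thr <- tryCatch(
    max_entropy_threshold(gl_hist(hist$levels[keep], hist$counts[keep])),
    error = function(e) NULL)
  if (is.null(thr)) {
    warning("degenerate focus-response histogram; no foci detected",
            call. = FALSE)
    return(list(masks = empty_masks(), threshold = NA_integer_,
                histogram = hist, filtered = filtered))
  }
  snr <- (thr - ls[["median"]]) / ls[["scale"]]
  if (gates && snr < settings$min_threshold_snr) {
    warning(sprintf(
      paste0("threshold lies %.1f robust SD above the background median ",
             "(gate %.1f): no signal class distinct from background, ",
             "reporting no foci"), snr, settings$min_threshold_snr),
      call. = FALSE)
    return(list(masks = empty_masks(), threshold = thr, histogram = hist,
                filtered = filtered))
  }
  masks <- lapply(filtered, function(s) binarize_and_close(s, thr) & gmask)
  fg <- sum(vapply(masks, sum, numeric(1)))
  if (gates &&
      fg > settings$max_foreground_fraction * sum(gmask) * length(masks)) {
    warning(sprintf(
      paste0("threshold marks %.0f%% of in-mask pixels as foreground ",
             "(cap %.0f%%): no separable signal class, reporting no foci"),
      100 * fg / (sum(gmask) * length(masks)),
      100 * settings$max_foreground_fraction), call. = FALSE)
    return(list(masks = empty_masks(), threshold = thr, histogram = hist,
                filtered = filtered))
  }
  list(masks = masks, threshold = thr, histogram = hist, filtered = filtered)
}

#' Discard sub-resolution 3D foci
#'
#' Removes reconstructed foci whose largest member slice is smaller than
#' `min_focus_px` pixels; these are isolated speckle residues rather than
#' diffraction-limited foci. Focus ids are reassigned contiguously.
#'
#' @param foci list of `focus_3d` (see [reconstruct_3d()]).
#' @param min_focus_px minimum largest-slice area in pixels.
#' @return filtered list of `focus_3d`.
#' @export
discard_small_foci <- function(foci, min_focus_px = 5L) {
  keep <- Filter(function(f)
    max(vapply(f$members, function(m) m$area_px, numeric(1))) >=
      min_focus_px, foci)
  for (i in seq_along(keep)) keep[[i]]$focus_id <- i
  keep
}
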