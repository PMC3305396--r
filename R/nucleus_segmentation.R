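#' Segment nuclei from the nuclear-channel stack
#'
#' Computes the maximum-intensity projection of the nuclear (DAPI) channel,
#' thresholds it with [otsu_threshold()] on its gray-level histogram, labels
#' the 8-connected foreground components by sequential region labelling, and
#' materialises each component as a `nucleus_region`. Components smaller than
#' `min_nucleus_px` pixels (strictly) or whose mask touches any image edge
#' are flagged excluded (`too_small` / `touches_boundary`); the remaining
#' nuclei are labelled `1..K` in raster-scan order of their first pixel.
#'
#' The single 2D mask derived from the MIP is used for every slice of the
#' focus channel (see [crop_nucleus()]): segmenting on the composite image
#' avoids false positives on slices that contain only noise.
#'
#' @param nuclear_stack an [image_stack()] with `channel_tag = "nuclear"`
#'   (the tag is not enforced).
#' @param min_nucleus_px exclusion bound: regions with `area_px <
#'   min_nucleus_px` are excluded; a region of exactly `min_nucleus_px`
#'   pixels is retained.
#' @return list of `nucleus_region` objects (excluded ones carry label
#'   `NA` and their `exclusion_reason`); empty list with a warning when the
#'   MIP histogram is degenerate (all pixels identical). The MIP mask is
#'   attached as attribute `"otsu_mask"`, the MIP as `"mip"`.
#' @export
segment_nuclei <- function(nuclear_stack, min_nucleus_px = 1000L) {
  mip <- max_intensity_projection(nuclear_stack)
  h <- pixel_histogram(as.numeric(mip))
  t <- tryCatch(otsu_threshold(h), error = function(e) NULL)
  if (is.null(t)) {
    warning("degenerate nuclear histogram (all pixels identical): no nuclei",
            call. = FALSE)
    return(structure(list(), otsu_mask = matrix(FALSE, nrow(mip), ncol(mip)),
                     mip = mip))
  }
  mask <- mip > t
  lab <- label_regions(mask)
  regions <- vector("list", lab$count)
  pixel_sets <- component_pixel_sets(lab$labels, lab$count)
  nr <- nrow(mask); nc <- ncol(mask)
  next_label <- 0L
  for (k in seq_len(lab$count)) {
    px <- pixel_sets[[k]]          # 0-based (u, v) = (col, row)
    comp_mask <- lab$labels == k
    area <- nrow(px)
    touches <- any(px[, "v"] == 0L) || any(px[, "v"] == nr - 1L) ||
      any(px[, "u"] == 0L) || any(px[, "u"] == nc - 1L)
    reason <- if (area < min_nucleus_px) "too_small"
      else if (touches) "touches_boundary" else "none"
    excluded <- reason != "none"
    if (!excluded) next_label <- next_label + 1L
    bbox <- c(row_min = min(px[, "v"]), col_min = min(px[, "u"]),
              row_max = max(px[, "v"]) + 1L, col_max = max(px[, "u"]) + 1L)
    regions[[k]] <- structure(
      list(label = if (excluded) NA_integer_ else next_label,
           mask = comp_mask,
           bbox = bbox,
           area_px = area,
           centroid_xy = c(x = mean(px[, "u"]), y = mean(px[, "v"])),
           excluded = excluded,
           exclusion_reason = reason),
      class = "nucleus_region")
  }
  structure(regions, otsu_mask = mask, mip = mip)
}

#' @export
print.nucleus_region <- function(x, ...) {
  cat(sprintf(
    "nucleus_region %s: area %d px, centroid (%.1f, %.1f), %s\n",
    ifelse(is.na(x$label), "<excluded>", as.character(x$label)),
    x$area_px, x$centroid_xy[1], x$centroid_xy[2],
    if (x$excluded) paste0("excluded (", x$exclusion_reason, ")")
    else "retained"))
  invisible(x)
}

#' Crop one nucleus out of the focus-channel stack
#'
#' Crops every slice of `focus_stack` to the nucleus bounding box (padded by
#' `pad_px`, clamped to the frame) and zeroes every pixel outside the nucleus
#' mask, so all information from outside the nucleus is removed before focus
#' detection.
#'
#' @param focus_stack an [image_stack()] of the focus channel, same frame as
#'   the segmentation MIP.
#' @param nucleus a non-excluded `nucleus_region` from [segment_nuclei()].
#' @param pad_px extra pixels around the bounding box (clamped to the image).
#' @return list with `stack` (cropped, masked [image_stack()]), `mask` (the
#'   cropped nucleus mask) and `origin` (0-based `(row_min, col_min)` of the
#'   crop in the full frame).
#' @export
crop_nucleus <- function(focus_stack, nucleus, pad_px = 0L) {
  stopifnot(inherits(focus_stack, "image_stack"),
            inherits(nucleus, "nucleus_region"))
  if (isTRUE(nucleus$excluded))
    stop("cannot crop an excluded nucleus", call. = FALSE)
  d <- dim(focus_stack$slices[[1]])
  if (!identical(dim(nucleus$mask), d))
    stop("nucleus mask frame does not match the focus stack", call. = FALSE)
  pad_px <- max(0L, as.integer(pad_px))
  r0 <- max(0L, nucleus$bbox[["row_min"]] - pad_px)
  c0 <- max(0L, nucleus$bbox[["col_min"]] - pad_px)
  r1 <- min(d[1], nucleus$bbox[["row_max"]] + pad_px)
  c1 <- min(d[2], nucleus$bbox[["col_max"]] + pad_px)
  rows <- (r0 + 1L):r1
  cols <- (c0 + 1L):c1
  mask_crop <- nucleus$mask[rows, cols, drop = FALSE]
  slices <- lapply(focus_stack$slices, function(s) {
    cs <- s[rows, cols, drop = FALSE]
    cs[!mask_crop] <- 0
    cs
  })
  stack <- image_stack(slices, bit_depth = focus_stack$bit_depth,
                       pixel_scale_um = focus_stack$pixel_scale_um,
                       z_step_um = focus_stack$z_step_um,
                       channel_tag = focus_stack$channel_tag,
                       source_path = focus_stack$source_path)
  list(stack = stack, mask = mask_crop, origin = c(row_min = r0, col_min = c0))
}
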