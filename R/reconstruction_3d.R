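#' Centre-containment linking predicate
#'
#' Two per-slice foci on adjacent z-slices belong to the same 3D focus iff
#' the centroid of either one, rounded to the nearest pixel, lies within the
#' binary pixel set of the other. Overlap of footprints alone is not enough:
#' if neither centre falls inside the other region the foci stay separate.
#'
#' @param f1 `slice_focus` at z = N (see [measure_slice_foci()]).
#' @param f2 `slice_focus` at z = N + 1.
#' @return logical.
#' @export
link_predicate <- function(f1, f2) {
  stopifnot(inherits(f1, "slice_focus"), inherits(f2, "slice_focus"))
  if (f1$z_index + 1L != f2$z_index)
    stop("link_predicate requires foci on adjacent z-slices", call. = FALSE)
  centre_in_region(f1$centroid_px, f2$pixels) ||
    centre_in_region(f2$centroid_px, f1$pixels)
}

centre_in_region <- function(centroid_xy, pixels) {
  cu <- round_half_away(centroid_xy[[1L]])
  cv <- round_half_away(centroid_xy[[2L]])
  any(pixels[, 1L] == cu & pixels[, 2L] == cv)
}

#' Link per-slice foci into 3D foci
#'
#' Partitions the slice foci of one nucleus into 3D foci: adjacent-slice
#' pairs satisfying [link_predicate()] are joined and the transitive closure
#' (union-find) of those links forms each `focus_3d`. Foci separated by a
#' z-slice with no linked region are always independent (gaps never bridge).
#' Every slice focus belongs to exactly one 3D focus. Y-junctions (one region
#' linked to two non-mutually-linked regions on the next slice) are merged by
#' the closure and flagged `junction = TRUE` for auditing.
#'
#' @param slice_foci list of `slice_focus` records for one nucleus.
#' @return list of `focus_3d` objects, each with `focus_id` (1..n in order
#'   of first z then raster position), `members` (slice foci ordered by z),
#'   `z_extent` (member count) and `junction`.
#' @export
reconstruct_3d <- function(slice_foci) {
  n <- length(slice_foci)
  if (n == 0L) return(list())
  z <- vapply(slice_foci, function(f) f$z_index, numeric(1))
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  by_z <- split(seq_len(n), z)
  zs <- as.numeric(names(by_z))
  for (k in seq_along(zs)) {
    nxt <- which(zs == zs[k] + 1)
    if (length(nxt) == 0L) next
    for (i in by_z[[k]]) {
      for (j in by_z[[nxt]]) {
        if (link_predicate(slice_foci[[i]], slice_foci[[j]])) {
          ri <- find_root(i); rj <- find_root(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  groups <- split(seq_len(n), root)
  # deterministic ordering: first z, then (y, x) of the first member centroid
  key <- t(vapply(groups, function(idx) {
    i0 <- idx[order(z[idx])][1L]
    c(z[i0], slice_foci[[i0]]$centroid_px[[2L]],
      slice_foci[[i0]]$centroid_px[[1L]])
  }, numeric(3)))
  ord <- order(key[, 1L], key[, 2L], key[, 3L])
  foci <- vector("list", length(groups))
  for (g in seq_along(ord)) {
    idx <- groups[[ord[g]]]
    idx <- idx[order(z[idx])]
    members <- slice_foci[idx]
    junction <- anyDuplicated(z[idx]) > 0L
    foci[[g]] <- structure(
      list(focus_id = g, members = members,
           z_extent = length(members), junction = junction),
      class = "focus_3d")
  }
  foci
}

#' @export
print.focus_3d <- function(x, ...) {
  zr <- range(vapply(x$members, function(f) f$z_index, numeric(1)))
  cat(sprintf("focus_3d %d: %d member slice region(s), z %d..%d%s\n",
              x$focus_id, x$z_extent, zr[1], zr[2],
              if (x$junction) " (junction)" else ""))
  invisible(x)
}

#' Area-weighted 3D centroid of a focus
#'
#' The 3D coordinate of a focus is the mass-weighted mean of its member
#' centroids, with mass = member area (pixel count), converted to
#' micrometres: x and y with `pixel_scale_um`, z (the weighted mean slice
#' index) with `z_step_um`. This equals the plain binary 3D centroid of the
#' union of member pixel sets.
#'
#' @param focus a `focus_3d`.
#' @param calibration list with `pixel_scale_um` and `z_step_um`.
#' @return `c(x_um, y_um, z_um)`.
#' @export
weighted_centroid_3d <- function(focus,
                                 calibration = list(pixel_scale_um = 0.07,
                                                    z_step_um = 0.5)) {
  stopifnot(inherits(focus, "focus_3d"), length(focus$members) >= 1L)
  w <- vapply(focus$members, function(f) f$area_px, numeric(1))
  x <- vapply(focus$members, function(f) f$centroid_px[[1L]], numeric(1))
  y <- vapply(focus$members, function(f) f$centroid_px[[2L]], numeric(1))
  z <- vapply(focus$members, function(f) f$z_index, numeric(1))
  sw <- sum(w)
  c(x_um = sum(w * x) / sw * calibration$pixel_scale_um,
    y_um = sum(w * y) / sw * calibration$pixel_scale_um,
    z_um = sum(w * z) / sw * calibration$z_step_um)
}

#' Focus volume, equivalent diameter and size category
#'
#' The primary volume is the voxel sum
#' \eqn{\sum_i A_i \cdot s^2 \cdot \Delta z} over member areas \eqn{A_i}
#' (pixel scale s, z-step \eqn{\Delta z}); a secondary ellipsoid-model volume
#' \eqn{\frac43 \pi r_a r_b \cdot (z_{extent} \Delta z / 2)} (radii of the
#' largest member, in um) is also reported. The size category follows the
#' manual scoring convention based on the most in-focus (largest-area) slice:
#' the equivalent-circle diameter \eqn{d = 2\sqrt{A_{max} s^2/\pi}} is binned
#' as small (d < 0.5 um), medium (0.5 <= d <= 1.0 um) or large (d > 1.0 um).
#'
#' @param focus a `focus_3d`.
#' @param calibration list with `pixel_scale_um` and `z_step_um`.
#' @return list with `volume_um3`, `volume_ellipsoid_um3`,
#'   `max_slice_area_px`, `equivalent_diameter_um`, `size_category`.
#' @export
volume_and_size <- function(focus,
                            calibration = list(pixel_scale_um = 0.07,
                                               z_step_um = 0.5)) {
  stopifnot(inherits(focus, "focus_3d"))
  s <- calibration$pixel_scale_um
  dz <- calibration$z_step_um
  areas <- vapply(focus$members, function(f) f$area_px, numeric(1))
  volume <- sum(areas) * s^2 * dz
  imax <- which.max(areas)
  d <- 2 * sqrt(areas[imax] * s^2 / pi)
  ell <- 4 / 3 * pi * (focus$members[[imax]]$r_a_px * s) *
    (focus$members[[imax]]$r_b_px * s) * (focus$z_extent * dz / 2)
  list(volume_um3 = volume,
       volume_ellipsoid_um3 = ell,
       max_slice_area_px = areas[imax],
       equivalent_diameter_um = d,
       size_category = size_category(d))
}

#' @rdname volume_and_size
#' @param d equivalent diameter in micrometres.
#' @export
size_category <- function(d) {
  ifelse(d < 0.5, "small", ifelse(d <= 1.0, "medium", "large"))
}

#' Pairwise and centre distances between 3D foci
#'
#' Euclidean distances in micrometres between every unordered pair of foci
#' in a nucleus, and from every focus to the nuclear centre. The nuclear
#' centre is the (x, y) centroid of the nucleus MIP mask with z at the
#' midpoint of the acquired z-range.
#'
#' @param centroids_um matrix with columns `x_um`, `y_um`, `z_um`, one row
#'   per focus (e.g. from [weighted_centroid_3d()]).
#' @param nuclear_centre_um `c(x, y, z)` in micrometres.
#' @param nucleus_label label written into the output table.
#' @return data frame with columns `nucleus_label`, `focus_id_a`,
#'   `focus_id_b` (`"CENTRE"` for centre rows) and `distance_um`.
#' @export
pairwise_distances <- function(centroids_um, nuclear_centre_um,
                               nucleus_label = 1L) {
  if (is.null(dim(centroids_um)))
    centroids_um <- matrix(centroids_um, nrow = length(centroids_um) %/% 3L,
                           ncol = 3L, byrow = TRUE)
  n <- nrow(centroids_um)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        rows[[length(rows) + 1L]] <- data.frame(
          nucleus_label = nucleus_label,
          focus_id_a = as.character(i), focus_id_b = as.character(j),
          distance_um = sqrt(sum((centroids_um[i, ] - centroids_um[j, ])^2)),
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      nucleus_label = nucleus_label,
      focus_id_a = as.character(i), focus_id_b = "CENTRE",
      distance_um = sqrt(sum((centroids_um[i, ] - nuclear_centre_um)^2)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(nucleus_label = integer(0),
                      focus_id_a = character(0), focus_id_b = character(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
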