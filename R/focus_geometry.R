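#' Image moments of a binary region
#'
#' A region is a set of pixel coordinates given as a two-column matrix with
#' columns `u` (x, column) and `v` (y, row), 0-based. The raw moment of order
#' (p, q) is \eqn{m_{pq} = \sum_{(u,v) \in R} u^p v^q}; the region area is
#' \eqn{m_{00} = |R|}, the centroid is
#' \eqn{(\bar x, \bar y) = (m_{10}/m_{00}, m_{01}/m_{00})}, and the central
#' moments \eqn{\mu_{pq} = \sum (u - \bar x)^p (v - \bar y)^q} are computed
#' about the real-valued centroid and are translation invariant.
#'
#' @param region two-column numeric matrix of (u, v) pixel coordinates.
#' @param p,q non-negative integer moment orders.
#' @return `raw_moment()`: a number. `centroid()`: `c(x, y)`.
#'   `central_moments()`: `c(mu20, mu02, mu11)`.
#' @export
raw_moment <- function(region, p, q) {
  region <- as_region(region)
  stopifnot(p >= 0L, q >= 0L)
  sum(region[, 1L]^p * region[, 2L]^q)
}

#' @rdname raw_moment
#' @export
centroid <- function(region) {
  region <- as_region(region)
  c(x = mean(region[, 1L]), y = mean(region[, 2L]))
}

#' @rdname raw_moment
#' @export
central_moments <- function(region) {
  region <- as_region(region)
  du <- region[, 1L] - mean(region[, 1L])
  dv <- region[, 2L] - mean(region[, 2L])
  c(mu20 = sum(du * du), mu02 = sum(dv * dv), mu11 = sum(du * dv))
}

as_region <- function(region) {
  if (!is.matrix(region) || ncol(region) != 2L || nrow(region) == 0L)
    stop("region must be a non-empty two-column (u, v) matrix", call. = FALSE)
  region
}

#' Moment-ellipse parameters of a region
#'
#' From the second-order central moments, the eigenvalues
#' \eqn{\lambda_{1,2} = (\mu_{20} + \mu_{02} \pm \sqrt{(\mu_{20}-\mu_{02})^2 +
#' 4\mu_{11}^2}) / 2} of the moment matrix give the best-fit ellipse:
#' orientation \eqn{\theta = \frac12 \operatorname{atan2}(2\mu_{11},
#' \mu_{20}-\mu_{02})} (angle between the x-axis and the major axis, in
#' radians, \eqn{\theta = 0} for symmetric regions), eccentricity ratio
#' \eqn{Ecc = \lambda_1/\lambda_2 \ge 1} (note: the eigenvalue ratio, equal
#' to the squared axis ratio, not the conic eccentricity in \[0,1)), and
#' major/minor radii \eqn{r_a = 2\sqrt{\lambda_1/m_{00}}},
#' \eqn{r_b = 2\sqrt{\lambda_2/m_{00}}} in pixels. A rendered filled ellipse
#' of semi-axes (a, b) recovers \eqn{r_a \approx a}, \eqn{r_b \approx b}.
#'
#' Degenerate regions (\eqn{\lambda_2 = 0}: single pixels or perfect lines)
#' report `ecc_ratio = Inf` and `r_b = 0` without error.
#'
#' @param mu20,mu02,mu11 second-order central moments (see
#'   [central_moments()]).
#' @param area region area \eqn{m_{00}} (>= 1).
#' @return list with `theta_rad`, `ecc_ratio`, `axis_ratio` (`r_a / r_b`),
#'   `r_a`, `r_b` (pixels).
#' @export
ellipse_params <- function(mu20, mu02, mu11, area) {
  stopifnot(area >= 1)
  disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  l2 <- max(l2, 0)   # guard tiny negative round-off
  theta <- if (mu11 == 0 && mu20 == mu02) 0 else
    0.5 * atan2(2 * mu11, mu20 - mu02)
  r_a <- 2 * sqrt(l1 / area)
  r_b <- 2 * sqrt(l2 / area)
  eps <- .Machine$double.eps * max(1, l1)
  ecc <- if (l2 <= eps) Inf else l1 / l2
  axis_ratio <- if (r_b <= 0) Inf else r_a / r_b
  list(theta_rad = theta, ecc_ratio = ecc, axis_ratio = axis_ratio,
       r_a = r_a, r_b = r_b)
}

#' Measure per-slice foci from binary masks
#'
#' Labels each per-slice binary focus mask (8-connected) and computes, for
#' every connected region, the full set of moment descriptors plus raw-channel
#' intensity statistics. Intensities are measured on the unfiltered focus
#' channel within the region.
#'
#' @param binary_masks list of per-slice logical matrices (z order).
#' @param raw_stack the matching cropped raw [image_stack()] of the focus
#'   channel (same dimensions and z order).
#' @param nucleus_label integer label carried through to the output.
#' @return list of `slice_focus` records; each has `nucleus_label`,
#'   `z_index` (0-based), `pixels` (the (u, v) coordinate matrix), `area_px`,
#'   `centroid_px`, `mu20`, `mu02`, `mu11`, `theta_rad`, `ecc_ratio`,
#'   `axis_ratio`, `r_a_px`, `r_b_px`, `mean_intensity`,
#'   `integrated_intensity`.
#' @export
measure_slice_foci <- function(binary_masks, raw_stack, nucleus_label = 1L) {
  stopifnot(is.list(binary_masks))
  raw_slices <- if (inherits(raw_stack, "image_stack")) raw_stack$slices
    else raw_stack
  if (length(raw_slices) != length(binary_masks))
    stop("masks and raw stack must have the same number of slices",
         call. = FALSE)
  out <- list()
  for (z in seq_along(binary_masks)) {
    m <- mask_as_logical(binary_masks[[z]])
    if (!identical(dim(m), dim(raw_slices[[z]])))
      stop("mask and raw slice dimensions differ at z ", z - 1L,
           call. = FALSE)
    if (!any(m)) next
    lab <- label_regions(m)
    sets <- component_pixel_sets(lab$labels, lab$count)
    for (k in seq_len(lab$count)) {
      px <- sets[[k]]
      ctr <- centroid(px)
      mu <- central_moments(px)
      ell <- ellipse_params(mu[["mu20"]], mu[["mu02"]], mu[["mu11"]],
                            nrow(px))
      vals <- raw_slices[[z]][cbind(px[, "v"] + 1L, px[, "u"] + 1L)]
      out[[length(out) + 1L]] <- structure(
        list(nucleus_label = nucleus_label,
             z_index = z - 1L,
             pixels = px,
             area_px = nrow(px),
             centroid_px = ctr,
             mu20 = mu[["mu20"]], mu02 = mu[["mu02"]], mu11 = mu[["mu11"]],
             theta_rad = ell$theta_rad,
             ecc_ratio = ell$ecc_ratio,
             axis_ratio = ell$axis_ratio,
             r_a_px = ell$r_a, r_b_px = ell$r_b,
             mean_intensity = mean(vals),
             integrated_intensity = sum(vals)),
        class = "slice_focus")
    }
  }
  out
}
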