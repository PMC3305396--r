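# Shared in-code fixtures: small, fast synthetic stacks for unit tests.
# Acceptance tests use the full-size study conditions instead.

small_shape <- c(9L, 192L, 192L)

small_truth <- function(K, seed, shape = small_shape,
                        semi_axes_px = c(50, 62), ...) {
  sample_ground_truth(shape = shape, foci_per_nucleus = K,
                      semi_axes_px = semi_axes_px, seed = seed, ...)
}

# render + segment + return the pieces most tests need
small_field <- function(K = 3L, seed = 42L, shape = small_shape, ...) {
  truth <- small_truth(K, seed, shape = shape, ...)
  rendered <- render_field(truth, shape)
  regions <- segment_nuclei(rendered$nuclear)
  kept <- Filter(function(r) !r$excluded, regions)
  list(truth = truth, nuclear = rendered$nuclear, focus = rendered$focus,
       regions = regions, nucleus = kept[[1]])
}

disc_mask <- function(nr, nc, cx, cy, r) {
  x <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  y <- matrix(rep(0:(nr - 1L), nc), nr, nc)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# minimal hand-built slice_focus for linking tests
make_slice_focus <- function(pixels, z, nucleus_label = 1L, area = NULL) {
  px <- pixels
  colnames(px) <- c("u", "v")
  structure(list(
    nucleus_label = nucleus_label, z_index = z, pixels = px,
    area_px = if (is.null(area)) nrow(px) else area,
    centroid_px = c(x = mean(px[, 1]), y = mean(px[, 2])),
    mu20 = 0, mu02 = 0, mu11 = 0, theta_rad = 0, ecc_ratio = 1,
    axis_ratio = 1, r_a_px = 0, r_b_px = 0,
    mean_intensity = 0, integrated_intensity = 0),
    class = "slice_focus")
}

# logical mask -> 0-based (u, v) pixel matrix
as_region_px <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(u = idx[, 2] - 1L, v = idx[, 1] - 1L)
}

# containment test between two slice foci ignoring z adjacency
link_predicate_same_z_ok <- function(f1, f2) {
  inside <- function(ctr, px)
    any(px[, 1] == floor(ctr[[1]] + 0.5) & px[, 2] == floor(ctr[[2]] + 0.5))
  inside(f1$centroid_px, f2$pixels) || inside(f2$centroid_px, f1$pixels)
}

zeros_stack <- function(nslices, nr, nc, ...) {
  image_stack(replicate(nslices, matrix(0, nr, nc), simplify = FALSE), ...)
}
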