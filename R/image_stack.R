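#' Construct an image stack
#'
#' An `image_stack` is an ordered z-series of 2D grayscale slices for one
#' channel of one field of view, together with its physical calibration.
#' Slice order corresponds to monotonically increasing z; all slices share the
#' same dimensions; pixel values are non-negative integers that fit within
#' `bit_depth`.
#'
#' Pixels are stored as base R matrices indexed `[row, col]`. All pixel
#' coordinates reported by the package are 0-based `(x, y) = (col, row)`;
#' z index 0 is the first slice. Conversion to micrometres happens only in
#' reporting and 3D geometry, using `pixel_scale_um` (x/y) and `z_step_um`.
#'
#' @param slices list of numeric matrices, all with identical dimensions.
#' @param bit_depth integer in 8..16; pixel values must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_scale_um micrometres per pixel in x and y (> 0).
#' @param z_step_um micrometres between consecutive slices (> 0).
#' @param channel_tag `"nuclear"` or `"focus"`.
#' @param source_path provenance string (folder the stack was read from).
#' @return an object of class `image_stack`.
#' @seealso [read_stack()], [write_stack()], [max_intensity_projection()]
#' @export
image_stack <- function(slices, bit_depth = 14L,
                        pixel_scale_um = 0.07, z_step_um = 0.5,
                        channel_tag = c("focus", "nuclear"),
                        source_path = "<memory>") {
  channel_tag <- match.arg(channel_tag)
  if (!is.list(slices) || length(slices) == 0L)
    stop("'slices' must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(slices, is.matrix, logical(1))))
    stop("every slice must be a matrix", call. = FALSE)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share identical dimensions", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (bit_depth < 8L || bit_depth > 16L)
    stop("'bit_depth' must be in 8..16", call. = FALSE)
  if (!is.numeric(pixel_scale_um) || pixel_scale_um <= 0)
    stop("'pixel_scale_um' must be > 0", call. = FALSE)
  if (!is.numeric(z_step_um) || z_step_um <= 0)
    stop("'z_step_um' must be > 0", call. = FALSE)
  maxv <- 2^bit_depth - 1
  rng <- range(vapply(slices, function(s) range(s), numeric(2)))
  if (rng[1] < 0 || rng[2] > maxv)
    stop("pixel values must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  structure(
    list(slices = slices, bit_depth = bit_depth,
         pixel_scale_um = pixel_scale_um, z_step_um = z_step_um,
         channel_tag = channel_tag, source_path = source_path),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf(
    "image_stack: %d slice(s) of %d x %d (rows x cols), %d-bit, %s channel\n",
    length(x$slices), d[1], d[2], x$bit_depth, x$channel_tag))
  cat(sprintf("  calibration: %.4g um/pixel (x/y), %.4g um z-step\n",
              x$pixel_scale_um, x$z_step_um))
  cat(sprintf("  source: %s\n", x$source_path))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) {
  c(length(x$slices), dim(x$slices[[1]]))
}

#' @export
length.image_stack <- function(x) length(x$slices)
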