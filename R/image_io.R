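#' Read a TIFF z-series from a folder
#'
#' Reads one channel of one field of view stored as single-plane grayscale
#' TIFF files, one file per z-slice, all in one folder. Slices are ordered by
#' the trailing integer in the file name (before the extension), so
#' `f_z00.tif ... f_z21.tif` yields a 22-slice stack. Channels sharing a
#' folder are told apart by a case-insensitive substring of the file name
#' (default `"dapi"` for the nuclear channel, `"rif"` for the focus channel).
#'
#' Plain TIFF series carry no physical metadata, so calibration is supplied by
#' the caller; the defaults are 0.07 um/pixel and 0.5 um z-step, typical for a
#' 100x widefield acquisition.
#'
#' @param folder path containing the TIFF series.
#' @param channel_tag `"nuclear"` or `"focus"`.
#' @param calibration list with `pixel_scale_um` and `z_step_um`.
#' @param pattern case-insensitive substring selecting this channel's files;
#'   `NULL` uses `"dapi"` for nuclear and `"rif"` for focus. Use `""` to take
#'   every TIFF in the folder.
#' @return an [image_stack()].
#' @export
read_stack <- function(folder, channel_tag = c("focus", "nuclear"),
                       calibration = list(pixel_scale_um = 0.07,
                                          z_step_um = 0.5),
                       pattern = NULL) {
  channel_tag <- match.arg(channel_tag)
  if (!dir.exists(folder))
    stop("folder does not exist: ", folder, call. = FALSE)
  if (is.null(pattern))
    pattern <- if (channel_tag == "nuclear") "dapi" else "rif"
  files <- list.files(folder, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  if (nzchar(pattern))
    files <- files[grepl(tolower(pattern), tolower(basename(files)),
                         fixed = TRUE)]
  if (length(files) == 0L)
    stop("no TIFF files matching channel pattern '", pattern,
         "' in ", folder, call. = FALSE)
  files <- files[order(z_suffix(files))]
  planes <- lapply(files, read_tiff_plane)
  dims <- vapply(planes, function(p) dim(p$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions in ", folder, call. = FALSE)
  bit_depth <- max(vapply(planes, function(p) p$bits, integer(1)))
  image_stack(lapply(planes, `[[`, "pixels"), bit_depth = bit_depth,
              pixel_scale_um = calibration$pixel_scale_um,
              z_step_um = calibration$z_step_um,
              channel_tag = channel_tag,
              source_path = normalizePath(folder))
}

# trailing integer before the extension; files without one sort first
z_suffix <- function(files) {
  base <- tools::file_path_sans_ext(basename(files))
  has <- grepl("[0-9]+$", base)
  z <- rep(-Inf, length(files))
  z[has] <- as.numeric(regmatches(base, regexpr("[0-9]+$", base)))
  z
}

read_tiff_plane <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop("RGB/multi-sample TIFF not supported: ", path, call. = FALSE)
  }
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(img) > 255) 16L else 8L
  bits <- as.integer(bits)
  if (bits < 8L) bits <- 8L
  list(pixels = matrix(as.numeric(img), nrow(img), ncol(img)), bits = bits)
}

#' Write an image stack as a TIFF z-series
#'
#' Writes one lossless grayscale TIFF per slice into `folder`, named
#' `<prefix><zz>.tif` with a zero-padded z index. Bit depths up to 8 are
#' stored in an 8-bit container, deeper ones (e.g. 14-bit) in a 16-bit
#' container; pixel values are preserved exactly, so [read_stack()] round
#' trips bit-identically.
#'
#' @param stack an [image_stack()].
#' @param folder output folder (created if absent).
#' @param prefix file-name prefix; defaults to `"dapi_z"` or `"rif_z"`
#'   according to the stack's channel so that [read_stack()]'s default
#'   channel patterns find the files again.
#' @return invisibly, the written file paths.
#' @export
write_stack <- function(stack, folder, prefix = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$slices) == 0L) stop("empty slice list", call. = FALSE)
  if (is.null(prefix))
    prefix <- if (stack$channel_tag == "nuclear") "dapi_z" else "rif_z"
  if (!dir.exists(folder) &&
      !dir.create(folder, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create folder: ", folder, call. = FALSE)
  container_bits <- if (stack$bit_depth <= 8L) 8L else 16L
  denom <- 2^container_bits - 1
  n <- length(stack$slices)
  width <- max(2L, nchar(as.character(n - 1L)))
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(folder, sprintf("%s%0*d.tif", prefix, width, i - 1L))
    ok <- tiff::writeTIFF(stack$slices[[i]] / denom, paths[i],
                          bits.per.sample = container_bits,
                          compression = "none", reduce = FALSE)
    if (!isTRUE(ok == 1L)) stop("failed to write ", paths[i], call. = FALSE)
  }
  invisible(paths)
}

#' Maximum-intensity projection
#'
#' Collapses a z-stack into a single 2D image whose each pixel is the maximum
#' over all slices at that position. The MIP of the nuclear channel is the
#' frame in which nuclei are segmented.
#'
#' @param stack an [image_stack()] or a non-empty list of equal-size matrices.
#' @return a matrix with the slice dimensions.
#' @export
max_intensity_projection <- function(stack) {
  slices <- if (inherits(stack, "image_stack")) stack$slices else stack
  if (!is.list(slices) || length(slices) == 0L)
    stop("empty stack", call. = FALSE)
  out <- slices[[1]]
  for (s in slices[-1]) out <- pmax(out, s)
  out
}
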