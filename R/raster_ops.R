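# Small vectorized raster primitives shared by the segmentation and filtering
# stages. All convolutions use reflective (symmetric) border padding so that
# image edges do not generate spurious gradient/Laplacian responses; binary
# morphology pads dilation with background and erosion with foreground so that
# closing never erodes objects at the frame edge and stays idempotent.

# out[r, c] = M[r + dy, c + dx], out-of-range indices replaced by `fill`
shift_pad <- function(M, dy, dx, fill = 0) {
  nr <- nrow(M); nc <- ncol(M)
  ri <- seq_len(nr) + dy
  ci <- seq_len(nc) + dx
  out <- matrix(fill, nr, nc)
  rok <- ri >= 1L & ri <= nr
  cok <- ci >= 1L & ci <= nc
  if (any(rok) && any(cok))
    out[rok, cok] <- M[ri[rok], ci[cok]]
  out
}

# out[r, c] = M[reflect(r + dy), reflect(c + dx)] (symmetric reflection,
# edge row/col duplicated: index 0 -> 1, -1 -> 2, nr+1 -> nr, ...)
shift_reflect <- function(M, dy, dx) {
  nr <- nrow(M); nc <- ncol(M)
  ri <- reflect_index(seq_len(nr) + dy, nr)
  ci <- reflect_index(seq_len(nc) + dx, nc)
  M[ri, ci, drop = FALSE]
}

reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  i <- ifelse(i > n, 2L * n + 1L - i, i)
  pmin(pmax(i, 1L), n)  # guard for offsets beyond one reflection
}

# 2D convolution (correlation with the kernel as written) of a matrix with an
# odd-sized kernel, reflective borders
convolve2d_reflect <- function(M, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  ry <- (kr - 1L) %/% 2L; rx <- (kc - 1L) %/% 2L
  out <- matrix(0, nrow(M), ncol(M))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- kernel[i, j]
      if (w != 0)
        out <- out + w * shift_reflect(M, i - 1L - ry, j - 1L - rx)
    }
  }
  out
}

neighbour_offsets_8 <- cbind(
  dy = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dx = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

binary_dilate3 <- function(B) {
  out <- B
  for (k in seq_len(nrow(neighbour_offsets_8)))
    out <- out | shift_pad(B, neighbour_offsets_8[k, 1L],
                           neighbour_offsets_8[k, 2L], fill = FALSE)
  out
}

binary_erode3 <- function(B) {
  out <- B
  for (k in seq_len(nrow(neighbour_offsets_8)))
    out <- out & shift_pad(B, neighbour_offsets_8[k, 1L],
                           neighbour_offsets_8[k, 2L], fill = TRUE)
  out
}

binary_close3 <- function(B) binary_erode3(binary_dilate3(B))

#' Label connected components of a binary mask
#'
#' Sequential region labelling by row runs with union-find merging:
#' 8-connected foreground components receive contiguous positive labels
#' 1..count in raster-scan (row-major) order of each component's first pixel;
#' background is 0.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return list with `labels` (integer matrix) and `count`.
#' @export
label_regions <- function(mask) {
  mask <- mask_as_logical(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  runs_by_row <- vector("list", nr)
  nrun <- 0L
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v)) { runs_by_row[[r]] <- integer(0); next }
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    s <- starts[keep]; e <- ends[keep]
    ids <- nrun + seq_along(s)
    nrun <- nrun + length(s)
    run_row <- c(run_row, rep.int(r, length(s)))
    run_s <- c(run_s, s); run_e <- c(run_e, e)
    runs_by_row[[r]] <- ids
  }
  if (nrun == 0L)
    return(list(labels = matrix(0L, nr, nc), count = 0L))
  parent <- seq_len(nrun)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in 2L:nr) {
    cur <- runs_by_row[[r]]; prev <- runs_by_row[[r - 1L]]
    if (length(cur) == 0L || length(prev) == 0L) next
    for (i in cur) {
      # 8-connectivity: runs touch if column spans overlap within +/- 1
      for (j in prev) {
        if (run_s[i] <= run_e[j] + 1L && run_e[i] >= run_s[j] - 1L) {
          ri <- find_root(i); rj <- find_root(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(nrun), find_root, integer(1))
  # contiguous labels in raster-scan order of first pixel = order of the
  # smallest run id in each component
  first_seen <- !duplicated(root)
  lab_of_root <- integer(nrun)
  lab_of_root[root[first_seen]] <- seq_len(sum(first_seen))
  run_lab <- lab_of_root[root]
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(nrun))
    labels[run_row[i], run_s[i]:run_e[i]] <- run_lab[i]
  list(labels = labels, count = max(run_lab))
}

mask_as_logical <- function(mask) {
  if (is.logical(mask)) {
    mask[is.na(mask)] <- FALSE
    return(mask)
  }
  if (is.numeric(mask)) return(mask != 0)
  stop("mask must be logical or numeric", call. = FALSE)
}

# pixel sets of every labelled component as 0-based (u, v) = (x, y) = (col-1,
# row-1) coordinate matrices, ordered by label
component_pixel_sets <- function(labels, count) {
  if (count == 0L) return(list())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nrow(labels))        # 0-based row
  cc <- ((idx - 1L) %/% nrow(labels))       # 0-based col
  ord <- order(lab, rr, cc)
  split_idx <- split(seq_along(ord), lab[ord])
  lapply(seq_len(count), function(k) {
    sel <- ord[split_idx[[as.character(k)]]]
    cbind(u = cc[sel], v = rr[sel])
  })
}
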