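#' Gray-level histograms
#'
#' Histograms used by the threshold selectors have exactly one bin per integer
#' gray level over a contiguous `min..max` range, so no bin width needs
#' tuning and thresholds are exact gray levels. `pixel_histogram()` bins a
#' set of (possibly signed, possibly fractional) pixel values by
#' round-half-away-from-zero to integers over their observed range;
#' `combine_histograms()` adds counts, aligning ranges, which is how stack- and
#' folder-scope histograms are accumulated.
#'
#' @param values numeric vector of pixel values (fractions are rounded
#'   half-away-from-zero).
#' @return a `gl_hist`: list with integer `levels` (contiguous) and numeric
#'   `counts` of equal length.
#' @export
pixel_histogram <- function(values) {
  if (length(values) == 0L) stop("no pixel values", call. = FALSE)
  v <- round_half_away(values)
  lo <- min(v); hi <- max(v)
  counts <- tabulate(v - lo + 1L, nbins = hi - lo + 1L)
  gl_hist(lo:hi, counts)
}

#' @rdname pixel_histogram
#' @param levels contiguous integer gray levels.
#' @param counts non-negative counts, one per level.
#' @export
gl_hist <- function(levels, counts) {
  levels <- as.integer(levels)
  stopifnot(length(levels) == length(counts),
            all(counts >= 0),
            length(levels) == 1L || all(diff(levels) == 1L))
  structure(list(levels = levels, counts = as.numeric(counts)),
            class = "gl_hist")
}

#' @rdname pixel_histogram
#' @param ... `gl_hist` objects to add together.
#' @export
combine_histograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1L && is.list(hs[[1]]) && !inherits(hs[[1]], "gl_hist"))
    hs <- hs[[1]]
  stopifnot(length(hs) >= 1L, all(vapply(hs, inherits, logical(1), "gl_hist")))
  lo <- min(vapply(hs, function(h) h$levels[1L], integer(1)))
  hi <- max(vapply(hs, function(h) h$levels[length(h$levels)], integer(1)))
  counts <- numeric(hi - lo + 1L)
  for (h in hs) {
    i <- h$levels - lo + 1L
    counts[i] <- counts[i] + h$counts
  }
  gl_hist(lo:hi, counts)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' Otsu threshold of a gray-level histogram
#'
#' Returns the gray level `t` maximising the between-class variance
#' \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the split
#' into background (levels \eqn{\le t}) and foreground (levels \eqn{> t}).
#' Pixels strictly above the returned threshold are foreground. When several
#' thresholds attain the maximum, the lowest is returned.
#'
#' @param histogram a `gl_hist` (see [pixel_histogram()]) or a bare numeric
#'   vector of counts for levels `0..length-1`.
#' @return the threshold gray level (integer).
#' @seealso [max_entropy_threshold()] for the Kapur selector used on the
#'   focus channel.
#' @export
otsu_threshold <- function(histogram) {
  h <- as_gl_hist(histogram)
  nz <- which(h$counts > 0)
  if (length(nz) < 2L)
    stop("degenerate histogram: fewer than two populated gray levels",
         call. = FALSE)
  p <- h$counts / sum(h$counts)
  lev <- as.numeric(h$levels)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * lev)
  mu_t <- mu0[length(mu0)]
  # candidates: both classes non-empty
  n <- length(p)
  cand <- which(w0 > 0 & w0 < 1)
  cand <- cand[cand < n]
  sigma_b <- (mu_t * w0[cand] - mu0[cand])^2 / (w0[cand] * (1 - w0[cand]))
  h$levels[cand[which.max(sigma_b)]]
}

#' Maximum-entropy (Kapur) threshold of a gray-level histogram
#'
#' Returns the gray level `t` maximising the sum of Shannon entropies of the
#' background (levels \eqn{\le t}) and foreground (levels \eqn{> t}) gray
#' level distributions. This is the selector applied to the stack-global
#' histogram of the filtered focus channel: accumulating all slices into one
#' histogram makes the noise and signal classes more distinct and prevents
#' noise from being segmented as signal in slices that contain no true foci.
#' Ties return the lowest maximising level.
#'
#' @inheritParams otsu_threshold
#' @return the threshold gray level (integer).
#' @export
max_entropy_threshold <- function(histogram) {
  h <- as_gl_hist(histogram)
  nz <- which(h$counts > 0)
  if (length(nz) < 2L)
    stop("degenerate histogram: fewer than two populated gray levels",
         call. = FALSE)
  p <- h$counts / sum(h$counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(-plogp)            # partial entropy sums
  P_tot <- P[length(P)]
  S_tot <- S[length(S)]
  n <- length(p)
  cand <- which(P > 0 & P < 1)
  cand <- cand[cand < n]
  Pb <- P[cand]; Pf <- 1 - Pb
  Hb <- log(Pb) + S[cand] / Pb
  Hf <- log(Pf) + (S_tot - S[cand]) / Pf
  h$levels[cand[which.max(Hb + Hf)]]
}

as_gl_hist <- function(histogram) {
  if (inherits(histogram, "gl_hist")) return(histogram)
  if (is.numeric(histogram))
    return(gl_hist(seq_along(histogram) - 1L, histogram))
  stop("histogram must be a gl_hist or a numeric count vector", call. = FALSE)
}
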