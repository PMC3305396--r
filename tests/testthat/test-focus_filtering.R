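test_that("pre-smoothing is the documented 3x3 mean with reflective borders", {
  m <- matrix(stats::runif(63, 0, 100), 7, 9)
  expect_identical(presmooth(m, 0L), m)

  # single bright pixel spreads to value/9 at the centre
  p <- matrix(0, 9, 9); p[5, 5] <- 100
  sm <- presmooth(p, 1L)
  expect_equal(sm[5, 5], 100 / 9)
  expect_equal(sm[4, 4], 100 / 9)
  expect_equal(sm[5, 7], 0)
  expect_equal(sum(sm), 100)   # reflective borders conserve mass away from edges

  # constants are preserved for any iteration count
  flat <- matrix(42, 6, 6)
  expect_equal(presmooth(flat, 4L), flat)
})

test_that("Laplacian turns peaks into troughs and applies the offset and clamp", {
  flat <- matrix(7, 8, 8)
  expect_equal(laplacian(flat, "low", 1500), matrix(1500, 8, 8))
  expect_equal(laplacian(flat, "medium", 1500), matrix(1500, 8, 8))
  expect_equal(laplacian(flat, "high", 1500), matrix(1500, 8, 8))

  # single-pixel peak of height h: centre 1500 - 4h, 4-neighbours 1500 + h
  h <- 100
  p <- matrix(0, 9, 9); p[5, 5] <- h
  lp <- laplacian(p, "low", 1500)
  expect_equal(lp[5, 5], 1500 - 4 * h)
  expect_equal(lp[4, 5], 1500 + h)
  expect_equal(lp[5, 4], 1500 + h)
  expect_equal(lp[4, 4], 1500)

  # clamp at zero warns
  p[5, 5] <- 1000
  expect_warning(lp <- laplacian(p, "low", 1500), "clamped")
  expect_equal(lp[5, 5], 0)

  # a Gaussian blob's minimum lands at the blob centre
  g <- outer(seq(-8, 8), seq(-8, 8),
             function(y, x) 500 * exp(-(x^2 + y^2) / (2 * 2.5^2)))
  lg <- laplacian(g, "medium", 1500)
  expect_equal(which(lg == min(lg)), which.max(g))
})

test_that("Crimmins filter matches a direct loop implementation and damps speckle", {
  m <- matrix(stats::runif(49, 0, 20), 7, 7)
  expect_identical(crimmins(m, 0L), m)
  set.seed(7)
  for (i in 1:3) {
    m <- matrix(sample(0:30, 81, TRUE), 9, 9)
    expect_equal(crimmins(m, 1L), oracle_crimmins(m, 1L))
  }
  expect_equal(crimmins(m, 2L), oracle_crimmins(m, 2L))

  # salt pixel amplitude decreases strictly per iteration until ~flat
  field <- matrix(10, 11, 11); field[6, 6] <- 10 + 12
  amp <- function(x) max(x) - 10
  prev <- amp(field)
  cur <- field
  for (i in 1:10) {
    if (prev <= 1) break
    cur <- crimmins(cur, 1L)
    expect_lt(amp(cur), prev)
    prev <- amp(cur)
  }
  expect_lte(prev, 1)

  # the filter is a bounded, flat-preserving operator: constants are fixed
  # points and output never leaves the input range (the sequential
  # directional passes are not exactly reflection-symmetric, so symmetry of
  # the input is only preserved approximately)
  flat <- matrix(13, 8, 8)
  expect_identical(crimmins(flat, 3L), flat)
  sym <- matrix(5, 9, 9); sym[4:6, 4:6] <- 5 + 7
  out <- crimmins(sym, 1L)
  expect_gte(min(out), 5)
  expect_lte(max(out), 12)
})

test_that("global histogram accumulates in-mask pixels with stack/folder equivalence", {
  s1 <- matrix(1:12, 3, 4)
  s2 <- matrix(12:1, 3, 4)
  mask <- matrix(TRUE, 3, 4); mask[1, 1] <- FALSE
  h_stack <- build_global_histogram(list(s1, s2), "stack", mask)
  h_folder <- build_global_histogram(list(list(s1, s2)), "folder", list(mask))
  expect_identical(h_stack, h_folder)
  # masked-out pixels contribute nothing
  direct <- pixel_histogram(c(s1[mask], s2[mask]))
  expect_identical(h_stack, direct)
  expect_error(build_global_histogram(list(s1), "stack",
                                      matrix(TRUE, 2, 2)), "align")
})

test_that("binarisation + 3x3 closing fills one-pixel gaps and is idempotent", {
  ring <- disc_mask(11, 11, 5, 5, 2.3) & !disc_mask(11, 11, 5, 5, 0.5)
  expect_false(ring[6, 6])
  closed <- binarize_and_close(ring * 10, 5)
  expect_true(closed[6, 6])
  expect_identical(rifquant:::binary_close3(closed), closed)

  none <- binarize_and_close(matrix(0, 6, 6), 5)
  expect_false(any(none))

  # polarity flag flips the focus side
  m <- matrix(0, 9, 9); m[5, 5] <- 10
  above <- binarize_and_close(m, 5)
  expect_identical(which(above), which(m == 10))
  below <- binarize_and_close(m, 5, polarity_inverted = FALSE)
  expect_true(all(below))   # single hole filled by the closing
})

test_that("detection finds the planted foci, is deterministic, and reports sham as empty", {
  f <- small_field(K = 5L, seed = 21L)
  crop <- crop_nucleus(f$focus, f$nucleus)
  det1 <- detect_foci_masks(crop$stack, crop$mask)
  det2 <- detect_foci_masks(crop$stack, crop$mask)
  expect_identical(det1$masks, det2$masks)   # bit-identical rerun

  sf <- measure_slice_foci(det1$masks, crop$stack)
  foci <- discard_small_foci(reconstruct_3d(sf), 5L)
  expect_length(foci, 5L)

  sham <- small_field(K = 0L, seed = 22L)
  scrop <- crop_nucleus(sham$focus, sham$nucleus)
  expect_warning(sdet <- detect_foci_masks(scrop$stack, scrop$mask),
                 "no foci|no signal")
  expect_false(any(vapply(sdet$masks, any, logical(1))))
})

test_that("salt-and-pepper component count is non-increasing in pre-smoothing iterations", {
  f <- small_field(K = 4L, seed = 31L)
  crop <- crop_nucleus(f$focus, f$nucleus)
  gm <- rifquant:::guard_mask(crop$mask, 4L)
  # threshold and count directly (no signal-presence gating) so the effect
  # of the smoothing alone is visible
  singles <- function(pre) {
    st <- filter_settings(pre_iterations = pre, post_iterations = 0L,
                          mask_guard_px = 4L)
    filt <- lapply(crop$stack$slices, rifquant:::focus_response,
                   settings = st)
    h <- build_global_histogram(filt, "stack", gm)
    med <- rifquant:::hist_location_scale(h)[["median"]]
    keep <- h$levels >= med
    thr <- max_entropy_threshold(gl_hist(h$levels[keep], h$counts[keep]))
    sum(vapply(filt, function(s) {
      lab <- label_regions(binarize_and_close(s, thr) & gm)
      if (lab$count == 0L) return(0L)
      sum(tabulate(lab$labels[lab$labels > 0L], lab$count) == 1L)
    }, integer(1)))
  }
  counts <- vapply(c(0L, 1L, 3L), singles, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
})

test_that("stack-global thresholding beats per-slice thresholds on focus-free slices", {
  # foci confined to the lower half of the stack; upper slices are noise-only
  truth <- small_truth(0L, seed = 77L)
  nuc <- truth$nuclei[[1]]
  for (k in 1:4) {
    ang <- 2 * pi * k / 4
    truth$foci[[k]] <- list(
      nucleus_index = 1L,
      centre_3d_px = c(nuc$centre_px[1] + 25 * cos(ang),
                       nuc$centre_px[2] + 20 * sin(ang), 2),
      sigma_xy_px = fwhm_to_sigma_px(0.7), sigma_z_slices = 1,
      peak_intensity = 10000)
  }
  rendered <- render_field(truth, small_shape)
  region <- Filter(function(r) !r$excluded,
                   segment_nuclei(rendered$nuclear))[[1]]
  crop <- crop_nucleus(rendered$focus, region)
  settings <- filter_settings()
  gmask <- rifquant:::guard_mask(crop$mask, settings$mask_guard_px)
  det <- detect_foci_masks(crop$stack, crop$mask, settings)
  empty_slices <- 8:9   # blobs at z = 2 with sigma_z 1 vanish well before z 7
  n_components <- function(masks, zs)
    sum(vapply(zs, function(z) label_regions(masks[[z]])$count, integer(1)))
  global_fp <- n_components(det$masks, empty_slices)

  per_slice_fp <- sum(vapply(empty_slices, function(z) {
    resp <- det$filtered[[z]]
    h <- build_global_histogram(list(resp), "stack", gmask)
    keep <- h$levels >= stats::median(resp[gmask])
    t_slice <- max_entropy_threshold(gl_hist(h$levels[keep], h$counts[keep]))
    label_regions(binarize_and_close(resp, t_slice) & gmask)$count
  }, integer(1)))
  expect_lte(global_fp, per_slice_fp)
  expect_gt(per_slice_fp, 0)
})
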