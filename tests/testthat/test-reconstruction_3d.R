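test_that("centre-containment predicate follows the overlap rules", {
  lower <- make_slice_focus(as_region_px(disc_mask(24, 24, 11, 11, 4)), 0L)
  upper_in <- make_slice_focus(as_region_px(disc_mask(24, 24, 13, 11, 4)), 1L)
  expect_true(link_predicate(lower, upper_in))       # centre falls inside

  a <- make_slice_focus(as_region_px(disc_mask(24, 24, 9, 11, 3)), 0L)
  b <- make_slice_focus(as_region_px(disc_mask(24, 24, 14, 11, 3)), 1L)
  expect_true(nrow(merge(as.data.frame(a$pixels),
                         as.data.frame(b$pixels))) > 0)  # footprints overlap
  expect_false(link_predicate(a, b))                 # but centres are outside

  far <- make_slice_focus(cbind(20:21, 20), 1L)
  expect_false(link_predicate(lower, far))           # disjoint footprints
  expect_error(link_predicate(lower, make_slice_focus(cbind(1, 1), 2L)),
               "adjacent")
})

test_that("canonical linking cases reconstruct to 1, 2 and 2 foci", {
  cases <- render_fig4_cases()
  for (nm in names(cases)) {
    case <- cases[[nm]]
    nr <- nrow(case$masks[[1]])
    raw <- zeros_stack(length(case$masks), nr, ncol(case$masks[[1]]),
                       bit_depth = 8)
    foci <- reconstruct_3d(measure_slice_foci(case$masks, raw))
    expect_length(foci, case$expected_count)
  }
})

test_that("transitive closure partitions slice foci and matches a union-find oracle", {
  # three coaxial discs -> one focus spanning three slices
  discs <- lapply(0:2, function(z)
    make_slice_focus(as_region_px(disc_mask(20, 20, 10, 10, 4)), z))
  foci <- reconstruct_3d(discs)
  expect_length(foci, 1L)
  expect_equal(foci[[1]]$z_extent, 3L)

  # Y junction: one lower disc containing the centres of two upper discs
  base <- make_slice_focus(as_region_px(disc_mask(24, 24, 11, 11, 7)), 0L)
  up1 <- make_slice_focus(as_region_px(disc_mask(24, 24, 8, 11, 2)), 1L)
  up2 <- make_slice_focus(as_region_px(disc_mask(24, 24, 14, 11, 2)), 1L)
  expect_false(link_predicate_same_z_ok(up1, up2))
  y <- reconstruct_3d(list(up1, base, up2))
  expect_length(y, 1L)
  expect_true(y[[1]]$junction)
  expect_equal(y[[1]]$z_extent, 3L)

  # random stacks of small discs: partition property + z-reversal invariance
  set.seed(17)
  for (i in 1:10) {
    sf <- list()
    for (z in 0:4) {
      for (k in seq_len(sample(0:3, 1))) {
        cx <- sample(4:20, 1); cy <- sample(4:20, 1)
        sf[[length(sf) + 1L]] <- make_slice_focus(
          as_region_px(disc_mask(25, 25, cx, cy, sample(2:4, 1))), z)
      }
    }
    if (length(sf) == 0L) next
    foci <- reconstruct_3d(sf)
    expect_equal(sum(vapply(foci, function(f) length(f$members), integer(1))),
                 length(sf))
    # reversing the z order must produce the same grouping sizes
    zmax <- max(vapply(sf, function(f) f$z_index, numeric(1)))
    rev_sf <- lapply(sf, function(f) { f$z_index <- zmax - f$z_index; f })
    rev_foci <- reconstruct_3d(rev_sf)
    expect_setequal(
      vapply(foci, function(f) length(f$members), integer(1)),
      vapply(rev_foci, function(f) length(f$members), integer(1)))
  }
})

test_that("area-weighted 3D centroid follows the mass-weighted mean", {
  cal <- list(pixel_scale_um = 0.07, z_step_um = 0.5)
  single <- structure(list(
    focus_id = 1L, z_extent = 1L, junction = FALSE,
    members = list(make_slice_focus(cbind(10, 12), 6L))), class = "focus_3d")
  expect_equal(weighted_centroid_3d(single, cal),
               c(x_um = 10 * 0.07, y_um = 12 * 0.07, z_um = 6 * 0.5))

  m1 <- make_slice_focus(as_region_px(disc_mask(30, 30, 10, 10, 3)), 4L)
  m1$area_px <- 30
  m2 <- make_slice_focus(as_region_px(disc_mask(30, 30, 10, 10, 2)), 5L)
  m2$area_px <- 10
  f <- structure(list(focus_id = 1L, members = list(m1, m2), z_extent = 2L,
                      junction = FALSE), class = "focus_3d")
  expect_equal(weighted_centroid_3d(f, cal)[["z_um"]],
               (30 * 4 + 10 * 5) / 40 * 0.5)

  # symmetric areas about a slice put z exactly there
  mm <- lapply(c(3L, 4L, 5L), function(z)
    make_slice_focus(as_region_px(disc_mask(30, 30, 10, 10, 2)), z))
  mm[[1]]$area_px <- 7; mm[[2]]$area_px <- 20; mm[[3]]$area_px <- 7
  sym <- structure(list(focus_id = 1L, members = mm, z_extent = 3L,
                        junction = FALSE), class = "focus_3d")
  expect_equal(weighted_centroid_3d(sym, cal)[["z_um"]], 4 * 0.5)

  # equals the brute-force binary 3D centroid of the union of member pixels
  f2 <- structure(list(focus_id = 1L, z_extent = 2L, junction = FALSE,
                       members = list(
                         make_slice_focus(as_region_px(
                           disc_mask(30, 30, 9, 12, 4)), 2L),
                         make_slice_focus(as_region_px(
                           disc_mask(30, 30, 11, 12, 3)), 3L))),
                  class = "focus_3d")
  vox <- do.call(rbind, lapply(f2$members, function(m)
    cbind(m$pixels, z = m$z_index)))
  expect_equal(unname(weighted_centroid_3d(f2, cal)),
               unname(c(mean(vox[, 1]) * 0.07, mean(vox[, 2]) * 0.07,
                        mean(vox[, 3]) * 0.5)))
})

test_that("volume, equivalent diameter and size bins follow the stated conventions", {
  cal <- list(pixel_scale_um = 0.07, z_step_um = 0.5)
  m <- make_slice_focus(as_region_px(disc_mask(30, 30, 12, 12, 5.58)), 3L)
  m$area_px <- 100
  f <- structure(list(focus_id = 1L, members = list(m), z_extent = 1L,
                      junction = FALSE), class = "focus_3d")
  vs <- volume_and_size(f, cal)
  expect_equal(vs$volume_um3, 100 * 0.07^2 * 0.5)
  expect_equal(vs$equivalent_diameter_um, 2 * sqrt(100 * 0.07^2 / pi))
  expect_equal(vs$size_category, "medium")

  # doubling the pixel scale quadruples the volume
  vs2 <- volume_and_size(f, list(pixel_scale_um = 0.14, z_step_um = 0.5))
  expect_equal(vs2$volume_um3, 4 * vs$volume_um3)

  # bin edges: boundaries belong to medium
  expect_equal(size_category(0.4), "small")
  expect_equal(size_category(0.5), "medium")
  expect_equal(size_category(1.0), "medium")
  expect_equal(size_category(1.5), "large")
  expect_equal(size_category(0.5 - 1e-9), "small")
  expect_equal(size_category(1.0 + 1e-9), "large")
})

test_that("pairwise and centre distances match the brute-force double loop", {
  cent <- rbind(c(0, 0, 0), c(3, 4, 0))
  d <- pairwise_distances(cent, c(0, 0, 0), nucleus_label = 2L)
  expect_equal(d$distance_um[d$focus_id_b == "2"], 5)
  expect_equal(nrow(d), 3L)

  one <- pairwise_distances(rbind(c(1, 2, 2)), c(0, 0, 0))
  expect_equal(nrow(one), 1L)
  expect_equal(one$focus_id_b, "CENTRE")
  expect_equal(one$distance_um, 3)

  set.seed(9)
  cent <- matrix(stats::runif(30, 0, 20), 10, 3)
  centre <- c(5, 5, 2)
  d <- pairwise_distances(cent, centre)
  for (i in 1:9) for (j in (i + 1):10) {
    row <- d[d$focus_id_a == as.character(i) & d$focus_id_b == as.character(j), ]
    expect_equal(row$distance_um, sqrt(sum((cent[i, ] - cent[j, ])^2)))
  }
  expect_equal(nrow(d), 45 + 10)
})
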