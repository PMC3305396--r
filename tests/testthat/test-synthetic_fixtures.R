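test_that("rendering is seed-deterministic and respects the noise model", {
  truth <- small_truth(2L, seed = 3L)
  a <- render_field(truth, small_shape)
  b <- render_field(truth, small_shape)
  expect_identical(a$nuclear$slices, b$nuclear$slices)
  expect_identical(a$focus$slices, b$focus$slices)

  # no foci + no noise -> focus channel is exactly the flat background
  quiet <- ground_truth(
    list(list(centre_px = c(40, 40), semi_axes_px = c(20, 15),
              orientation_rad = 0)),
    noise_model = list(gaussian_sd = 0, poisson = FALSE,
                       background_level = 500))
  rf <- render_field(quiet, c(3L, 96L, 96L))
  for (s in rf$focus$slices) expect_true(all(s == 500))

  # one focus, no noise -> argmax at the focus centre voxel
  one <- ground_truth(
    quiet$nuclei,
    foci = list(list(nucleus_index = 1L, centre_3d_px = c(40, 40, 1),
                     sigma_xy_px = 3, sigma_z_slices = 1,
                     peak_intensity = 4000)),
    noise_model = list(gaussian_sd = 0, poisson = FALSE,
                       background_level = 500))
  rf1 <- render_field(one, c(3L, 96L, 96L))
  peak_slice <- rf1$focus$slices[[2]]
  expect_equal(which(peak_slice == max(peak_slice)),
               which(row(peak_slice) == 41 & col(peak_slice) == 41))
  expect_gt(max(rf1$focus$slices[[2]]), max(rf1$focus$slices[[1]]))
})

test_that("focus centres outside their nucleus are rejected", {
  nuc <- list(list(centre_px = c(30, 30), semi_axes_px = c(10, 8),
                   orientation_rad = 0))
  expect_error(ground_truth(
    nuc, list(list(nucleus_index = 1L, centre_3d_px = c(45, 30, 1),
                   sigma_xy_px = 2, sigma_z_slices = 1,
                   peak_intensity = 100))), "outside")
  expect_error(ground_truth(
    nuc, list(list(nucleus_index = 2L, centre_3d_px = c(30, 30, 1),
                   sigma_xy_px = 2, sigma_z_slices = 1,
                   peak_intensity = 100))), "does not exist")
})

test_that("ground truth serialises to JSON and round-trips losslessly", {
  truth <- small_truth(3L, seed = 8L)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$nuclei, truth$nuclei)
  expect_equal(back$foci, truth$foci)
  expect_equal(back$noise_model, truth$noise_model)
  expect_equal(back$calibration, truth$calibration)
  expect_identical(back$seed, truth$seed)
})

test_that("physical focus size is preserved when resolution doubles", {
  fwhm_width_um <- function(pixel_scale, sigma_px, n = 160L) {
    tr <- ground_truth(
      list(list(centre_px = c(n / 2, n / 2), semi_axes_px = c(n / 3, n / 3),
                orientation_rad = 0)),
      foci = list(list(nucleus_index = 1L,
                       centre_3d_px = c(n / 2, n / 2, 1),
                       sigma_xy_px = sigma_px, sigma_z_slices = 1,
                       peak_intensity = 8000)),
      noise_model = list(gaussian_sd = 0, poisson = FALSE,
                         background_level = 100),
      calibration = list(pixel_scale_um = pixel_scale, z_step_um = 0.5))
    s <- render_field(tr, c(3L, n, n))$focus$slices[[2]] - 100
    sum(s[n / 2 + 1, ] >= max(s) / 2) * pixel_scale
  }
  w1 <- fwhm_width_um(0.07, 5, 160L)
  w2 <- fwhm_width_um(0.035, 10, 320L)
  expect_lt(abs(w2 - w1) / w1, 0.05)
})

test_that("scoring reports perfect recovery, count errors and jitter RMSE correctly", {
  truth <- small_truth(4L, seed = 12L)
  cal <- truth$calibration
  fake_focus <- function(f, id) {
    px_x <- f$centre_3d_px[1]; px_y <- f$centre_3d_px[2]
    structure(list(focus_id = id, z_extent = 1L, junction = FALSE,
                   members = list(make_slice_focus(
                     cbind(round(px_x), round(px_y)), f$centre_3d_px[3],
                     area = 60))),
              class = "focus_3d")
  }
  # exact centroids: zero count error, near-zero RMSE
  det <- lapply(seq_along(truth$foci), function(i) {
    fc <- fake_focus(truth$foci[[i]], i)
    fc$members[[1]]$centroid_px <- c(x = truth$foci[[i]]$centre_3d_px[1],
                                     y = truth$foci[[i]]$centre_3d_px[2])
    fc$members[[1]]$z_index <- truth$foci[[i]]$centre_3d_px[3]
    fc
  })
  sc <- score_against_truth(list(det), truth)
  expect_equal(sc$per_nucleus$count_error, 0L)
  expect_equal(sc$localisation_rmse_um, 0)
  expect_equal(sc$n_missed + sc$n_spurious, 0L)

  # one missing focus -> count error -1
  sc1 <- score_against_truth(list(det[-1]), truth)
  expect_equal(sc1$per_nucleus$count_error, -1L)
  expect_equal(sc1$n_missed, 1L)

  # isotropic jitter of sigma in um -> 3D RMSE ~ sigma * sqrt(3)
  sigma <- 0.1
  grid_truth <- ground_truth(
    list(list(centre_px = c(300, 300), semi_axes_px = c(345, 345),
              orientation_rad = 0)),
    foci = lapply(1:225, function(i) {
      gx <- 60 + 32 * ((i - 1) %% 15); gy <- 60 + 32 * ((i - 1) %/% 15)
      list(nucleus_index = 1L, centre_3d_px = c(gx, gy, 10),
           sigma_xy_px = 2, sigma_z_slices = 1, peak_intensity = 1000)
    }))
  set.seed(99)
  jdet <- lapply(seq_along(grid_truth$foci), function(i) {
    f <- grid_truth$foci[[i]]
    fc <- fake_focus(f, i)
    fc$members[[1]]$centroid_px <-
      c(x = f$centre_3d_px[1] + stats::rnorm(1, 0, sigma / 0.07),
        y = f$centre_3d_px[2] + stats::rnorm(1, 0, sigma / 0.07))
    fc$members[[1]]$z_index <- f$centre_3d_px[3] + stats::rnorm(1, 0, sigma / 0.5)
    fc
  })
  scj <- score_against_truth(list(jdet), grid_truth, match_radius_um = 1)
  expect_equal(scj$n_matched, 225L)
  expect_lt(abs(scj$localisation_rmse_um - sigma * sqrt(3)) / (sigma * sqrt(3)),
            0.15)
})
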