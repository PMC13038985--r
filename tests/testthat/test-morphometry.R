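test_that("local thickness equals the exhaustive sphere oracle", {
  set.seed(31)
  for (trial in 1:8) {
    d <- sample(8:16, 3, replace = TRUE)
    mask <- array(runif(prod(d)) < runif(1, 0.2, 0.5), d)
    tm <- local_thickness(binary_volume(mask, 1))
    expect_equal(tm$values, brute_local_thickness(mask), tolerance = 1e-12)
  }
})

test_that("an isolated void voxel has thickness twice the voxel size", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  tm <- local_thickness(binary_volume(m, 5.8))
  expect_equal(tm$values[3, 3, 3], 2 * 5.8)
  expect_equal(sum(tm$values > 0), 1)
})

test_that("a digitized cylinder recovers its diameter", {
  m <- cylinder_mask(8, 21, 40)
  tm <- local_thickness(binary_volume(m, 1))
  interior <- tm$values[, , 9:32][m[, , 9:32]]  # trim 8 voxels per end
  expect_true(all(abs(interior - 16) <= 1))
  expect_equal(mean(interior), 16, tolerance = 1 / 16)
})

test_that("thickness is monotone under dilation of the void phase", {
  set.seed(5)
  m <- array(runif(12^3) < 0.3, c(12, 12, 12))
  grown <- m
  # dilate by one voxel (6-neighbourhood)
  idx <- which(m, arr.ind = TRUE)
  for (k in 1:3) {
    for (dd in c(-1, 1)) {
      shifted <- idx
      shifted[, k] <- pmin(pmax(shifted[, k] + dd, 1), 12)
      grown[shifted] <- TRUE
    }
  }
  t1 <- local_thickness(binary_volume(m, 1))
  t2 <- local_thickness(binary_volume(grown, 1))
  expect_true(all(t2$values[m] >= t1$values[m] - 1e-12))
})

test_that("roi_porosity is exact integer voxel counting", {
  set.seed(13)
  for (trial in 1:5) {
    d <- c(30, 30, 6)
    bone <- array(runif(prod(d)) < 0.7, d)
    envv <- array(TRUE, d)
    env <- structure(list(voxels = envv, cavity = array(FALSE, d),
                          voxel_size = 1, closing_radius = 0),
                     class = "bone_envelope")
    bv <- binary_volume(bone, 1)
    roi <- list(y0 = 3L, y1 = 20L, x0 = 5L, x1 = 28L, z0 = 2L, z1 = 5L)
    got <- roi_porosity(bv, env, roi)
    sub <- bone[3:20, 5:28, 2:5]
    expect_identical(got, sum(!sub) / length(sub))
  }
  # ROI fully inside solid bone -> 0
  solid <- binary_volume(array(TRUE, c(10, 10, 2)), 1)
  envs <- structure(list(voxels = array(TRUE, c(10, 10, 2)),
                         cavity = array(FALSE, c(10, 10, 2)),
                         voxel_size = 1, closing_radius = 0),
                    class = "bone_envelope")
  expect_identical(roi_porosity(solid, envs), 0)
})

test_that("an ROI that misses the envelope yields NA with a warning", {
  d <- c(10, 10, 2)
  bv <- binary_volume(array(FALSE, d), 1)
  env <- structure(list(voxels = array(FALSE, d), cavity = array(FALSE, d),
                        voxel_size = 1, closing_radius = 0),
                   class = "bone_envelope")
  expect_warning(p <- roi_porosity(bv, env), "NA")
  expect_true(is.na(p))
  expect_error(roi_index(list(y0 = 0, y1 = 5, x0 = 1, x1 = 5, z0 = 1, z1 = 2),
                         d), "outside")
})

test_that("canal histograms are volume percentages that sum to 100", {
  # uniform 30 um map: everything lands in [25, 50)
  vals <- array(0, c(6, 6, 3))
  vals[2:4, 2:4, ] <- 30
  tm <- structure(list(values = vals, voxel_size = 5.8),
                  class = "thickness_map")
  h <- canal_histogram(tm)
  expect_equal(sum(h$volume_percent), 100, tolerance = 1e-9)
  expect_equal(h$volume_percent[h$bin_lower == 25], 100)
  # empty map flags NA
  empty <- structure(list(values = array(0, c(4, 4, 2)), voxel_size = 5.8),
                     class = "thickness_map")
  expect_true(all(is.na(canal_histogram(empty)$volume_percent)))
  expect_true(is.na(mean_canal_diameter(empty)))
  expect_error(canal_histogram(tm, edges = c(10, 20)), "start at 0")
})

test_that("two cylinders of 40 and 80 um bin in a 1:4 volume ratio", {
  # voxel size 1 um so radii 20 and 40 voxels digitize cleanly
  n <- 130
  m <- array(FALSE, c(n, n, 30))
  disk1 <- outer((seq_len(n) - 32)^2, (seq_len(n) - 32)^2, `+`) < 20^2
  disk2 <- outer((seq_len(n) - 85)^2, (seq_len(n) - 85)^2, `+`) < 40^2
  for (z in seq_len(30)) m[, , z] <- disk1 | disk2
  tm <- local_thickness(binary_volume(m, 1))
  h <- canal_histogram(tm)
  expect_equal(sum(h$volume_percent), 100, tolerance = 1e-9)
  p1 <- h$volume_percent[h$bin_lower == 25]
  p2 <- h$volume_percent[h$bin_lower == 75]
  expect_equal(p1 + p2, 100, tolerance = 1e-9)
  expect_equal(p2 / p1, 4, tolerance = 0.05)
  expect_equal(mean_canal_diameter(tm), 72, tolerance = 72 * 0.02)
})

test_that("increasing canal diameters raises both porosity and diameter", {
  # same canal count, larger diameter profile: monotone coupling
  base <- small_phantom_spec(seed = 21, fixed_canal_count = 6)
  wide <- small_phantom_spec(seed = 21, fixed_canal_count = 6,
                             diameter_shaft = 60, diameter_end = 140)
  ph1 <- generate_cortical_phantom(base)
  ph2 <- generate_cortical_phantom(wide)
  poro <- function(ph) sum(ph$truth$label > 1L) / sum(ph$truth$label != 0L)
  dia <- function(ph) {
    with(ph$truth$canals, sum(2 * radius * voxel_count) / sum(voxel_count))
  }
  expect_gt(poro(ph2), poro(ph1))
  expect_gt(dia(ph2), dia(ph1))
  # and the measured thickness map sees it too
  meas <- function(ph) {
    mask <- segment_volume(ph$volume)
    env <- build_envelope(mask, closing_radius = 150)
    mean_canal_diameter(local_thickness(intracortical_void(mask, env)))
  }
  expect_gt(meas(ph2), meas(ph1))
})

test_that("intracortical void excludes components open to cavity or exterior", {
  d <- c(30, 30, 2)
  bone <- array(FALSE, d)
  bone[5:26, 5:26, ] <- TRUE
  bone[14:17, 14:17, ] <- FALSE   # interior pore (kept)
  bone[5:8, 10:12, ] <- FALSE     # notch open to the exterior (dropped)
  env <- structure(list(voxels = array(FALSE, d), cavity = array(FALSE, d),
                        voxel_size = 1, closing_radius = 0),
                   class = "bone_envelope")
  env$voxels[5:26, 5:26, ] <- TRUE
  void <- intracortical_void(binary_volume(bone, 1), env)
  expect_true(all(void$voxels[14:17, 14:17, ]))
  expect_false(any(void$voxels[5:8, 10:12, ]))
})
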