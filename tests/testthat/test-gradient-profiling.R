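# helper: hand-built envelope object from logical slices
fake_env <- function(envelope, cavity = array(FALSE, dim(envelope)),
                     voxel_size = 1) {
  structure(list(voxels = envelope, cavity = cavity, voxel_size = voxel_size,
                 closing_radius = 0),
            class = "bone_envelope")
}

annulus_stack <- function(n, r_out, r_in, nz, cy = (n + 1) / 2,
                          cx = (n + 1) / 2) {
  r2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  sl <- r2 < r_out^2 & r2 >= r_in^2
  cav <- r2 < r_in^2
  list(env = array(sl, c(n, n, nz)), cav = array(cav, c(n, n, nz)))
}

test_that("slice plans tile the volume at the requested interval", {
  # 50 mm at 1 mm steps -> 51 positions
  v <- binary_volume(array(TRUE, c(2, 2, 500)), 100)
  plan <- plan_slices(v, step = 1000)
  expect_equal(nrow(plan), 51)
  expect_equal(plan$position, seq(0, 50000, by = 1000))
  # 10.5 mm -> 11 positions, edge slabs flagged truncated
  v2 <- binary_volume(array(TRUE, c(2, 2, 105)), 100)
  plan2 <- plan_slices(v2, step = 1000)
  expect_equal(nrow(plan2), 11)
  expect_true(plan2$truncated[1])
  # one-voxel step degenerates to every voxel plane
  v3 <- binary_volume(array(TRUE, c(2, 2, 10)), 100)
  expect_equal(nrow(plan_slices(v3, step = 100)), 11)
  expect_error(plan_slices(v3, step = 10), "at least one voxel")
})

test_that("direction rays start at the envelope centroid", {
  # centred disk: all four boundary hits at equal radius
  a <- annulus_stack(41, 15, 0, 1)
  loc <- locate_directions(a$env[, , 1])
  expect_equal(loc$centroid, c(21, 21))
  hits <- vapply(seq_len(4), function(k) {
    dir <- loc$directions[k, ]
    s <- ray_surface(a$env[, , 1], loc$centroid, dir$dy, dir$dx)
    abs(s - 21)
  }, numeric(1))
  expect_true(all(hits == hits[1]))
  # off-centre annulus: centroid equals the first-moment oracle
  b <- annulus_stack(61, 18, 9, 1, cy = 25, cx = 38)
  loc2 <- locate_directions(b$env[, , 1])
  w <- which(b$env[, , 1], arr.ind = TRUE)
  expect_equal(loc2$centroid, c(mean(w[, 1]), mean(w[, 2])))
  # empty slice: NA rays
  expect_true(all(is.na(locate_directions(matrix(FALSE, 5, 5))$centroid)))
})

test_that("an ellipse's boundary distances scale with its axes", {
  n <- 81
  r2 <- outer(((seq_len(n) - 41) / 30)^2, ((seq_len(n) - 41) / 15)^2, `+`)
  ell <- r2 < 1  # semi-axes 30 (y) and 15 (x)
  loc <- locate_directions(ell)
  sy <- ray_surface(ell, loc$centroid, 1, 0) - 41
  sx <- ray_surface(ell, loc$centroid, 0, 1) - 41
  expect_equal(sy / sx, 2, tolerance = 0.05)
})

test_that("ROI windows anchor at the periosteal surface and stop at air", {
  # flat slab occupying x in [71, 120]: "lateral" (+x) ROIs step inward
  d <- c(41, 140, 3)
  env <- array(FALSE, d)
  env[, 71:120, ] <- TRUE
  rois <- place_rois(fake_env(env, voxel_size = 10), step = 1000,
                     depths = c(250, 500), window = c(200, 250))
  lat <- rois[rois$direction == "lateral", ]
  expect_true(all(lat$valid))
  # depth 250 at 10 um voxels spans the outermost 25 columns [96, 120]
  expect_equal(lat$x1[lat$depth == 250][1], 120)
  expect_equal(lat$x0[lat$depth == 250][1], 96)
  # a depth beyond the slab plus air has no bone in the window
  deep <- place_rois(fake_env(env, voxel_size = 10), step = 1000,
                     depths = 800, window = c(200, 250))
  expect_false(any(deep$valid[deep$direction == "lateral"]))
  expect_match(deep$reason[deep$direction == "lateral"][1], "no bone")
})

test_that("cortical thickness is the ray chord from periosteum to endosteum", {
  # annulus with wall 12 voxels at 100 um voxels = 1.2 mm
  a <- annulus_stack(61, 27, 15, 1)
  for (dn in c("anterior", "posterior", "medial", "lateral")) {
    ct <- cortical_thickness(a$env[, , 1], a$cav[, , 1], dn, 100)
    expect_false(ct$no_cavity)
    expect_equal(ct$thickness_mm, 1.2, tolerance = 0.13)  # within 1.5 voxels
  }
  # solid disk: full chord, flagged
  s <- annulus_stack(61, 20, 0, 1)
  ct <- cortical_thickness(s$env[, , 1], s$cav[, , 1], "lateral", 100)
  expect_true(ct$no_cavity)
  expect_equal(ct$thickness_mm, 2.0, tolerance = 0.1)
})

test_that("profile assembly recovers wall taper and direction averages", {
  ph <- generate_cortical_phantom(small_phantom_spec(seed = 3))
  mask <- segment_volume(ph$volume)
  prof <- assemble_profiles(mask, step = 300, depths = c(100, 200),
                            window = c(300, 100), closing_radius = 150)
  # direction average equals the arithmetic mean of emitted directions
  joined <- dplyr::inner_join(
    prof$directional |>
      dplyr::group_by(position, depth) |>
      dplyr::summarise(m = mean(porosity, na.rm = TRUE), .groups = "drop"),
    prof$radial, by = c("position", "depth"))
  expect_equal(joined$m, joined$porosity, tolerance = 1e-12)
  # thickness profile tracks the quadratic wall: argmax at mid-length,
  # regression of measured on true wall has slope 1
  tm <- prof$thickness_mean
  spec <- ph$truth$spec
  # evaluate the true wall at the centre of each measured slab
  lfrac <- (pmax(tm$position - 150, 0) + pmin(tm$position + 150, spec$length)) /
    2 / spec$length
  truth_mm <- phantom_wall(spec, lfrac) / 1000
  expect_equal(tm$position[which.max(tm$thickness_mm)],
               tm$position[which.max(truth_mm)])
  fit <- lm(tm$thickness_mm ~ truth_mm)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
})

test_that("rotating the volume permutes labels but not the averages", {
  ph <- generate_cortical_phantom(
    small_phantom_spec(seed = 8, length = 600))
  mask <- segment_volume(ph$volume)
  rot <- mask$voxels
  rot <- aperm(rot[dim(rot)[1]:1, , , drop = FALSE], c(2, 1, 3))
  mask_rot <- binary_volume(rot, mask$voxel_size)
  p1 <- assemble_profiles(mask, step = 300, depths = c(100, 200),
                          window = c(300, 100), closing_radius = 150)
  p2 <- assemble_profiles(mask_rot, step = 300, depths = c(100, 200),
                          window = c(300, 100), closing_radius = 150)
  expect_equal(p1$radial$porosity, p2$radial$porosity, tolerance = 1e-12)
  expect_equal(p1$radial$mean_diameter, p2$radial$mean_diameter,
               tolerance = 1e-12)
  # per-direction values are permuted, not equal
  expect_false(isTRUE(all.equal(p1$directional$porosity,
                                p2$directional$porosity)))
})

test_that("an asymmetric phantom dominates in the loaded quadrant", {
  # extra canals forced into the +x (lateral) quadrant
  extra <- data.frame(y = c(-20, 30, 0, -40),
                      x = c(250, 290, 340, 300),
                      radius = 25)
  sp <- phantom_spec(outer_radius = 420, inner_radius = 200, length = 600,
                     voxel_size = 5.8, forced_canals = extra)
  ph <- generate_cortical_phantom(sp)
  mask <- segment_volume(ph$volume)
  prof <- assemble_profiles(mask, step = 600, depths = c(100, 200),
                            window = c(300, 100), closing_radius = 150)
  dirs <- prof$directional |>
    dplyr::group_by(direction) |>
    dplyr::summarise(p = mean(porosity, na.rm = TRUE))
  expect_gt(dirs$p[dirs$direction == "lateral"],
            max(dirs$p[dirs$direction != "lateral"]))
})
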