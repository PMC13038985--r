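test_that("a zero-porosity spec yields a solid shell with no canals", {
  sp <- phantom_spec(outer_radius = 300, wall_mid = 150, wall_end = 120,
                     length = 400, voxel_size = 5.8,
                     porosity_profile = function(l, d, w) 0)
  ph <- generate_cortical_phantom(sp)
  expect_identical(nrow(ph$truth$canals), 0L)
  expect_identical(sum(ph$truth$label > 1L), 0L)
  tp <- true_profile(ph$truth, step = 200, depths = 100, window = c(300, 100),
                     closing_radius = 80)
  expect_true(all(tp$true_porosity[!is.na(tp$true_porosity)] == 0))
})

test_that("a forced single canal is voxelized with exact bookkeeping", {
  # radius 58 um = 10 voxels at 5.8 um, full phantom length
  sp <- phantom_spec(outer_radius = 300, inner_radius = 100, length = 400,
                     voxel_size = 5.8,
                     forced_canals = data.frame(y = 0, x = 200, radius = 58))
  ph <- generate_cortical_phantom(sp)
  tr <- ph$truth
  expect_identical(sum(tr$label == 2L), tr$canals$voxel_count[1])
  # measured shell porosity equals the voxel-count ratio exactly
  shell_poro <- sum(tr$label > 1L) / sum(tr$label != 0L)
  expect_identical(shell_poro,
                   tr$canals$voxel_count[1] / sum(tr$label != 0L))
  # any ROI containing the canal reports true mean diameter 116 um
  tp <- true_profile(tr, step = 400, depths = 250, window = c(500, 250),
                     closing_radius = 80)
  got <- tp$true_mean_diameter[!is.na(tp$true_mean_diameter)]
  expect_true(length(got) > 0)
  expect_true(all(got == 116))
})

test_that("volume-weighted truth diameters follow the d^2 closed form", {
  # two equal-length canals, 40 and 80 um: volume ratio ~ 1:4, weighted
  # mean ~ (40 + 80*4)/5 = 72 um (exact for continuum areas)
  sp <- phantom_spec(outer_radius = 400, inner_radius = 120, length = 200,
                     voxel_size = 5.8,
                     forced_canals = data.frame(y = c(0, 80), x = c(250, -230),
                                                radius = c(20, 40)))
  ph <- generate_cortical_phantom(sp)
  cc <- ph$truth$canals
  v <- cc$voxel_count
  expect_equal(v[2] / v[1], 4, tolerance = 0.05)
  wmean <- sum(2 * cc$radius * v) / sum(v)
  expect_equal(wmean, 72, tolerance = 0.02)
})

test_that("canal placement never overlaps: void volume is the sum of canals", {
  for (seed in 1:3) {
    ph <- generate_cortical_phantom(small_phantom_spec(seed = seed))
    expect_identical(sum(ph$truth$canals$voxel_count),
                     sum(ph$truth$label > 1L))
    # every void voxel belongs to exactly one canal id
    ids <- sort(unique(as.vector(ph$truth$label[ph$truth$label > 1L]))) - 1L
    expect_true(all(ids %in% ph$truth$canals$id))
  }
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- generate_cortical_phantom(small_phantom_spec(seed = 11, noise_sd = 10))
  b <- generate_cortical_phantom(small_phantom_spec(seed = 11, noise_sd = 10))
  c <- generate_cortical_phantom(small_phantom_spec(seed = 12, noise_sd = 10))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$canals, b$truth$canals)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("measured cell porosity tracks the recorded placement targets", {
  # sampling tolerance: realized void fraction within 2 percentage points of
  # the effective per-cell target, per longitudinal band and overall
  for (seed in 1:5) {
    ph <- generate_cortical_phantom(small_phantom_spec(seed = 100 + seed))
    cells <- ph$truth$cells
    expect_true(all(abs(cells$placed_fraction - cells$target_effective) <=
                      0.02 + 1e-12))
    # voxel-counted void fraction inside each placement cell vs its target
    lab <- ph$truth$label
    s <- ph$truth$spec$voxel_size
    d <- dim(lab)
    half <- (d[1] - 1L) / 2
    yc <- (seq_len(d[1]) - (half + 1L)) * s
    rho2 <- outer(yc^2, yc^2, `+`)
    bands <- unique(ph$truth$canals[, c("band", "z0_vox", "z1_vox")])
    for (k in seq_len(nrow(cells))) {
      cl <- cells[k, ]
      zb <- bands[bands$band == cl$band, ]
      if (nrow(zb) == 0) next
      ring <- rho2 >= cl$r_in^2 & rho2 < cl$r_out^2
      slab <- lab[, , zb$z0_vox[1]:zb$z1_vox[1]]
      dim(slab) <- c(d[1] * d[2], dim(slab)[3])
      sel <- slab[as.vector(ring), ]
      meas <- sum(sel > 1L) / length(sel)
      expect_lt(abs(meas - cl$target_effective), 0.02)
    }
  }
})

test_that("infeasible porosity targets fail loudly, naming the cell", {
  sp <- phantom_spec(outer_radius = 420, wall_mid = 240, wall_end = 170,
                     length = 600, voxel_size = 5.8,
                     porosity_shaft = 0.6, porosity_end = 0.6,
                     max_cell_porosity = 0.6, cap_at_packing_limit = FALSE,
                     max_attempts = 100)
  expect_error(generate_cortical_phantom(sp), "packing limit")
})

test_that("too-coarse voxels for the smallest canals fail loudly", {
  sp <- phantom_spec(outer_radius = 2000, wall_mid = 1300, wall_end = 800,
                     length = 400, voxel_size = 30,
                     diameter_shaft = 40, diameter_end = 110)
  expect_error(generate_cortical_phantom(sp), "too coarse")
})

test_that("synthetic stress-strain curves obey the piecewise closed form", {
  # noiseless: sigma(0.04) = 15*0.02 + 1.4*0.02 = 0.328 MPa
  cs <- curve_spec(modulus1_true = 15, modulus2_true = 1.4,
                   breakpoint_strain = 0.02, failure_strain = 0.06,
                   n_points = 301L, noise_sd = 0)
  curve <- generate_stress_strain(cs)
  i <- which.min(abs(curve$strain - 0.04))
  expect_equal(curve$strain[i], 0.04, tolerance = 1e-12)
  expect_equal(curve$stress[i], 0.328, tolerance = 1e-12)
  # degenerate single regime: straight line through the origin, slope 10
  cs2 <- curve_spec(modulus1_true = 10, modulus2_true = 10,
                    breakpoint_strain = 0.02, failure_strain = 0.06,
                    noise_sd = 0)
  curve2 <- generate_stress_strain(cs2)
  pre <- curve2[curve2$strain <= 0.06, ]
  expect_equal(pre$stress, 10 * pre$strain, tolerance = 1e-12)
  # post-peak tail drops by the requested fraction
  expect_equal(min(curve2$stress[curve2$strain > 0.06]),
               max(curve2$stress) * (1 - cs2$peak_stress_drop_fraction),
               tolerance = 1e-12)
})

test_that("curve generation is seed-deterministic and seed-sensitive", {
  cs <- function(seed) curve_spec(noise_sd = 0.01, seed = seed)
  expect_identical(generate_stress_strain(cs(3)), generate_stress_strain(cs(3)))
  expect_false(identical(generate_stress_strain(cs(3))$stress,
                         generate_stress_strain(cs(4))$stress))
})

test_that("curve specs with too few points are rejected", {
  expect_error(curve_spec(n_points = 9), "n_points")
  expect_error(curve_spec(breakpoint_strain = 0.08, failure_strain = 0.06))
})
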