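#' Specify a synthetic cortical-bone phantom
#'
#' Describes a hollow, roughly cylindrical cortical shell pierced by straight,
#' axis-parallel vascular canals whose density and diameter follow prescribed
#' radial (depth from the outer surface) and longitudinal gradients. The
#' default profiles emulate a long-bone diaphysis: low porosity and small
#' canals at mid-shaft, higher porosity and larger canals toward both ends,
#' both increasing from the periosteal surface inward, with a cortical wall
#' that is thickest at mid-shaft.
#'
#' Canals are placed by rejection sampling of non-overlapping cylinders inside
#' (longitudinal band) x (radial ring) cells, so the realized void volume is
#' exactly the sum of per-canal voxel counts and the target porosity of every
#' cell is met to within half a canal cross-section. Intracortical porosity
#' targets are capped at `max_cell_porosity` because non-overlapping disks jam
#' well below dense packing; near the bone ends the measured porosity still
#' rises far above the cap because the thin wall lets deep sampling windows
#' reach the medullary cavity.
#'
#' @param outer_radius Outer (periosteal) radius, um.
#' @param wall_mid,wall_end Cortical wall thickness at mid-shaft and at the
#'   two ends, um. The wall varies quadratically in between. Supplying
#'   `inner_radius` instead fixes a constant wall `outer_radius - inner_radius`.
#' @param inner_radius Optional constant medullary cavity radius, um.
#' @param length Phantom length, um.
#' @param voxel_size Isotropic voxel size, um.
#' @param porosity_shaft,porosity_end Target intracortical void fraction at
#'   mid-shaft / at the ends (axial profile; a radial gradient factor is
#'   applied on top, see `porosity_profile`).
#' @param diameter_shaft,diameter_end Mean canal diameter at mid-shaft / ends, um.
#' @param diameter_cv Coefficient of variation of the log-normal canal
#'   diameter distribution.
#' @param porosity_profile Optional `function(lfrac, depth, wall)` returning
#'   the target void fraction for a cell at longitudinal fraction `lfrac`
#'   (0..1), depth `depth` um from the outer surface, local wall `wall` um.
#'   The default combines the quadratic axial profile with a linear radial
#'   increase (factor 0.7 at the surface to 1.3 at the endosteum), capped at
#'   `max_cell_porosity`.
#' @param diameter_profile Optional `function(lfrac, depth, wall)` returning
#'   the mean canal diameter (um) for a cell; default: quadratic axial profile
#'   times a 0.85-1.15 radial factor.
#' @param ring_width Radial width of placement cells, um.
#' @param band_height Longitudinal height of placement cells, um.
#' @param max_cell_porosity Per-cell cap on the intracortical porosity target.
#' @param bone_intensity,void_intensity 8-bit gray levels for bone and void.
#' @param noise_sd Additive Gaussian intensity noise (0 = noise-free).
#' @param seed Integer seed; the generator is bit-reproducible for fixed seed.
#' @param fixed_canal_count If given, place exactly this many canals per cell
#'   instead of filling to the porosity target.
#' @param forced_canals Optional tibble with columns `y`, `x`, `radius`
#'   (um, centre coordinates relative to the phantom axis) and optionally
#'   `z_start`, `z_end` (um): bypass random placement entirely and voxelize
#'   exactly these canals.
#' @param max_attempts Consecutive rejection-sampling failures tolerated per
#'   cell before placement aborts (packing limit).
#' @param cap_at_packing_limit Rejection sampling of non-overlapping disks
#'   jams well below dense packing, so each cell's porosity target is
#'   additionally capped at `0.45 * (1 - mean_diameter / ring_width)` (the
#'   effective per-cell targets are recorded in the returned ground truth).
#'   With `FALSE`, an unreachable target aborts with an error naming the cell.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(outer_radius = 1000,
                         wall_mid = 650,
                         wall_end = 400,
                         inner_radius = NULL,
                         length = 4000,
                         voxel_size = 5.8,
                         porosity_shaft = 0.05,
                         porosity_end = 0.40,
                         diameter_shaft = 40,
                         diameter_end = 110,
                         diameter_cv = 0.25,
                         porosity_profile = NULL,
                         diameter_profile = NULL,
                         ring_width = 250,
                         band_height = 1000,
                         max_cell_porosity = 0.35,
                         bone_intensity = 200L,
                         void_intensity = 20L,
                         noise_sd = 0,
                         seed = 1L,
                         fixed_canal_count = NULL,
                         forced_canals = NULL,
                         max_attempts = 500L,
                         cap_at_packing_limit = TRUE) {
  check_voxel_size(voxel_size)
  if (!is.null(inner_radius)) {
    if (inner_radius >= outer_radius) abort("`inner_radius` must be < `outer_radius`.")
    wall_mid <- wall_end <- outer_radius - inner_radius
  }
  if (wall_mid <= 0 || wall_end <= 0 || wall_mid >= outer_radius ||
      wall_end >= outer_radius) {
    abort("Wall thickness must be positive and smaller than `outer_radius`.")
  }
  if (length <= 0) abort("`length` must be positive (um).")
  if (bone_intensity < 80 || void_intensity >= 80) {
    abort("Default segmentation requires `bone_intensity` >= 80 and `void_intensity` < 80.")
  }
  spec <- structure(list(
    outer_radius = outer_radius, wall_mid = wall_mid, wall_end = wall_end,
    length = length, voxel_size = voxel_size,
    porosity_shaft = porosity_shaft, porosity_end = porosity_end,
    diameter_shaft = diameter_shaft, diameter_end = diameter_end,
    diameter_cv = diameter_cv,
    porosity_profile = porosity_profile, diameter_profile = diameter_profile,
    ring_width = ring_width, band_height = band_height,
    max_cell_porosity = max_cell_porosity,
    bone_intensity = as.integer(bone_intensity),
    void_intensity = as.integer(void_intensity),
    noise_sd = noise_sd, seed = as.integer(seed),
    fixed_canal_count = fixed_canal_count,
    forced_canals = forced_canals,
    max_attempts = as.integer(max_attempts),
    cap_at_packing_limit = isTRUE(cap_at_packing_limit)
  ), class = "phantom_spec")
  # validate profile range on a coarse grid
  pf <- phantom_porosity_fun(spec)
  grid <- expand.grid(l = seq(0, 1, by = 0.1), dfrac = seq(0.05, 0.95, by = 0.15))
  wl <- phantom_wall(spec, grid$l)
  pv <- mapply(pf, grid$l, grid$dfrac * wl, wl)
  if (any(pv < 0 | pv > 0.95)) {
    abort("`porosity_profile` values must lie in [0, 0.95].")
  }
  spec
}

# wall thickness at longitudinal fraction l in [0, 1] (quadratic, max at mid)
phantom_wall <- function(spec, lfrac) {
  spec$wall_mid - (spec$wall_mid - spec$wall_end) * (2 * lfrac - 1)^2
}

phantom_porosity_fun <- function(spec) {
  if (!is.null(spec$porosity_profile)) return(spec$porosity_profile)
  function(lfrac, depth, wall) {
    axial <- spec$porosity_shaft +
      (spec$porosity_end - spec$porosity_shaft) * (2 * lfrac - 1)^2
    radial <- 0.7 + 0.6 * pmin(depth / wall, 1)
    pmin(pmin(axial * radial, spec$max_cell_porosity), 0.95)
  }
}

phantom_diameter_fun <- function(spec) {
  if (!is.null(spec$diameter_profile)) return(spec$diameter_profile)
  function(lfrac, depth, wall) {
    axial <- spec$diameter_shaft +
      (spec$diameter_end - spec$diameter_shaft) * (2 * lfrac - 1)^2
    axial * (0.85 + 0.3 * pmin(depth / wall, 1))
  }
}

#' Generate a grayscale cortical phantom with exact ground truth
#'
#' Voxelizes the shell described by a [phantom_spec()], places non-overlapping
#' axis-parallel canals by rejection sampling, and renders an 8-bit grayscale
#' volume. A voxel is void iff its centre lies inside a canal; the returned
#' label volume (0 = background/medullary cavity, 1 = bone, id + 1 = canal id)
#' agrees with the grayscale rendering before noise, so the total void volume
#' is exactly the sum of per-canal voxel counts.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [grayscale_volume()]) and `truth`
#'   (class `phantom_truth`: list of `canals` tibble, `label` integer array,
#'   `spec`).
#' @export
generate_cortical_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$voxel_size
  nz <- max(1L, as.integer(round(spec$length / s)))
  half <- ceiling(spec$outer_radius / s) + 2L
  ny <- nx <- 2L * half + 1L
  c0 <- half + 1L  # axis voxel index

  # mean canal diameter must be resolvable (>= 2 voxels) everywhere
  if (is.null(spec$forced_canals)) {
    df <- phantom_diameter_fun(spec)
    wl <- phantom_wall(spec, c(0, 0.5, 1))
    dmin <- min(mapply(df, c(0, 0.5, 1), 0.1 * wl, wl))
    if (dmin < 2 * s) {
      abort(sprintf(
        "voxel_size %.3g um too coarse for smallest mean canal diameter %.3g um (< 2 voxels).",
        s, dmin))
    }
  }

  # centre coordinates (um) and radial distance of each in-plane voxel
  yc <- (seq_len(ny) - c0) * s
  xc <- (seq_len(nx) - c0) * s
  rho <- sqrt(outer(yc^2, xc^2, `+`))

  # shell rasterization per slice (wall varies along z)
  lfrac_z <- (seq_len(nz) - 0.5) / nz
  rin_z <- spec$outer_radius - phantom_wall(spec, lfrac_z)
  label <- array(0L, c(ny, nx, nz))
  in_outer <- rho < spec$outer_radius
  for (iz in seq_len(nz)) {
    label[, , iz] <- as.integer(in_outer & rho >= rin_z[iz])
  }

  placement <- withr::with_seed(spec$seed, place_canals(spec, nz))
  canals <- placement$canals

  if (nrow(canals) > 0) {
    disks <- vector("list", nrow(canals))
    counts <- integer(nrow(canals))
    for (i in seq_len(nrow(canals))) {
      cyl <- canals[i, ]
      iy <- which(abs(yc - cyl$y) < cyl$radius)
      ix <- which(abs(xc - cyl$x) < cyl$radius)
      sub <- outer((yc[iy] - cyl$y)^2, (xc[ix] - cyl$x)^2, `+`) < cyl$radius^2
      pix <- which(sub, arr.ind = TRUE)
      disks[[i]] <- as.integer((ix[pix[, 2]] - 1L) * ny + iy[pix[, 1]])
      counts[i] <- nrow(pix) * (cyl$z1_vox - cyl$z0_vox + 1L)
    }
    label <- cpp_paint_canals(label, dim(label), disks,
                              canals$z0_vox, canals$z1_vox, canals$id)
    canals$voxel_count <- counts
  } else {
    canals$voxel_count <- integer(0)
  }

  gray <- array(spec$void_intensity, dim(label))
  gray[label == 1L] <- spec$bone_intensity
  if (spec$noise_sd > 0) {
    gray <- withr::with_seed(spec$seed + 1L, {
      g <- gray + round(rnorm(length(gray), 0, spec$noise_sd))
      pmin(pmax(g, 0), 255)
    })
  }
  storage.mode(gray) <- "integer"
  dim(gray) <- dim(label)

  truth <- structure(list(canals = canals, label = label, spec = spec,
                          cells = placement$cells),
                     class = "phantom_truth")
  list(volume = grayscale_volume(gray, s), truth = truth)
}

# rejection-sampling canal placement; returns tibble of canal records
# (um coordinates relative to the axis, plus voxel z spans)
place_canals <- function(spec, nz) {
  s <- spec$voxel_size
  empty <- tibble(id = integer(), y = numeric(), x = numeric(),
                  radius = numeric(), z_start = numeric(), z_end = numeric(),
                  z0_vox = integer(), z1_vox = integer(),
                  band = integer(), ring = integer())

  if (!is.null(spec$forced_canals)) {
    fc <- as_tibble(spec$forced_canals)
    if (nrow(fc) == 0) return(empty)
    if (!"z_start" %in% names(fc)) fc$z_start <- 0
    if (!"z_end" %in% names(fc)) fc$z_end <- spec$length
    fc$id <- seq_len(nrow(fc))
    fc$z0_vox <- pmax(1L, as.integer(ceiling(fc$z_start / s + 0.5)))
    fc$z1_vox <- pmin(nz, as.integer(floor(fc$z_end / s + 0.5)))
    fc$band <- 0L
    fc$ring <- 0L
    return(list(canals = fc[, names(empty)], cells = NULL))
  }

  pf <- phantom_porosity_fun(spec)
  df <- phantom_diameter_fun(spec)
  sdlog <- sqrt(log(1 + spec$diameter_cv^2))
  cells <- list()
  cell_id <- 0L

  n_bands <- max(1L, as.integer(round(spec$length / spec$band_height)))
  zb <- floor(seq(0, nz, length.out = n_bands + 1))
  out <- list()
  next_id <- 1L

  for (b in seq_len(n_bands)) {
    z0v <- as.integer(zb[b] + 1L)
    z1v <- as.integer(zb[b + 1])
    if (z1v < z0v) next
    l0 <- (z0v - 1) / nz
    l1 <- z1v / nz
    lmid <- (l0 + l1) / 2
    # guaranteed wall over the whole band (wall profile is concave in l)
    wall_ref <- min(phantom_wall(spec, c(l0, l1)))
    rin_max <- spec$outer_radius - wall_ref

    # canals already placed in this band (for overlap checks)
    by <- numeric(0); bx <- numeric(0); br <- numeric(0)

    depth_edges <- seq(0, wall_ref, by = spec$ring_width)
    if (tail(depth_edges, 1) < wall_ref) depth_edges <- c(depth_edges, wall_ref)

    for (r in seq_len(length(depth_edges) - 1)) {
      d0 <- depth_edges[r]
      d1 <- depth_edges[r + 1]
      # 2-voxel clearance from the periosteal surface and the medullary
      # cavity: a sub-voxel bone sliver between a canal and background would
      # be despeckled, breaking exact segmentation closure
      r_out <- spec$outer_radius - d0 - (if (d0 == 0) 2 * s else 0)
      r_in <- max(spec$outer_radius - d1, rin_max + 2 * s)
      if (r_out - r_in < 4 * s) next
      dmid <- (d0 + d1) / 2
      mean_d <- df(lmid, dmid, wall_ref)
      # log-normal diameter draw with mean `mean_d` and CV `diameter_cv`
      meanlog <- log(mean_d) - sdlog^2 / 2
      cell_area <- pi * (r_out^2 - r_in^2)
      p_profile <- pf(lmid, dmid, wall_ref)
      pack_cap <- 0.45 * max(0, 1 - mean_d / (r_out - r_in))
      p_target <- if (spec$cap_at_packing_limit) min(p_profile, pack_cap) else
        p_profile
      if (is.null(spec$fixed_canal_count)) {
        target_area <- p_target * cell_area
        n_target <- Inf
      } else {
        target_area <- Inf
        n_target <- spec$fixed_canal_count
      }
      placed_area <- 0
      n_placed <- 0L
      fails <- 0L
      cell_id <- cell_id + 1L
      while (placed_area < target_area && n_placed < n_target) {
        cr <- rlnorm(1, meanlog, sdlog) / 2
        if (cr < s || cr > (r_out - r_in) / 2 - s) {
          fails <- fails + 1L
          if (fails > spec$max_attempts) break
          next
        }
        rc <- sqrt(runif(1, (r_in + cr)^2, (r_out - cr)^2))
        th <- runif(1, 0, 2 * pi)
        # snap centres to the voxel grid: keeps the discrete inscribed-sphere
        # diameter an unbiased proxy for the true canal diameter
        cyv <- round(rc * sin(th) / s) * s
        cxv <- round(rc * cos(th) / s) * s
        rc2 <- sqrt(cyv^2 + cxv^2)
        if (rc2 < r_in + cr || rc2 > r_out - cr) {
          fails <- fails + 1L
          if (fails > spec$max_attempts) break
          next
        }
        # 2-voxel separation so despeckling can never isolate bone slivers
        ok <- !length(by) ||
          all((by - cyv)^2 + (bx - cxv)^2 >= (br + cr + 2 * s)^2)
        if (!ok) {
          fails <- fails + 1L
          if (fails > spec$max_attempts) break
          next
        }
        fails <- 0L
        by <- c(by, cyv); bx <- c(bx, cxv); br <- c(br, cr)
        out[[length(out) + 1L]] <- tibble(
          id = next_id, y = cyv, x = cxv, radius = cr,
          z_start = (z0v - 1) * s, z_end = z1v * s,
          z0_vox = z0v, z1_vox = z1v, band = b, ring = r)
        next_id <- next_id + 1L
        placed_area <- placed_area + pi * cr^2
        n_placed <- n_placed + 1L
      }
      if (is.finite(target_area) && placed_area < target_area &&
          fails > spec$max_attempts) {
        abort(sprintf(
          paste0("Unreachable target porosity %.3f in band %d (z %.0f-%.0f um), ",
                 "ring %d (depth %.0f-%.0f um): packing limit after %d attempts."),
          target_area / cell_area, b, (z0v - 1) * s, z1v * s, r, d0, d1,
          spec$max_attempts))
      }
      cells[[cell_id]] <- tibble(
        band = b, ring = r, lfrac = lmid, depth = dmid,
        r_in = r_in, r_out = r_out, cell_area = cell_area,
        target_profile = p_profile, target_effective = p_target,
        placed_fraction = placed_area / cell_area, n_canals = n_placed)
    }
  }
  list(canals = if (length(out)) dplyr::bind_rows(out) else empty,
       cells = if (length(cells)) dplyr::bind_rows(cells) else NULL)
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<phantom_truth> %d x %d x %d voxels, %d canals, void fraction of shell %.3f\n",
              d[1], d[2], d[3], nrow(x$canals),
              sum(x$canals$voxel_count) / sum(x$label != 0L)))
  invisible(x)
}

#' Exact structural profiles from phantom ground truth
#'
#' Computes per-ROI true porosity and true volume-weighted mean canal diameter
#' directly from the label volume by voxel counting; diameters come from the
#' canal records, weighted by each canal's voxel count inside the ROI. Medullary
#' cavity voxels (recovered analytically from the phantom geometry) count toward
#' porosity, mirroring the measurement pipeline's default, but never toward
#' diameter.
#'
#' @param truth A `phantom_truth` object.
#' @param rois Optional ROI table from [place_rois()] (resolved voxel ranges).
#'   If `NULL`, ROIs are placed on the noise-free truth itself using `step`,
#'   `depths` and `window`.
#' @param step,depths,window Passed to [place_rois()] when `rois` is `NULL`.
#' @param closing_radius Envelope closing radius (um) used when placing ROIs.
#' @return A tibble: `position`, `direction`, `depth`, `true_porosity`,
#'   `true_mean_diameter`, `n_true_void` (canal + cavity voxels),
#'   `n_true_canal`, `n_true_region`.
#' @export
true_profile <- function(truth, rois = NULL, step = 1000,
                         depths = c(250, 500, 750), window = c(500, 250),
                         closing_radius = 300) {
  stopifnot(inherits(truth, "phantom_truth"))
  s <- truth$spec$voxel_size
  label <- truth$label
  d <- dim(label)
  if (is.null(rois)) {
    bone <- binary_volume(label == 1L, s)
    env <- build_envelope(bone, closing_radius = closing_radius)
    rois <- place_rois(env, step = step, depths = depths, window = window)
  }
  half <- (d[1] - 1L) / 2
  yc <- (seq_len(d[1]) - (half + 1L)) * s
  rho2 <- outer(yc^2, yc^2, `+`)
  interior <- rho2 < truth$spec$outer_radius^2

  canals <- truth$canals
  res <- purrr::pmap(rois, function(...) {
    roi <- list(...)
    if (!roi$valid) {
      return(tibble(true_porosity = NA_real_, true_mean_diameter = NA_real_,
                    n_true_void = NA_integer_, n_true_canal = NA_integer_,
                    n_true_region = NA_integer_))
    }
    box <- label[roi$y0:roi$y1, roi$x0:roi$x1, roi$z0:roi$z1, drop = FALSE]
    inbox <- interior[roi$y0:roi$y1, roi$x0:roi$x1]
    n_cavity <- sum((box == 0L) & as.vector(inbox))
    n_bone <- sum(box == 1L)
    n_canal <- sum(box > 1L)
    n_region <- n_cavity + n_bone + n_canal
    poro <- if (n_region > 0) (n_cavity + n_canal) / n_region else NA_real_
    mean_d <- NA_real_
    if (n_canal > 0) {
      idx <- sort(unique(as.vector(box[box > 1L]))) - 1L
      w <- tabulate(box[box > 1L] - 1L, nbins = max(idx))[idx]
      mean_d <- sum(2 * canals$radius[match(idx, canals$id)] * w) / sum(w)
    }
    tibble(true_porosity = poro, true_mean_diameter = mean_d,
           n_true_void = as.integer(n_cavity + n_canal),
           n_true_canal = as.integer(n_canal),
           n_true_region = as.integer(n_region))
  })
  dplyr::bind_cols(
    rois[, c("position", "direction", "depth")],
    dplyr::bind_rows(res))
}
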