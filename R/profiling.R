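#' Plan transverse sampling positions along the bone axis
#'
#' Positions start at the distal end (z = 0) and advance by `step` um; each
#' position maps to a slab of voxels centred on it (`slab = step` by default,
#' so slabs tile the volume). Slabs clipped by the volume extent are flagged
#' truncated.
#'
#' @param volume A [binary_volume()], [grayscale_volume()] or 3D array-bearing
#'   object with `voxel_size`.
#' @param step Longitudinal sampling interval, um (default 1000 = 1 mm).
#' @param slab Slab thickness aggregated per position, um; defaults to `step`.
#' @return A tibble: `position` (um from distal end), `z0`, `z1` (1-based
#'   inclusive voxel indices), `truncated`.
#' @export
plan_slices <- function(volume, step = 1000, slab = step) {
  d <- dim(volume$voxels)
  s <- volume$voxel_size
  if (step < s) abort("`step` must be at least one voxel.")
  extent <- d[3] * s
  positions <- seq(0, extent, by = step)
  z0 <- pmax(1L, as.integer(floor((positions - slab / 2) / s)) + 1L)
  z1 <- pmin(d[3], as.integer(ceiling((positions + slab / 2) / s)))
  tibble(position = positions, z0 = z0, z1 = z1,
         truncated = (positions - slab / 2 < 0) |
           (positions + slab / 2 > extent))
}

#' Locate the four anatomical direction rays on a slice
#'
#' Rays run from the envelope centroid along the image axes: +y anterior,
#' -y posterior, +x lateral, -x medial. The anatomical labelling is a declared
#' image-axis convention (recorded in outputs), not an atlas registration.
#'
#' @param slice_envelope Logical matrix (one envelope slice).
#' @return A list with `centroid` (c(y, x), fractional voxel coordinates) and
#'   `directions`, a tibble of unit rays (`direction`, `dy`, `dx`). `NA`
#'   centroid for an empty slice.
#' @export
locate_directions <- function(slice_envelope) {
  dirs <- tibble(direction = c("anterior", "posterior", "medial", "lateral"),
                 dy = c(1, -1, 0, 0), dx = c(0, 0, -1, 1))
  if (!any(slice_envelope)) {
    return(list(centroid = c(NA_real_, NA_real_), directions = dirs))
  }
  w <- which(slice_envelope, arr.ind = TRUE)
  list(centroid = c(mean(w[, 1]), mean(w[, 2])), directions = dirs)
}

# first (outermost) envelope voxel along an axis-aligned ray from the centroid;
# returns NA if the ray misses the envelope.
ray_surface <- function(slice_envelope, centroid, dy, dx) {
  cy <- as.integer(round(centroid[1]))
  cx <- as.integer(round(centroid[2]))
  d <- dim(slice_envelope)
  if (dy != 0) {
    line <- slice_envelope[, cx]
    hits <- which(line)
    if (!length(hits)) return(NA_integer_)
    if (dy > 0) max(hits) else min(hits)
  } else {
    line <- slice_envelope[cy, ]
    hits <- which(line)
    if (!length(hits)) return(NA_integer_)
    if (dx > 0) max(hits) else min(hits)
  }
}

#' Place the sampling windows of the radial ROI scheme
#'
#' For each longitudinal position and direction, a rectangular window of
#' `window[1]` um tangential by `window[2]` um radial extent is placed with
#' its inner edge `depth` um inward from the periosteal surface along the
#' direction ray (depth d spans the radial band `[d - window[2], d]`), and
#' extends over the position's slab longitudinally. The surface is found by
#' ray casting against the envelope so surface pores create no false hits;
#' following the sampling rule, placement returns an invalid ROI once no bone
#' area remains inside the window.
#'
#' @param envelope A [bone_envelope()].
#' @param step,slab Longitudinal scheme, um (see [plan_slices()]).
#' @param depths Depths of the ROI inner edge from the outer surface, um.
#' @param window Tangential x radial window size, um (default 500 x 250).
#' @return A tibble of resolved ROIs: `position`, `direction`, `depth`,
#'   voxel ranges `y0..z1`, `valid`, `reason`.
#' @export
place_rois <- function(envelope, step = 1000, depths = c(250, 500, 750),
                       window = c(500, 250), slab = step) {
  stopifnot(inherits(envelope, "bone_envelope"))
  s <- envelope$voxel_size
  d <- dim(envelope$voxels)
  plan <- plan_slices(envelope, step = step, slab = slab)
  # symmetric (odd-width) tangential window so on-grid rotations are exact
  half_tan <- max(1L, as.integer(round(window[1] / 2 / s)))
  w_rad <- max(1L, as.integer(round(window[2] / s)))

  out <- list()
  for (p in seq_len(nrow(plan))) {
    zmid <- as.integer(round((plan$z0[p] + plan$z1[p]) / 2))
    sl <- envelope$voxels[, , zmid]
    loc <- locate_directions(sl)
    for (k in seq_len(nrow(loc$directions))) {
      dir <- loc$directions[k, ]
      surf <- if (any(is.na(loc$centroid))) NA_integer_ else
        ray_surface(sl, loc$centroid, dir$dy, dir$dx)
      for (depth in depths) {
        d_vox <- as.integer(round(depth / s))
        roi <- list(y0 = NA_integer_, y1 = NA_integer_,
                    x0 = NA_integer_, x1 = NA_integer_,
                    z0 = plan$z0[p], z1 = plan$z1[p])
        valid <- FALSE
        reason <- NA_character_
        if (is.na(surf)) {
          reason <- "ray misses bone"
        } else {
          cy <- as.integer(round(loc$centroid[1]))
          cx <- as.integer(round(loc$centroid[2]))
          if (dir$dy != 0) {
            rr <- if (dir$dy > 0) {
              c(surf - d_vox + 1L, surf - d_vox + w_rad)
            } else {
              c(surf + d_vox - w_rad, surf + d_vox - 1L)
            }
            roi$y0 <- rr[1]; roi$y1 <- rr[2]
            roi$x0 <- cx - half_tan; roi$x1 <- cx + half_tan
          } else {
            rr <- if (dir$dx > 0) {
              c(surf - d_vox + 1L, surf - d_vox + w_rad)
            } else {
              c(surf + d_vox - w_rad, surf + d_vox - 1L)
            }
            roi$x0 <- rr[1]; roi$x1 <- rr[2]
            roi$y0 <- cy - half_tan; roi$y1 <- cy + half_tan
          }
          inside <- roi$y0 >= 1 && roi$y1 <= d[1] && roi$x0 >= 1 &&
            roi$x1 <= d[2]
          if (!inside) {
            reason <- "ROI outside volume"
            roi[c("y0", "y1", "x0", "x1")] <- NA_integer_
          } else if (!any(envelope$voxels[roi$y0:roi$y1, roi$x0:roi$x1,
                                          roi$z0:roi$z1])) {
            reason <- "no bone material in ROI"
          } else {
            valid <- TRUE
          }
        }
        out[[length(out) + 1L]] <- tibble(
          position = plan$position[p], direction = dir$direction,
          depth = depth, y0 = roi$y0, y1 = roi$y1, x0 = roi$x0, x1 = roi$x1,
          z0 = roi$z0, z1 = roi$z1, valid = valid, reason = reason)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Cortical thickness along a direction ray
#'
#' Thickness is the chord length of the contiguous envelope run containing
#' the periosteal surface point along the ray from the centroid: the distance
#' from the outer surface to the endosteal boundary. On solid sections with
#' no medullary cavity along the ray, the full chord to the centroid is
#' returned and flagged.
#'
#' @param slice_envelope Logical envelope matrix (one slice).
#' @param slice_cavity Logical cavity matrix (same slice).
#' @param direction One of `"anterior"`, `"posterior"`, `"medial"`, `"lateral"`.
#' @param voxel_size Voxel size, um.
#' @return A list: `thickness_mm`, `no_cavity` flag.
#' @export
cortical_thickness <- function(slice_envelope, slice_cavity, direction,
                               voxel_size) {
  loc <- locate_directions(slice_envelope)
  if (any(is.na(loc$centroid))) {
    return(list(thickness_mm = NA_real_, no_cavity = NA))
  }
  dir <- loc$directions[loc$directions$direction == direction, ]
  if (nrow(dir) != 1) abort("Unknown `direction`.")
  cy <- as.integer(round(loc$centroid[1]))
  cx <- as.integer(round(loc$centroid[2]))
  if (dir$dy != 0) {
    env_line <- slice_envelope[, cx]
    cav_line <- slice_cavity[, cx]
    start <- cy
    nn <- length(env_line)
    ray <- if (dir$dy > 0) start:nn else start:1
  } else {
    env_line <- slice_envelope[cy, ]
    cav_line <- slice_cavity[cy, ]
    start <- cx
    nn <- length(env_line)
    ray <- if (dir$dx > 0) start:nn else start:1
  }
  hits <- ray[env_line[ray]]
  if (!length(hits)) return(list(thickness_mm = NA_real_, no_cavity = NA))
  # outermost surface voxel and the contiguous run ending there
  env_ray <- env_line[ray]
  runs <- rle(env_ray)
  last_true <- max(which(env_ray))
  run_id <- findInterval(last_true, cumsum(runs$lengths), left.open = TRUE) + 1L
  run_len <- runs$lengths[run_id]
  no_cavity <- !any(cav_line[ray])
  list(thickness_mm = run_len * voxel_size / 1000, no_cavity = no_cavity)
}

#' Assemble radial, longitudinal and thickness profiles
#'
#' Runs the full ROI scheme over a segmented volume: per (position, direction,
#' depth) window it measures porosity and volume-weighted mean canal diameter,
#' averages directions into the radial profile, extracts fixed-depth
#' longitudinal profiles, and measures cortical thickness per direction.
#' Per-ROI failures propagate as `NA` rows without aborting the run.
#'
#' @param binary A [binary_volume()] bone mask.
#' @param envelope Optional [bone_envelope()]; built with `closing_radius`
#'   when omitted.
#' @param step,slab,depths,window ROI scheme parameters, um.
#' @param closing_radius Envelope closing radius, um.
#' @param include_cavity Count medullary cavity voxels toward porosity.
#' @param tmap Optional precomputed [local_thickness()] map of the
#'   intracortical void phase.
#' @return An object of class `bone_profiles`: list of tibbles `directional`
#'   (per position x direction x depth), `radial` (direction-averaged, per
#'   position x depth), `longitudinal` (same table keyed by depth),
#'   `thickness` (per position x direction plus direction mean), and the `rois`
#'   table; plus metadata (`voxel_size`, conventions).
#' @export
assemble_profiles <- function(binary, envelope = NULL, step = 1000,
                              depths = c(250, 500, 750), window = c(500, 250),
                              closing_radius = 300, include_cavity = TRUE,
                              slab = step, tmap = NULL) {
  stopifnot(inherits(binary, "binary_volume"))
  if (is.null(envelope)) {
    envelope <- build_envelope(binary, closing_radius = closing_radius)
  }
  s <- binary$voxel_size
  if (is.null(tmap)) {
    tmap <- local_thickness(intracortical_void(binary, envelope))
  }
  rois <- place_rois(envelope, step = step, depths = depths, window = window,
                     slab = slab)

  meas <- purrr::pmap(rois, function(...) {
    roi <- list(...)
    if (!roi$valid) {
      return(tibble(porosity = NA_real_, mean_diameter = NA_real_,
                    n_void = NA_integer_, n_region = NA_integer_))
    }
    idx <- roi_index(roi, dim(binary$voxels))
    env <- envelope$voxels[idx$y, idx$x, idx$z]
    bone <- binary$voxels[idx$y, idx$x, idx$z]
    cav <- envelope$cavity[idx$y, idx$x, idx$z]
    n_env <- sum(env)
    n_void <- sum(env & !bone)
    n_region <- if (include_cavity) n_env + sum(cav) else n_env
    n_void_all <- if (include_cavity) n_void + sum(cav) else n_void
    th <- tmap$values[idx$y, idx$x, idx$z]
    th <- th[th > 0]
    tibble(porosity = if (n_region > 0) n_void_all / n_region else NA_real_,
           mean_diameter = if (length(th)) mean(th) else NA_real_,
           n_void = as.integer(n_void_all), n_region = as.integer(n_region))
  })
  directional <- dplyr::bind_cols(
    rois[, c("position", "direction", "depth", "valid")],
    dplyr::bind_rows(meas))

  radial <- directional |>
    dplyr::group_by(.data$position, .data$depth) |>
    dplyr::summarise(
      n_directions = sum(!is.na(.data$porosity)),
      porosity = mean(.data$porosity, na.rm = TRUE),
      mean_diameter = mean(.data$mean_diameter, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(porosity = ifelse(is.nan(.data$porosity), NA_real_,
                                    .data$porosity),
                  mean_diameter = ifelse(is.nan(.data$mean_diameter), NA_real_,
                                         .data$mean_diameter))

  longitudinal <- radial |> dplyr::arrange(.data$depth, .data$position)

  plan <- plan_slices(binary, step = step, slab = slab)
  thick <- list()
  for (p in seq_len(nrow(plan))) {
    zmid <- as.integer(round((plan$z0[p] + plan$z1[p]) / 2))
    sl <- envelope$voxels[, , zmid]
    cav <- envelope$cavity[, , zmid]
    for (dn in c("anterior", "posterior", "medial", "lateral")) {
      ct <- cortical_thickness(sl, cav, dn, s)
      thick[[length(thick) + 1L]] <- tibble(
        position = plan$position[p], direction = dn,
        thickness_mm = ct$thickness_mm, no_cavity = ct$no_cavity)
    }
  }
  thickness <- dplyr::bind_rows(thick)
  thickness_mean <- thickness |>
    dplyr::group_by(.data$position) |>
    dplyr::summarise(thickness_mm = mean(.data$thickness_mm, na.rm = TRUE),
                     .groups = "drop")

  structure(list(directional = directional, radial = radial,
                 longitudinal = longitudinal, thickness = thickness,
                 thickness_mean = thickness_mean, rois = rois,
                 voxel_size = s,
                 conventions = list(
                   depth_anchor = "inner edge: depth d spans [d - window_radial, d]",
                   directions = "image-axis convention: +y anterior, -y posterior, +x lateral, -x medial",
                   distal_end = "z = 0",
                   include_cavity = include_cavity)),
            class = "bone_profiles")
}

#' @export
print.bone_profiles <- function(x, ...) {
  cat(sprintf("<bone_profiles> %d positions x %d depths x 4 directions (%d valid ROIs)\n",
              dplyr::n_distinct(x$directional$position),
              dplyr::n_distinct(x$directional$depth),
              sum(x$directional$valid)))
  invisible(x)
}
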