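#' Grayscale and binary voxel volumes
#'
#' Lightweight containers for 3D image stacks. Arrays are stored `[y, x, z]`
#' (column-major, so `vol$voxels[, , k]` is the k-th transverse slice); the z
#' index ascends from the distal end of the bone. All physical lengths are in
#' micrometres; `voxel_size` is the isotropic voxel edge length.
#'
#' @param voxels 3D array. For `grayscale_volume`, integer intensities in
#'   `[0, 255]`; for `binary_volume`, logical with `TRUE` = bone.
#' @param voxel_size Isotropic voxel edge length, um.
#' @param provenance Optional named list recording how a mask was produced
#'   (threshold bounds, despeckle settings, ...).
#' @return An object of class `grayscale_volume` or `binary_volume`: a list
#'   with elements `voxels`, `voxel_size` (and `provenance` for masks).
#' @examples
#' g <- grayscale_volume(array(200L, c(4, 4, 2)), voxel_size = 5.8)
#' dim(g$voxels)
#' @export
grayscale_volume <- function(voxels, voxel_size) {
  check_voxel_size(voxel_size)
  if (length(dim(voxels)) != 3) {
    abort("`voxels` must be a 3D array [y, x, z].")
  }
  rng <- range(voxels)
  if (rng[1] < 0 || rng[2] > 255) {
    abort("Grayscale intensities must lie in [0, 255].")
  }
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, voxel_size = voxel_size),
            class = "grayscale_volume")
}

#' @rdname grayscale_volume
#' @export
binary_volume <- function(voxels, voxel_size, provenance = list()) {
  check_voxel_size(voxel_size)
  if (length(dim(voxels)) != 3 || !is.logical(voxels)) {
    abort("`voxels` must be a 3D logical array [y, x, z].")
  }
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 provenance = provenance),
            class = "binary_volume")
}

#' @export
print.grayscale_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<grayscale_volume> %d x %d x %d voxels @ %.3g um (%.2f x %.2f x %.2f mm)\n",
              d[1], d[2], d[3],
              x$voxel_size,
              d[1] * x$voxel_size / 1000, d[2] * x$voxel_size / 1000,
              d[3] * x$voxel_size / 1000))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_volume> %d x %d x %d voxels @ %.3g um, %.1f%% foreground\n",
              d[1], d[2], d[3], x$voxel_size, 100 * mean(x$voxels)))
  if (length(x$provenance)) {
    cat("  provenance:", jsonlite::toJSON(x$provenance, auto_unbox = TRUE), "\n")
  }
  invisible(x)
}

check_voxel_size <- function(voxel_size) {
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    abort("`voxel_size` must be a single positive number (um).")
  }
  invisible(voxel_size)
}

# squared Euclidean distance transform in voxel units (exact integers).
# phase: logical array; returns distance^2 from TRUE voxels to nearest FALSE.
# dims: logical length 3, which axes propagate distance.
edt2_voxel <- function(phase, dims = c(TRUE, TRUE, TRUE)) {
  d <- dim(phase)
  out <- cpp_edt2(as.vector(phase), as.integer(d), as.logical(dims),
                  c(1, 1, 1))
  array(out, d)
}

# natural ("version-aware") sort used for slice filenames: s2 < s10.
natural_sort <- function(x) {
  key <- gsub("(\\d+)", " \\1 ", x)
  parts <- strsplit(trimws(key), "\\s+")
  maxlen <- max(lengths(parts))
  mat <- vapply(parts, function(p) {
    p <- c(p, rep("", maxlen - length(p)))
    vapply(p, function(tok) {
      if (grepl("^\\d+$", tok)) sprintf("%020d", as.numeric(tok)) else tok
    }, character(1))
  }, character(maxlen))
  if (maxlen == 1) mat <- matrix(mat, nrow = 1)
  x[do.call(order, c(split(mat, row(mat)), list(x)))]
}
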