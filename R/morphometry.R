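#' Maximal-inscribed-sphere local thickness of the void phase
#'
#' At every void voxel, the local thickness is the diameter (um) of the
#' largest sphere that fits entirely within the void phase and contains that
#' voxel (the Hildebrand-Ruegsegger definition, the standard proxy for canal
#' diameter). Computed via an exact Euclidean distance transform followed by
#' sphere coverage: thickness(x) = max over void voxels c with |x - c| <
#' EDT(c) of 2 EDT(c).
#'
#' Boundary convention: the transverse (y, x) faces of the array are treated
#' as background (exterior), while the longitudinal (z) faces are open --
#' canals are assumed to continue beyond the imaged extent, so a full-length
#' canal carries no end artifact. An isolated single void voxel has thickness
#' `2 * voxel_size` (one-voxel sphere convention); every positive value is at
#' least that.
#'
#' @param void_mask A [binary_volume()] whose `TRUE` voxels are the void
#'   phase (e.g. `envelope & !bone`).
#' @return An object of class `thickness_map`: list with `values` (3D double
#'   array, um; 0 outside the void phase) and `voxel_size`.
#' @export
local_thickness <- function(void_mask) {
  stopifnot(inherits(void_mask, "binary_volume"))
  d <- dim(void_mask$voxels)
  # pad y,x with one background layer (exterior); z faces stay open
  padded <- array(FALSE, d + c(2L, 2L, 0L))
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- void_mask$voxels
  edt2 <- cpp_edt2(as.vector(padded), dim(padded), c(TRUE, TRUE, TRUE),
                   c(1, 1, 1))
  th <- cpp_local_thickness(edt2, dim(padded))
  dim(th) <- dim(padded)
  values <- th[2:(d[1] + 1L), 2:(d[2] + 1L), , drop = FALSE] *
    void_mask$voxel_size
  dim(values) <- d
  structure(list(values = values, voxel_size = void_mask$voxel_size),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  d <- dim(x$values)
  pos <- x$values[x$values > 0]
  cat(sprintf("<thickness_map> %d x %d x %d voxels @ %.3g um; %d void voxels",
              d[1], d[2], d[3], x$voxel_size, length(pos)))
  if (length(pos)) {
    cat(sprintf("; thickness %.1f-%.1f um (volume-weighted mean %.1f)",
                min(pos), max(pos), mean(pos)))
  }
  cat("\n")
  invisible(x)
}

#' Intracortical void phase for canal statistics
#'
#' The canal (intracortical void) phase is `envelope & !bone` with one
#' qualification: a genuine intracortical void component is enclosed by bone
#' within its slice. Void components that touch non-envelope space (the
#' medullary cavity or the exterior) are boundary residue of the
#' morphological closing -- or void continuous with the cavity -- and are
#' excluded, so they never contaminate canal-diameter statistics. Components
#' are 8-connected in 2D, per transverse slice.
#'
#' @param binary A [binary_volume()] bone mask.
#' @param envelope A [bone_envelope()].
#' @return A [binary_volume()] whose `TRUE` voxels are the canal phase.
#' @export
intracortical_void <- function(binary, envelope) {
  stopifnot(inherits(binary, "binary_volume"),
            inherits(envelope, "bone_envelope"))
  d <- dim(binary$voxels)
  void <- envelope$voxels & !binary$voxels
  for (iz in seq_len(d[3])) {
    v <- void[, , iz]
    if (!any(v)) next
    outside <- !envelope$voxels[, , iz]
    # 8-neighbourhood dilation of non-envelope space via squared EDT <= 2
    t2 <- cpp_edt2(as.vector(!outside), c(d[1], d[2], 1L),
                   c(TRUE, TRUE, FALSE), c(1, 1, 1))
    touch <- matrix(t2 <= 2, d[1], d[2]) & v
    if (!any(touch)) next
    lab <- matrix(cpp_label2d(v, d[1], d[2], TRUE), d[1], d[2])
    drop_ids <- unique(lab[touch])
    void[, , iz] <- v & !(lab %in% drop_ids)
  }
  binary_volume(void, binary$voxel_size,
                provenance = list(phase = "intracortical_void"))
}

#' Void volume fraction within a region of interest
#'
#' Porosity is the void volume fraction within the bone area: the count of
#' non-bone voxels inside the reference region divided by the region voxel
#' count, in exact integer arithmetic. By default the reference region is the
#' envelope plus the medullary cavity, so deep ROIs that reach the cavity
#' report its void toward porosity (this is how porosity approaches 80-100%
#' near the bone ends); `include_cavity = FALSE` restricts both numerator and
#' denominator to the intracortical envelope.
#'
#' @param binary A [binary_volume()] bone mask.
#' @param envelope A [bone_envelope()].
#' @param roi Either `NULL` (whole volume) or a list/one-row data frame with
#'   1-based inclusive voxel index ranges `y0, y1, x0, x1, z0, z1`.
#' @param include_cavity Count medullary cavity voxels as void (default TRUE).
#' @return A single porosity fraction in `[0, 1]`, or `NA` (with a warning)
#'   when the ROI does not intersect the reference region.
#' @export
roi_porosity <- function(binary, envelope, roi = NULL, include_cavity = TRUE) {
  stopifnot(inherits(binary, "binary_volume"),
            inherits(envelope, "bone_envelope"))
  idx <- roi_index(roi, dim(binary$voxels))
  bone <- binary$voxels[idx$y, idx$x, idx$z, drop = FALSE]
  env <- envelope$voxels[idx$y, idx$x, idx$z, drop = FALSE]
  region_n <- sum(env)
  void_n <- sum(env & !bone)
  if (include_cavity) {
    cav_n <- sum(envelope$cavity[idx$y, idx$x, idx$z, drop = FALSE])
    region_n <- region_n + cav_n
    void_n <- void_n + cav_n
  }
  if (region_n == 0) {
    warn("ROI does not intersect the bone envelope; porosity is NA.")
    return(NA_real_)
  }
  void_n / region_n
}

roi_index <- function(roi, d) {
  if (is.null(roi)) {
    return(list(y = seq_len(d[1]), x = seq_len(d[2]), z = seq_len(d[3])))
  }
  roi <- as.list(roi)
  need <- c("y0", "y1", "x0", "x1", "z0", "z1")
  if (!all(need %in% names(roi))) {
    abort("`roi` must provide voxel ranges y0, y1, x0, x1, z0, z1.")
  }
  if (roi$y0 < 1 || roi$y1 > d[1] || roi$x0 < 1 || roi$x1 > d[2] ||
      roi$z0 < 1 || roi$z1 > d[3] || roi$y0 > roi$y1 || roi$x0 > roi$x1 ||
      roi$z0 > roi$z1) {
    abort("ROI voxel ranges fall outside the volume.")
  }
  list(y = roi$y0:roi$y1, x = roi$x0:roi$x1, z = roi$z0:roi$z1)
}

#' Volume-percentage canal-diameter histogram
#'
#' Bins the per-voxel local thickness of the void phase into diameter ranges
#' and expresses each bin as the percentage of total canal volume (each void
#' voxel contributes equally). Bins are right-open except the last, which is
#' closed; values beyond the last edge are counted into the last bin.
#'
#' @param tmap A [local_thickness()] map, optionally restricted first.
#' @param edges Strictly increasing bin edges in um starting at 0; default
#'   0 to 375 in steps of 25.
#' @param roi Optional ROI voxel ranges (see [roi_porosity()]).
#' @return A tibble with `bin_lower`, `bin_upper`, `volume_percent`; the
#'   percentages sum to 100 when any void exists, and are all `NA` otherwise.
#' @export
canal_histogram <- function(tmap, edges = seq(0, 375, by = 25), roi = NULL) {
  stopifnot(inherits(tmap, "thickness_map"))
  if (edges[1] != 0 || any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing and start at 0.")
  }
  idx <- roi_index(roi, dim(tmap$values))
  v <- tmap$values[idx$y, idx$x, idx$z]
  v <- v[v > 0]
  k <- length(edges) - 1L
  out <- tibble(bin_lower = edges[-length(edges)], bin_upper = edges[-1])
  if (!length(v)) {
    out$volume_percent <- NA_real_
    return(out)
  }
  bin <- findInterval(v, edges, rightmost.closed = FALSE)
  bin[bin > k] <- k  # last bin closed on the right
  out$volume_percent <- 100 * tabulate(bin, nbins = k) / length(v)
  out
}

#' Volume-weighted mean canal diameter
#'
#' The mean of per-voxel local thickness over the void phase: each void voxel
#' contributes equally, so larger canals are weighted by their volume,
#' matching the volume-percentage framing of the canal histograms.
#'
#' @inheritParams canal_histogram
#' @return Mean diameter in um, or `NA` for an empty map/ROI.
#' @export
mean_canal_diameter <- function(tmap, roi = NULL) {
  stopifnot(inherits(tmap, "thickness_map"))
  idx <- roi_index(roi, dim(tmap$values))
  v <- tmap$values[idx$y, idx$x, idx$z]
  v <- v[v > 0]
  if (!length(v)) return(NA_real_)
  mean(v)
}
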