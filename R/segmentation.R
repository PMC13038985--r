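#' Global threshold segmentation
#'
#' Binarizes a grayscale volume with an inclusive global gray-level window:
#' a voxel is bone iff `lower <= intensity <= upper`. No smoothing or
#' beam-hardening correction is applied. The defaults (80, 255) straddle the
#' gray levels of mineralized bone versus canal/marrow space in 8-bit
#' reconstructions.
#'
#' @param gray A [grayscale_volume()].
#' @param lower,upper Inclusive threshold bounds in `[0, 255]`.
#' @return A [binary_volume()] with threshold provenance recorded.
#' @export
global_threshold <- function(gray, lower = 80, upper = 255) {
  stopifnot(inherits(gray, "grayscale_volume"))
  if (!(lower >= 0 && lower <= upper && upper <= 255)) {
    abort("Need 0 <= lower <= upper <= 255.")
  }
  mask <- gray$voxels >= lower & gray$voxels <= upper
  binary_volume(mask, gray$voxel_size,
                provenance = list(lower = lower, upper = upper))
}

#' Remove small 2D foreground speckles
#'
#' Independently on each transverse (fixed-z) slice, every connected
#' foreground component with strictly fewer than `min_pixels` pixels is set to
#' background. This is the conventional despeckle step that suppresses
#' isolated segmentation noise; it is idempotent and its output is always a
#' subset of its input.
#'
#' @param binary A [binary_volume()].
#' @param min_pixels Components smaller than this (strict `<`) are removed.
#' @param connectivity 8 (default) or 4; pixel connectivity used to define
#'   components.
#' @return A [binary_volume()] with despeckle provenance appended.
#' @export
despeckle_2d <- function(binary, min_pixels = 25, connectivity = 8) {
  stopifnot(inherits(binary, "binary_volume"))
  if (min_pixels < 1) abort("`min_pixels` must be >= 1.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  out <- cpp_despeckle2d(as.vector(binary$voxels), dim(binary$voxels),
                         as.integer(min_pixels), connectivity == 8)
  dim(out) <- dim(binary$voxels)
  binary_volume(out, binary$voxel_size,
                provenance = c(binary$provenance,
                               list(despeckle_min = min_pixels,
                                    despeckle_connectivity = connectivity)))
}

#' Segment a grayscale volume with the default pipeline
#'
#' Convenience composition of [global_threshold()] and [despeckle_2d()].
#'
#' @inheritParams global_threshold
#' @inheritParams despeckle_2d
#' @return A [binary_volume()].
#' @export
segment_volume <- function(gray, lower = 80, upper = 255, min_pixels = 25,
                           connectivity = 8) {
  despeckle_2d(global_threshold(gray, lower, upper),
               min_pixels = min_pixels, connectivity = connectivity)
}
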