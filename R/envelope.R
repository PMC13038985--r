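#' Build the bone envelope (periosteal boundary including intracortical pores)
#'
#' Separates intracortical void from exterior background and medullary cavity.
#' Per transverse slice, the bone mask is morphologically closed with a
#' Euclidean disk of radius `closing_radius` (computed exactly via two 2D
#' distance transforms on a padded slice, so circular boundaries are preserved
#' voxel-exactly), then internal holes are filled. Background components
#' touching the slice border are exterior; of the interior background
#' components of the closed mask, the largest is taken to be the medullary
#' cavity (excluded from the envelope but returned as its own mask); all
#' smaller interior components are intracortical pores and are filled into
#' the envelope.
#'
#' @param binary A [binary_volume()] bone mask.
#' @param closing_radius Disk radius for morphological closing, um. Must be
#'   smaller than the medullary cavity radius or the cavity is closed over.
#' @param min_cavity_area Interior background components smaller than this
#'   (um^2) are never classified as the cavity (they are filled as pores).
#' @return An object of class `bone_envelope`: list with `voxels` (logical,
#'   bone area including pores, excluding cavity), `cavity` (logical),
#'   `voxel_size`, `closing_radius`.
#' @export
build_envelope <- function(binary, closing_radius = 300,
                           min_cavity_area = 10000) {
  stopifnot(inherits(binary, "binary_volume"))
  s <- binary$voxel_size
  d <- dim(binary$voxels)
  rvox2 <- (closing_radius / s)^2
  pad <- as.integer(ceiling(closing_radius / s)) + 2L
  nyp <- d[1] + 2L * pad
  nxp <- d[2] + 2L * pad
  pdim <- c(nyp, nxp, 1L)
  dims2d <- c(TRUE, TRUE, FALSE)
  iy <- pad + seq_len(d[1])
  ix <- pad + seq_len(d[2])

  envelope <- array(FALSE, d)
  cavity <- array(FALSE, d)
  min_cavity_px <- min_cavity_area / s^2

  for (iz in seq_len(d[3])) {
    sl <- binary$voxels[, , iz]
    if (!any(sl)) next  # empty slice -> empty envelope, no failure
    padded <- matrix(FALSE, nyp, nxp)
    padded[iy, ix] <- sl
    # Euclidean closing: dilate (distance-to-bone <= r), then erode
    dist2 <- cpp_edt2(as.vector(!padded), pdim, dims2d, c(1, 1, 1))
    dilated <- dist2 <= rvox2
    dist2 <- cpp_edt2(dilated, pdim, dims2d, c(1, 1, 1))
    cl <- matrix(dist2 > rvox2, nyp, nxp)[iy, ix]

    lab <- matrix(cpp_label2d(!cl, d[1], d[2], FALSE), d[1], d[2])
    env_sl <- cl
    if (max(lab) > 0) {
      border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
      border <- border[border > 0]
      sizes <- tabulate(lab, nbins = max(lab))
      interior <- setdiff(which(sizes > 0), border)
      if (length(interior)) {
        big <- interior[sizes[interior] >= min_cavity_px]
        cav_id <- if (length(big)) big[which.max(sizes[big])] else integer(0)
        fill_ids <- setdiff(interior, cav_id)
        if (length(fill_ids)) env_sl <- env_sl | (lab %in% fill_ids)
        if (length(cav_id)) cavity[, , iz] <- lab == cav_id
      }
    }
    envelope[, , iz] <- env_sl
  }
  structure(list(voxels = envelope, cavity = cavity, voxel_size = s,
                 closing_radius = closing_radius),
            class = "bone_envelope")
}

#' @export
print.bone_envelope <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<bone_envelope> %d x %d x %d voxels @ %.3g um (closing %g um), cavity %.1f%%\n",
              d[1], d[2], d[3], x$voxel_size, x$closing_radius,
              100 * mean(x$cavity)))
  invisible(x)
}
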