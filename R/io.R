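#' Read a grayscale volume from TIFF, a slice directory, or NIfTI
#'
#' Accepts a multi-page TIFF, a directory of 2D TIFF/PNG slices (slice order =
#' natural sort of filenames, ascending z from the distal end), or a NIfTI
#' file (requires the RNifti package). The voxel size is taken from the
#' `voxel_size_um` field of a JSON sidecar (`<path>.json`) when present,
#' otherwise from the `voxel_size` argument; it is an error to supply
#' neither. 16-bit inputs are rescaled to 8-bit with a warning.
#'
#' @param path File or directory path.
#' @param voxel_size Isotropic voxel size in um (overridden by a sidecar).
#' @return A [grayscale_volume()].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  sidecar <- paste0(sub("/$", "", path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$voxel_size_um)) voxel_size <- meta$voxel_size_um
  }
  if (is.null(voxel_size)) {
    abort("Voxel size not found: supply `voxel_size` or a JSON sidecar with `voxel_size_um`.")
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
    if (!length(files)) abort(sprintf("No TIFF/PNG slices found in %s", path))
    files <- natural_sort(files)
    slices <- lapply(file.path(path, files), read_slice)
    shapes <- vapply(slices, function(m) paste(dim(m), collapse = "x"),
                     character(1))
    if (length(unique(shapes)) > 1) {
      off <- files[shapes != shapes[1]]
      abort(sprintf("Mixed slice shapes; offending files: %s",
                    paste(off, collapse = ", ")))
    }
    vox <- array(0L, c(dim(slices[[1]]), length(slices)))
    for (k in seq_along(slices)) vox[, , k] <- slices[[k]]
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("Reading NIfTI requires the RNifti package.")
    }
    img <- RNifti::readNifti(path)
    vox <- rescale_8bit(as.array(img))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vox <- array(0L, c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) vox[, , k] <- to_8bit(pages[[k]])
  }
  grayscale_volume(vox, voxel_size)
}

read_slice <- function(f) {
  if (grepl("\\.png$", f, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      abort("Reading PNG slices requires the png package.")
    }
    m <- png::readPNG(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    return(as.integer(round(m * 255)) |> array(dim(m)[1:2]))
  }
  to_8bit(tiff::readTIFF(f, as.is = TRUE))
}

to_8bit <- function(m) {
  if (length(dim(m)) == 3) m <- m[, , 1]  # drop extra channels
  mx <- max(m)
  if (mx > 255) {
    warn(sprintf("Rescaling %d-bit-range intensities to 8-bit (factor %.4g).",
                 if (mx > 4095) 16L else 12L, 255 / mx))
    m <- m / mx * 255
  }
  storage.mode(m) <- "integer"
  m
}

rescale_8bit <- function(a) {
  mx <- max(a)
  if (mx > 255 || min(a) < 0) {
    rng <- range(a)
    a <- (a - rng[1]) / max(rng[2] - rng[1], 1) * 255
  }
  storage.mode(a) <- "integer"
  a
}

#' Write a volume as multi-page 8-bit TIFF with a JSON sidecar
#'
#' Masks are written as 0/255; grayscale volumes keep their intensities. The
#' sidecar (`<path>.json`) records the voxel size, any provenance, and extra
#' metadata.
#'
#' @param volume A [grayscale_volume()] or [binary_volume()].
#' @param path Output TIFF path.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, extra = list()) {
  vox <- volume$voxels
  if (is.logical(vox)) vox <- array(ifelse(vox, 255L, 0L), dim(vox))
  pages <- lapply(seq_len(dim(vox)[3]),
                  function(k) vox[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- c(list(voxel_size_um = volume$voxel_size,
                 dim = dim(vox), axis_order = "y,x,z (z distal -> proximal)"),
            if (!is.null(volume$provenance)) list(provenance = volume$provenance),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write / read a stress-strain curve as CSV with JSON sidecar
#'
#' The CSV has columns `strain`, `stress_MPa`; the sidecar stores the
#' generating spec or specimen geometry.
#'
#' @param curve A tibble with `strain`, `stress`.
#' @param path CSV path.
#' @param meta Named list for the sidecar (e.g. thickness_mm, area_mm2,
#'   position_mm, or the true generator parameters).
#' @return `path` (write) or a tibble with the sidecar in attribute `meta`
#'   (read).
#' @export
write_curve <- function(curve, path, meta = list()) {
  readr::write_csv(tibble(strain = curve$strain, stress_MPa = curve$stress),
                   path)
  sp <- attr(curve, "curve_spec")
  if (!is.null(sp) && !length(meta)) meta <- unclass(sp)
  if (length(meta)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(strain = df$strain, stress = df$stress_MPa)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "meta") <- jsonlite::read_json(sidecar)
  }
  out
}

#' Round-trippable run configuration
#'
#' Collects every tunable of the pipeline in one list that serializes
#' losslessly to JSON; each pipeline run writes its resolved configuration
#' beside its outputs.
#'
#' @param voxel_size,lower,upper,despeckle_min,step,depths,window,closing_radius
#'   Pipeline parameters (um / 8-bit intensities).
#' @param pairing_tolerance Pairing tolerance, mm.
#' @param seed Integer master seed.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(voxel_size = 5.8, lower = 80, upper = 255,
                       despeckle_min = 25, step = 1000,
                       depths = c(250, 500, 750), window = c(500, 250),
                       closing_radius = 300, pairing_tolerance = 0.5,
                       seed = 1L) {
  structure(list(voxel_size = voxel_size, lower = lower, upper = upper,
                 despeckle_min = despeckle_min, step = step, depths = depths,
                 window = window, closing_radius = closing_radius,
                 pairing_tolerance = pairing_tolerance,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$seed <- as.integer(x$seed)
  structure(x, class = "run_config")
}
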