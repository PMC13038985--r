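# Brute-force reference implementations, independent of the package kernels.
# Conventions match the package: transverse (y, x) borders are background,
# longitudinal z faces are open; distances in voxel units.

# squared EDT by exhaustive search over background voxels
brute_edt2 <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + c(2, 2, 0))
  pad[2:(d[1] + 1), 2:(d[2] + 1), ] <- mask
  coords <- which(pad, arr.ind = TRUE)
  bg <- which(!pad, arr.ind = TRUE)
  out <- array(0, dim(pad))
  for (i in seq_len(nrow(coords))) {
    v <- coords[i, ]
    out[v[1], v[2], v[3]] <-
      min((bg[, 1] - v[1])^2 + (bg[, 2] - v[2])^2 + (bg[, 3] - v[3])^2)
  }
  out[2:(d[1] + 1), 2:(d[2] + 1), , drop = FALSE]
}

# exhaustive maximal-sphere local thickness: tests the sphere centred at
# every void voxel (radius = that voxel's EDT, strict < membership)
brute_local_thickness <- function(mask, voxel_size = 1) {
  e2 <- brute_edt2(mask)
  d <- dim(mask)
  vox <- which(mask, arr.ind = TRUE)
  out <- array(0, d)
  for (i in seq_len(nrow(vox))) {
    c0 <- vox[i, ]
    r2 <- e2[c0[1], c0[2], c0[3]]
    d2 <- (vox[, 1] - c0[1])^2 + (vox[, 2] - c0[2])^2 + (vox[, 3] - c0[3])^2
    th <- 2 * sqrt(r2)
    sel <- vox[d2 < r2, , drop = FALSE]
    for (j in seq_len(nrow(sel))) {
      if (out[sel[j, 1], sel[j, 2], sel[j, 3]] < th) {
        out[sel[j, 1], sel[j, 2], sel[j, 3]] <- th
      }
    }
  }
  out * voxel_size
}

# recursive-free flood-fill labeling of a 2D matrix (queue based)
brute_label2d <- function(mask, eight = TRUE) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  offs <- if (eight) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      jy <- (j - 1) %% d[1] + 1
      jx <- (j - 1) %/% d[1] + 1
      for (q in seq_len(nrow(offs))) {
        ky <- jy + offs[q, 1]
        kx <- jx + offs[q, 2]
        if (ky < 1 || ky > d[1] || kx < 1 || kx > d[2]) next
        k <- (kx - 1) * d[1] + ky
        if (mask[k] && lab[k] == 0L) {
          lab[k] <- nxt
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

# despeckle oracle built on the flood-fill labeling
brute_despeckle2d <- function(mask, min_pixels, eight = TRUE) {
  lab <- brute_label2d(mask, eight)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab, nbins = max(lab))
  mask & !(lab %in% which(sizes < min_pixels))
}

# two-tailed p-value for the correlation t statistic by numerical
# integration of the t density
quad_t_pvalue <- function(r, n) {
  tstat <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::integrate(function(x) stats::dt(x, df = n - 2),
                       lower = tstat, upper = Inf,
                       rel.tol = 1e-12)$value
}

# small fast phantom geometry used across tests
small_phantom_spec <- function(seed = 1L, length = 1200, ...) {
  phantom_spec(outer_radius = 420, wall_mid = 240, wall_end = 170,
               length = length, voxel_size = 5.8, seed = seed, ...)
}

# digitized cylinder mask along z, radius in voxels, centred
cylinder_mask <- function(radius_vox, n_xy, n_z, cy = (n_xy + 1) / 2,
                          cx = (n_xy + 1) / 2) {
  disk <- outer((seq_len(n_xy) - cy)^2, (seq_len(n_xy) - cx)^2, `+`) <
    radius_vox^2
  array(disk, c(n_xy, n_xy, n_z))
}
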