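#' Specify a synthetic two-regime compression curve
#'
#' Describes an idealized compressive stress-strain record with two linear
#' regions (a stiff initial regime and a compliant second regime), a terminal
#' stress drop at failure, and optional additive Gaussian noise. Default
#' magnitudes follow the apparent moduli of transverse cortical-bone slices:
#' modulus 1 of order 5-25 MPa, modulus 2 of order 0.7-1.4 MPa.
#'
#' @param modulus1_true First-regime slope, MPa.
#' @param modulus2_true Second-regime slope, MPa.
#' @param breakpoint_strain Strain at the regime change (0 < breakpoint <
#'   failure).
#' @param failure_strain Strain at peak stress.
#' @param peak_stress_drop_fraction Fractional stress drop after failure.
#' @param n_points Number of samples from 0 to `failure_strain` (>= 10).
#' @param noise_sd Additive Gaussian stress noise, MPa.
#' @param seed Integer seed (bit-reproducible curves).
#' @return An object of class `curve_spec`.
#' @export
curve_spec <- function(modulus1_true = 15, modulus2_true = 1.4,
                       breakpoint_strain = 0.02, failure_strain = 0.06,
                       peak_stress_drop_fraction = 0.3, n_points = 200L,
                       noise_sd = 0, seed = 1L) {
  if (!(breakpoint_strain > 0 && breakpoint_strain < failure_strain)) {
    abort("Need 0 < breakpoint_strain < failure_strain.")
  }
  if (modulus1_true <= 0 || modulus2_true <= 0) {
    abort("Both true moduli must be positive.")
  }
  if (n_points < 10) {
    abort("`n_points` must be >= 10 (the fit needs support on both segments).")
  }
  structure(list(modulus1_true = modulus1_true, modulus2_true = modulus2_true,
                 breakpoint_strain = breakpoint_strain,
                 failure_strain = failure_strain,
                 peak_stress_drop_fraction = peak_stress_drop_fraction,
                 n_points = as.integer(n_points), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "curve_spec")
}

#' Generate a synthetic stress-strain curve
#'
#' Samples the bilinear law on a uniform strain grid from 0 to the failure
#' strain (continuous at the breakpoint), appends a short post-peak tail with
#' the terminal stress drop, and adds Gaussian noise. Deterministic for fixed
#' seed.
#'
#' @param spec A [curve_spec()].
#' @return A tibble with columns `strain`, `stress` (MPa) carrying the
#'   generating parameters as the `"curve_spec"` attribute.
#' @export
generate_stress_strain <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  strain <- seq(0, spec$failure_strain, length.out = spec$n_points)
  stress <- bilinear_stress(strain, spec$modulus1_true, spec$modulus2_true,
                            spec$breakpoint_strain)
  peak <- max(stress)
  dstep <- spec$failure_strain / (spec$n_points - 1)
  n_drop <- 3L
  drop_strain <- spec$failure_strain + dstep * seq_len(n_drop)
  drop_stress <- peak * (1 - spec$peak_stress_drop_fraction *
                           seq_len(n_drop) / n_drop)
  strain <- c(strain, drop_strain)
  stress <- c(stress, drop_stress)
  if (spec$noise_sd > 0) {
    stress <- withr::with_seed(spec$seed,
                               stress + rnorm(length(stress), 0, spec$noise_sd))
  }
  out <- tibble(strain = strain, stress = stress)
  attr(out, "curve_spec") <- spec
  out
}

bilinear_stress <- function(strain, m1, m2, bp) {
  ifelse(strain <= bp, m1 * strain, m1 * bp + m2 * (strain - bp))
}

#' Convert a force-displacement record to stress-strain
#'
#' Engineering strain is displacement over the slice thickness; stress is
#' force over the loaded area. The curve is origin-shifted so the first
#' sample is (0, 0).
#'
#' @param rec A data frame with columns `displacement_mm` and `force_N`.
#' @param slice_thickness Specimen thickness, mm (nominal 2.0).
#' @param load_area Loaded cross-sectional area, mm^2.
#' @param monotone_tol Tolerated backward displacement step, mm, before the
#'   record is rejected as non-monotone.
#' @return A tibble with columns `strain`, `stress` (MPa).
#' @export
to_stress_strain <- function(rec, slice_thickness = 2.0, load_area,
                             monotone_tol = 1e-9) {
  if (!all(c("displacement_mm", "force_N") %in% names(rec))) {
    abort("`rec` needs columns `displacement_mm` and `force_N`.")
  }
  if (load_area <= 0 || slice_thickness <= 0) {
    abort("`load_area` and `slice_thickness` must be positive.")
  }
  dd <- diff(rec$displacement_mm)
  bad <- which(dd < -monotone_tol)
  if (length(bad)) {
    abort(sprintf("Displacement decreases at indices: %s",
                  paste(head(bad + 1, 10), collapse = ", ")))
  }
  tibble(
    strain = (rec$displacement_mm - rec$displacement_mm[1]) / slice_thickness,
    stress = (rec$force_N - rec$force_N[1]) / load_area)
}

#' Continuous two-segment (bilinear) least-squares fit
#'
#' Operationalizes the "two distinct linear regions" of a compressive
#' stress-strain curve as a continuous piecewise-linear least-squares fit
#' with exhaustive breakpoint search. Candidate breakpoints run over an
#' interior grid of the pre-peak samples (excluding the first and last 10%);
#' the grid optimum is then refined continuously within its bracketing
#' interval. Ties in total squared error are broken toward the smaller
#' breakpoint strain. The fit domain ends at the peak-stress index; maximum
#' compressive strength is the sample maximum of stress over the full record.
#'
#' @param curve A data frame with columns `strain` and `stress` (MPa).
#' @param min_strain Optional toe-region cut: samples with strain below this
#'   are excluded from the fit (none by default; no preload is assumed).
#' @param edge_fraction Fraction of pre-peak points excluded from each end of
#'   the candidate breakpoint grid.
#' @return An object of class `bilinear_fit`: modulus1, modulus2 (MPa),
#'   breakpoint_strain, max_strength (MPa), sse, n_points_used, and the
#'   fitted coefficients.
#' @export
fit_bilinear <- function(curve, min_strain = 0, edge_fraction = 0.1) {
  if (!all(c("strain", "stress") %in% names(curve))) {
    abort("`curve` needs columns `strain` and `stress`.")
  }
  if (sd(curve$stress) == 0) {
    abort("Degenerate record: stress has zero variance.")
  }
  peak_i <- which.max(curve$stress)
  max_strength <- curve$stress[peak_i]
  pre <- curve[seq_len(peak_i), , drop = FALSE]
  pre <- pre[pre$strain >= min_strain, , drop = FALSE]
  n <- nrow(pre)
  if (n < 10) abort("Need at least 10 points before the peak-stress index.")
  if (sd(pre$stress) == 0) abort("Degenerate record: stress has zero variance.")

  eps <- pre$strain
  sig <- pre$stress
  lo <- max(2L, as.integer(ceiling(n * edge_fraction)))
  hi <- min(n - 1L, as.integer(floor(n * (1 - edge_fraction))))
  if (hi <= lo) {
    lo <- 2L
    hi <- n - 1L
  }
  cand <- unique(eps[lo:hi])

  sse_at <- function(b) {
    x2 <- pmax(eps - b, 0)
    ft <- lm.fit(cbind(1, eps, x2), sig)
    sum(ft$residuals^2)
  }
  sses <- vapply(cand, sse_at, numeric(1))
  best_sse <- min(sses)
  tol <- max(1e-12, 1e-9 * best_sse)
  best_i <- which(sses <= best_sse + tol)[1]  # tie-break: smaller breakpoint
  b <- cand[best_i]

  # continuous refinement within the bracketing candidate interval
  b_lo <- if (best_i > 1) cand[best_i - 1] else b
  b_hi <- if (best_i < length(cand)) cand[best_i + 1] else b
  if (b_hi > b_lo) {
    op <- optimize(sse_at, lower = b_lo, upper = b_hi, tol = 1e-12)
    if (op$objective < sses[best_i] - tol) b <- op$minimum
  }

  x2 <- pmax(eps - b, 0)
  ft <- lm.fit(cbind(1, eps, x2), sig)
  cf <- ft$coefficients
  structure(list(
    modulus1 = unname(cf[2]),
    modulus2 = unname(cf[2] + cf[3]),
    breakpoint_strain = b,
    max_strength = max_strength,
    sse = sum(ft$residuals^2),
    n_points_used = n,
    intercept = unname(cf[1])),
    class = "bilinear_fit")
}

#' @export
print.bilinear_fit <- function(x, ...) {
  cat(sprintf(paste0("<bilinear_fit> modulus1 = %.4g MPa, modulus2 = %.4g MPa, ",
                     "breakpoint strain = %.4g\n  max strength = %.4g MPa, ",
                     "SSE = %.3g (n = %d)\n"),
              x$modulus1, x$modulus2, x$breakpoint_strain, x$max_strength,
              x$sse, x$n_points_used))
  invisible(x)
}

#' @describeIn fit_bilinear Broom-style one-row-per-term coefficients.
#' @param x A `bilinear_fit`.
#' @param ... Unused.
#' @method tidy bilinear_fit
#' @export
tidy.bilinear_fit <- function(x, ...) {
  tibble(term = c("modulus1", "modulus2", "breakpoint_strain"),
         estimate = c(x$modulus1, x$modulus2, x$breakpoint_strain),
         unit = c("MPa", "MPa", "strain"))
}

#' @describeIn fit_bilinear Broom-style one-row fit summary.
#' @method glance bilinear_fit
#' @export
glance.bilinear_fit <- function(x, ...) {
  tibble(modulus1 = x$modulus1, modulus2 = x$modulus2,
         breakpoint_strain = x$breakpoint_strain,
         max_strength = x$max_strength, sse = x$sse,
         n_points_used = x$n_points_used)
}
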