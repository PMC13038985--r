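#' Run the full synthetic study end-to-end
#'
#' Generates `n_replicates` graded cortical phantoms (noisy grayscale),
#' segments them with the default threshold/despeckle pipeline, assembles
#' radial/longitudinal/thickness profiles, synthesizes position-matched
#' compression curves whose true moduli decrease with the phantom's true
#' porosity, extracts modulus 1 / modulus 2 by bilinear fitting, pairs
#' structure with mechanics by position, and reports the study correlations.
#' All outputs are plain CSV/JSON and are byte-reproducible for a fixed seed.
#'
#' The demo phantom is a scaled-down shell (outer radius 600 um, wall
#' 250-380 um, length 3 mm) so the whole study runs in a couple of minutes;
#' the gradient profiles use the same default axial/radial laws as
#' [phantom_spec()].
#'
#' @param out_dir Output directory (created if needed); `NULL` skips writing.
#' @param seed Master seed; every random stage derives its own seed from it.
#' @param n_replicates Number of phantom replicates (the study used 3).
#' @param step Longitudinal sampling interval, um.
#' @param depths ROI depths, um.
#' @param noise_sd Grayscale noise for the demo phantoms.
#' @return An object of class `demo_study`: list with `profiles` (per
#'   replicate), `structure` (per position x replicate tibble), `mech`
#'   (fitted moduli), `paired`, `report` (a `study_report`), and `files`.
#' @export
run_demo_study <- function(out_dir = NULL, seed = 1L, n_replicates = 3L,
                           step = 500, depths = c(250, 500),
                           noise_sd = 10) {
  seed <- as.integer(seed)
  structure_rows <- list()
  mech_rows <- list()
  profiles_all <- list()
  thickness_rows <- list()

  for (r in seq_len(n_replicates)) {
    spec <- phantom_spec(outer_radius = 600, wall_mid = 380, wall_end = 250,
                         length = 3000, voxel_size = 5.8,
                         noise_sd = noise_sd, seed = seed * 100L + r)
    ph <- generate_cortical_phantom(spec)
    mask <- segment_volume(ph$volume)
    env <- build_envelope(mask, closing_radius = 150)
    prof <- assemble_profiles(mask, envelope = env, step = step,
                              depths = depths)
    truth <- true_profile(ph$truth, rois = prof$rois)
    profiles_all[[r]] <- prof

    struct_r <- prof$radial |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(porosity = mean(.data$porosity, na.rm = TRUE),
                       mean_diameter = mean(.data$mean_diameter, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::left_join(
        prof$thickness_mean, by = "position") |>
      dplyr::mutate(replicate = r, position = .data$position / 1000)
    structure_rows[[r]] <- struct_r

    true_pos <- truth |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(true_porosity = mean(.data$true_porosity, na.rm = TRUE),
                       .groups = "drop")
    thickness_rows[[r]] <- prof$thickness |> dplyr::mutate(replicate = r)

    for (k in seq_len(nrow(true_pos))) {
      p_t <- true_pos$true_porosity[k]
      if (!is.finite(p_t)) next
      m1 <- max(26 - 55 * p_t, 1)
      m2 <- max(1.5 - 2 * p_t, 0.1)
      cs <- curve_spec(modulus1_true = m1, modulus2_true = m2,
                       breakpoint_strain = 0.02, failure_strain = 0.06,
                       n_points = 150L, noise_sd = 0.003,
                       seed = seed * 1000L + r * 100L + k)
      fit <- fit_bilinear(generate_stress_strain(cs))
      mech_rows[[length(mech_rows) + 1L]] <- tibble(
        position = true_pos$position[k] / 1000, replicate = r,
        modulus1 = fit$modulus1, modulus2 = fit$modulus2,
        max_strength = fit$max_strength,
        modulus1_true = m1, modulus2_true = m2, true_porosity = p_t)
    }
  }

  structure_table <- dplyr::bind_rows(structure_rows)
  mech_table <- dplyr::bind_rows(mech_rows)

  paired <- dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
    pair_by_position(
      structure_table[structure_table$replicate == r,
                      setdiff(names(structure_table), "replicate")],
      mech_table[mech_table$replicate == r, , drop = FALSE],
      tolerance = 0.5)
  }))
  report <- summarize_study(paired)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      path <- file.path(out_dir, name)
      readr::write_csv(df, path)
      path
    }
    radial_all <- dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
      profiles_all[[r]]$radial |> dplyr::mutate(replicate = r)
    }))
    directional_all <- dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
      profiles_all[[r]]$directional |> dplyr::mutate(replicate = r)
    }))
    files <- c(files, w(radial_all, "radial_profile.csv"))
    for (d in depths) {
      files <- c(files,
                 w(radial_all[radial_all$depth == d, , drop = FALSE],
                   sprintf("longitudinal_profile_%d.csv", d)))
    }
    files <- c(files,
               w(directional_all, "directional_profile.csv"),
               w(dplyr::bind_rows(thickness_rows), "cortical_thickness.csv"),
               w(mech_table, "mech_fits.csv"),
               w(paired, "paired.csv"))
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(correlations = report$correlations,
           covariation = report$covariation,
           n_matched = report$n_matched, n_unmatched = report$n_unmatched),
      report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    cfg_path <- file.path(out_dir, "config.json")
    write_config(run_config(step = step, depths = depths,
                            closing_radius = 150, seed = seed), cfg_path)
    files <- c(files, report_path, cfg_path)
  }

  structure(list(profiles = profiles_all, structure = structure_table,
                 mech = mech_table, paired = paired, report = report,
                 files = files, seed = seed),
            class = "demo_study")
}

#' @export
print.demo_study <- function(x, ...) {
  cat(sprintf("<demo_study> %d replicates, %d structure rows, %d mech fits\n",
              length(x$profiles), nrow(x$structure), nrow(x$mech)))
  print(x$report)
  invisible(x)
}
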