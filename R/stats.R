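#' Pair structural and mechanical records by longitudinal position
#'
#' Nearest-position matching of each mechanics record to at most one
#' structural record within a tolerance. Ambiguous matches are broken to the
#' nearest structure position; exact distance ties go to the smaller position.
#' Unmatched mechanics rows are retained and flagged rather than dropped.
#'
#' @param structure_table A data frame with a `position` column (mm) plus
#'   structural covariates (porosity, mean_diameter, ...).
#' @param mech_table A data frame with a `position` column (mm) plus
#'   mechanical covariates (modulus1, modulus2, max_strength, ...).
#' @param tolerance Maximum pairing distance, mm.
#' @return A tibble with one row per mechanics record: mechanics columns,
#'   matched structure columns (prefixed `struct_` on name collision),
#'   `matched` flag and `pair_distance`.
#' @export
pair_by_position <- function(structure_table, mech_table, tolerance = 0.5) {
  if (!("position" %in% names(structure_table)) ||
      !("position" %in% names(mech_table))) {
    abort("Both tables need a `position` column on the same distal-origin axis.")
  }
  st <- as_tibble(structure_table)
  mech <- as_tibble(mech_table)
  st <- st[order(st$position), , drop = FALSE]

  clash <- setdiff(intersect(names(st), names(mech)), "position")
  names(st)[names(st) %in% clash] <- paste0("struct_", clash)
  names(st)[names(st) == "position"] <- "struct_position"

  rows <- purrr::map(seq_len(nrow(mech)), function(i) {
    p <- mech$position[i]
    dist <- abs(st$struct_position - p)
    j <- which(dist == min(dist))[1]  # ties at equal distance: smaller position
    if (nrow(st) == 0 || dist[j] > tolerance) {
      out <- dplyr::bind_cols(mech[i, ],
                              st[0, ][1, , drop = FALSE])
      out$matched <- FALSE
      out$pair_distance <- NA_real_
      return(out)
    }
    out <- dplyr::bind_cols(mech[i, ], st[j, ])
    out$matched <- TRUE
    out$pair_distance <- dist[j]
    out
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation with a two-tailed t-test
#'
#' Product-moment correlation; the p-value comes from the t statistic
#' `r * sqrt((n - 2) / (1 - r^2))` against the t distribution with `n - 2`
#' degrees of freedom, two-tailed.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @param var_x,var_y Variable names recorded in the result.
#' @return A one-row tibble: `var_x`, `var_y`, `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y,
                        var_x = paste(deparse(substitute(x)), collapse = " "),
                        var_y = paste(deparse(substitute(y)), collapse = " ")) {
  force(var_x)
  force(var_y)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Pearson correlation needs at least 3 complete pairs.")
  if (sd(x) == 0) abort(sprintf("Zero variance in `%s`.", var_x))
  if (sd(y) == 0) abort(sprintf("Zero variance in `%s`.", var_y))
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(var_x = var_x, var_y = var_y,
         r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlate microstructure with compressive properties
#'
#' Computes the four study correlations (porosity and canal diameter against
#' modulus 1 and modulus 2) for the pooled data and per replicate, plus the
#' longitudinal co-variation table. Correlation failures (too few pairs,
#' zero variance) degrade to NA rows with the reason recorded.
#'
#' @param paired Output of [pair_by_position()] (or any data frame with
#'   columns `porosity`, `mean_diameter`, `modulus1`, `modulus2`, optionally
#'   `replicate`, `position`, `matched`).
#' @param alpha Two-tailed significance level used for the `significant`
#'   column (no multiple-testing correction, matching the study design;
#'   `p_adjust = "holm"` is available).
#' @param p_adjust Either "none" (default) or a method for [stats::p.adjust()].
#' @return An object of class `study_report`: list with `correlations`
#'   (pooled and per-replicate tibble), `covariation` (per-position means),
#'   and `n_matched` / `n_unmatched` bookkeeping.
#' @export
summarize_study <- function(paired, alpha = 0.05, p_adjust = "none") {
  pr <- as_tibble(paired)
  if (!"matched" %in% names(pr)) pr$matched <- TRUE
  n_total <- nrow(pr)
  pr_m <- pr[pr$matched, , drop = FALSE]
  if (!"replicate" %in% names(pr_m)) pr_m$replicate <- 1L

  pairs <- tidyr::expand_grid(
    sv = c("porosity", "mean_diameter"),
    mv = c("modulus1", "modulus2"))

  corr_one <- function(df, scope) {
    purrr::pmap(pairs, function(sv, mv) {
      res <- tryCatch(
        pearson_cor(df[[sv]], df[[mv]], var_x = sv, var_y = mv),
        error = function(e) {
          tibble(var_x = sv, var_y = mv, r = NA_real_, p = NA_real_,
                 n = sum(is.finite(df[[sv]]) & is.finite(df[[mv]])))
        })
      res$scope <- scope
      res
    }) |> dplyr::bind_rows()
  }

  correlations <- dplyr::bind_rows(
    corr_one(pr_m, "pooled"),
    pr_m |>
      dplyr::group_split(.data$replicate) |>
      purrr::map(~ corr_one(.x, paste0("replicate_", .x$replicate[1]))) |>
      dplyr::bind_rows())
  if (p_adjust != "none") {
    correlations$p_adjusted <- stats::p.adjust(correlations$p,
                                               method = p_adjust)
    correlations$significant <- !is.na(correlations$p_adjusted) &
      correlations$p_adjusted < alpha
  } else {
    correlations$significant <- !is.na(correlations$p) & correlations$p < alpha
  }

  covariation <- NULL
  if ("position" %in% names(pr_m)) {
    covariation <- pr_m |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(dplyr::across(
        dplyr::any_of(c("porosity", "mean_diameter", "modulus1", "modulus2",
                        "max_strength", "thickness_mm")),
        ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  }

  structure(list(correlations = correlations, covariation = covariation,
                 n_matched = nrow(pr_m), n_unmatched = n_total - nrow(pr_m),
                 alpha = alpha),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d matched pairs (%d unmatched)\n",
              x$n_matched, x$n_unmatched))
  pooled <- x$correlations[x$correlations$scope == "pooled", ]
  for (i in seq_len(nrow(pooled))) {
    cat(sprintf("  %s ~ %s: r = %+.3f, p = %.3g (n = %d)\n",
                pooled$var_x[i], pooled$var_y[i], pooled$r[i], pooled$p[i],
                pooled$n[i]))
  }
  invisible(x)
}
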