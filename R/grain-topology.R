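#' Assign grains to cohorts (rings) by bottom-up scanning
#'
#' Iterative grouping: the window is half the mean grain width (in px) of all
#' grains in the view; the seed is the lowest unassigned barycentre; every
#' unassigned grain whose barycentre lies within the window above the seed
#' joins the current cohort; assigned grains are removed and the scan repeats.
#' Ranks run from 1 at the ear bottom. Ties at the window boundary are
#' inclusive.
#'
#' @param grains Data frame from [extract_grains()] (one view).
#' @param window_factor Fraction of the mean grain width used as the grouping
#'   window. Default 0.5.
#' @return `grains` with an integer `cohort` column (rank from the bottom).
#' @export
assign_cohorts <- function(grains, window_factor = 0.5) {
  grains$cohort <- integer(nrow(grains))
  if (nrow(grains) == 0) return(grains)
  window <- window_factor * mean(grains$width_px)
  unassigned <- rep(TRUE, nrow(grains))
  rank <- 0L
  while (any(unassigned)) {
    rank <- rank + 1L
    seed_row <- max(grains$row_c[unassigned])   # lowest grain = max raster row
    members <- unassigned & grains$row_c >= seed_row - window
    grains$cohort[members] <- rank
    unassigned[members] <- FALSE
  }
  grains
}

#' Cohort-count profile by horizontal-line crossings
#'
#' Each grain is reduced to a one-pixel-high horizontal segment spanning its
#' bounding-box extent. For every image column the profile counts how many
#' segments it crosses on a bottom-to-top scan; since cohorts are incomplete
#' on the ear sides, the maximum over columns estimates the number of cohorts
#' visible in the view.
#'
#' @param grains Data frame from [extract_grains()].
#' @param n_cols Number of raster columns of the view.
#' @return A list of class `cohort_count_profile` with `counts` (per column)
#'   and `max` (the cohort-count estimate; 0 without grains).
#' @export
cohort_count_profile <- function(grains, n_cols) {
  counts <- integer(n_cols)
  if (nrow(grains) > 0) {
    for (g in seq_len(nrow(grains))) {
      cols <- grains$cmin[g]:grains$cmax[g]
      counts[cols] <- counts[cols] + 1L
    }
  }
  structure(list(counts = counts, max = if (length(counts)) max(counts) else 0L),
            class = "cohort_count_profile")
}

#' Grains-per-cohort profile from vertical-line crossings
#'
#' Each grain is reduced to a one-pixel-wide vertical segment at its
#' barycentre column. For every ear row the crossing columns are sorted, the
#' gaps between consecutive crossings are converted to arc lengths on the
#' ear's circular section (radius = half the row diameter, offsets measured
#' from the central axis), and their mean \eqn{Dist_i} combined with the row
#' perimeter gives the estimate \eqn{\pi \cdot Diameter_i / Dist_i}. Rows
#' crossed by fewer than two segments carry `NA`. The wrap-around gap is not
#' part of the mean: the perimeter-to-gap ratio itself extrapolates the
#' visible arc to the full circle.
#'
#' @param grains Data frame from [extract_grains()].
#' @param axis [central_axis()] of the view.
#' @param diam_profile [diameter_profile()] of the view.
#' @param pixel_scale Raster resolution in px per cm.
#' @return A data frame of class `grains_per_cohort_profile` with columns
#'   `row` (bottom to top), `n_cross`, `dist_cm`, `diameter_cm`, `estimate`.
#' @export
grains_per_cohort_profile <- function(grains, axis, diam_profile, pixel_scale) {
  stopifnot(inherits(axis, "central_axis"), pixel_scale > 0)
  rows <- axis$rows
  out <- data.frame(row = rows, n_cross = 0L, dist_cm = NA_real_,
                    diameter_cm = diam_profile$diameter_cm[match(rows, diam_profile$row)],
                    estimate = NA_real_)
  if (nrow(grains) > 0) {
    for (i in seq_along(rows)) {
      r <- rows[i]
      cross <- grains$rmin <= r & grains$rmax >= r
      nc <- sum(cross)
      out$n_cross[i] <- nc
      if (nc < 2) next
      cols <- sort(grains$col_c[cross])
      R <- out$diameter_cm[i] / 2
      offs <- (cols - axis$centre[i]) / pixel_scale
      gaps <- arc_correct(offs[-length(offs)], offs[-1], R, warn = FALSE)
      dist_i <- mean(gaps)
      out$dist_cm[i] <- dist_i
      if (dist_i > 0) out$estimate[i] <- pi * out$diameter_cm[i] / dist_i
    }
  }
  class(out) <- c("grains_per_cohort_profile", "data.frame")
  out
}

# Zone index (1 basal, 2 median, 3 apical) for each position of a
# bottom-to-top sequence of n ear rows, split into three equal thirds.
zone_thirds <- function(n) {
  if (n == 0) return(integer())
  pmin(ceiling(3 * seq_len(n) / n), 3L)
}

#' Composite grain-number estimate for one view
#'
#' Averages an over-estimator (mean grains-per-cohort in the median third of
#' ear rows times the maximum cohort count) and an under-estimator that sums,
#' over the basal/median/apical thirds, the zone mean grains-per-cohort times
#' the number of cohorts observed in that zone. The under-estimator reading is
#' configurable via `under_strategy`: `"zonal_max"` (default) takes the zone
#' cohort count as the maximum per-column crossing count among the zone's
#' grains, so a perfect fully-set lattice yields cohorts times
#' grains-per-cohort from both estimators; `"zonal_mean"` averages the
#' crossing counts over the columns the zone's segments span, which discounts
#' incomplete limb coverage and reads lower.
#'
#' @inheritParams grains_per_cohort_profile
#' @param n_cols Number of raster columns of the view.
#' @param under_strategy Under-estimator variant, see Description.
#' @return A list with `over`, `under`, `estimate` (their mean),
#'   `n_cohorts` (max crossing count), and the `gpc` profile.
#' @export
grain_number_view <- function(grains, axis, diam_profile, pixel_scale, n_cols,
                              under_strategy = c("zonal_max", "zonal_mean")) {
  under_strategy <- match.arg(under_strategy)
  gpc <- grains_per_cohort_profile(grains, axis, diam_profile, pixel_scale)
  ccp <- cohort_count_profile(grains, n_cols)
  nz <- zone_thirds(nrow(gpc))
  zone_mean_est <- function(z) {
    v <- gpc$estimate[nz == z]
    if (all(is.na(v))) 0 else mean(v, na.rm = TRUE)
  }
  over <- zone_mean_est(2L) * ccp$max

  grain_zone <- nz[match(round(grains$row_c), gpc$row)]
  under <- 0
  for (z in 1:3) {
    gz <- grains[!is.na(grain_zone) & grain_zone == z, , drop = FALSE]
    if (nrow(gz) == 0) next
    cz <- cohort_count_profile(gz, n_cols)
    mz <- switch(under_strategy,
                 zonal_mean = mean(cz$counts[cz$counts > 0]),
                 zonal_max = cz$max)
    under <- under + zone_mean_est(z) * mz
  }
  list(over = over, under = under, estimate = (over + under) / 2,
       n_cohorts = ccp$max, gpc = gpc)
}

#' Grain number per ear from all views
#'
#' @param view_estimates List of results from [grain_number_view()], one per
#'   view of the same ear.
#' @return The mean over views of the composite per-view estimates (0 for a
#'   barren ear).
#' @export
grain_number_per_ear <- function(view_estimates) {
  if (length(view_estimates) == 0) return(0)
  mean(vapply(view_estimates, function(v) v$estimate, numeric(1)))
}
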