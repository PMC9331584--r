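#' Extract per-grain measurements from a label mask
#'
#' One record per distinct positive label: barycentre (mean pixel coordinate)
#' and the axis-aligned bounding rectangle. Rectangles are axis-aligned
#' because grain height and width are defined relative to the (vertical) ear
#' axis after orientation.
#'
#' @param label_mask Integer matrix, background 0, one positive label per
#'   grain instance.
#' @return A data frame with columns `label`, `row_c`, `col_c` (barycentre,
#'   px), `rmin`, `rmax`, `cmin`, `cmax`, `height_px`, `width_px`, `area_px`.
#'   Empty mask gives zero rows.
#' @export
extract_grains <- function(label_mask) {
  if (any(label_mask < 0)) stop("label mask must be non-negative")
  idx <- which(label_mask > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), row_c = numeric(), col_c = numeric(),
                      rmin = integer(), rmax = integer(), cmin = integer(),
                      cmax = integer(), height_px = numeric(),
                      width_px = numeric(), area_px = integer()))
  lab <- label_mask[idx]
  H <- nrow(label_mask)
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  f <- factor(lab)
  out <- data.frame(
    label = as.integer(levels(f)),
    row_c = as.numeric(tapply(rows, f, mean)),
    col_c = as.numeric(tapply(cols, f, mean)),
    rmin = as.integer(tapply(rows, f, min)),
    rmax = as.integer(tapply(rows, f, max)),
    cmin = as.integer(tapply(cols, f, min)),
    cmax = as.integer(tapply(cols, f, max)))
  out$height_px <- out$rmax - out$rmin + 1
  out$width_px <- out$cmax - out$cmin + 1
  out$area_px <- as.integer(tapply(rows, f, length))
  rownames(out) <- NULL
  out
}

#' Cylindrical arc-length correction
#'
#' Distances measured horizontally on the image are chords of the ear's
#' (assumed circular) cross-section. Given the signed horizontal offsets of
#' two points from the ear centreline and the section radius, the
#' corresponding arc length on the cylinder surface is
#' \eqn{R \, | \asin(x_2/R) - \asin(x_1/R) |}. Offsets beyond the limb are
#' clamped to the radius (the projection is then tangent to the section).
#'
#' @param x1_offset,x2_offset Signed horizontal offsets from the ear
#'   centreline, cm. Vectorized.
#' @param radius Section radius in cm, positive.
#' @param warn Emit a warning when offsets are clamped to the limb.
#' @return Arc length(s) in cm, always at least the chord length.
#' @export
arc_correct <- function(x1_offset, x2_offset, radius, warn = TRUE) {
  if (any(radius <= 0)) stop("'radius' must be positive")
  s1 <- x1_offset / radius
  s2 <- x2_offset / radius
  if (any(abs(s1) > 1) || any(abs(s2) > 1)) {
    if (warn)
      warning("offset beyond the ear limb; clamped to the radius",
              call. = FALSE)
    s1 <- pmin(pmax(s1, -1), 1)
    s2 <- pmin(pmax(s2, -1), 1)
  }
  radius * abs(asin(s2) - asin(s1))
}

#' Grain dimensions in cm with arc-corrected width
#'
#' Grain height is the bounding-rectangle extent along the ear axis divided by
#' the pixel scale. Grain width is the arc length between the rectangle's left
#' and right edges, with offsets measured from the central axis at the grain's
#' barycentre row (tolerating bowed ears) and radius equal to half the ear
#' diameter at that row.
#'
#' @param grains Data frame from [extract_grains()].
#' @param axis [central_axis()] of the same view.
#' @param diam_profile [diameter_profile()] of the same view.
#' @param pixel_scale Raster resolution in px per cm.
#' @return `grains` with added columns `height_cm`, `width_cm`,
#'   `near_limb` (offset clamped or within 2% of the limb) and `invalid`
#'   (no diameter defined at the barycentre row).
#' @export
grain_dimensions <- function(grains, axis, diam_profile, pixel_scale) {
  stopifnot(inherits(axis, "central_axis"), pixel_scale > 0)
  n <- nrow(grains)
  grains$height_cm <- grains$height_px / pixel_scale
  grains$width_cm <- NA_real_
  grains$near_limb <- FALSE
  grains$invalid <- FALSE
  if (n == 0) return(grains)
  rr <- round(grains$row_c)
  ai <- match(rr, axis$rows)
  di <- match(rr, diam_profile$row)
  clamped_any <- FALSE
  for (g in seq_len(n)) {
    if (is.na(ai[g]) || is.na(di[g]) ||
        diam_profile$diameter_cm[di[g]] <= 0) {
      grains$invalid[g] <- TRUE
      next
    }
    R <- diam_profile$diameter_cm[di[g]] / 2
    cx <- axis$centre[ai[g]]
    x1 <- (grains$cmin[g] - 0.5 - cx) / pixel_scale
    x2 <- (grains$cmax[g] + 0.5 - cx) / pixel_scale
    if (max(abs(c(x1, x2))) > 0.98 * R) {
      grains$near_limb[g] <- TRUE
      if (max(abs(c(x1, x2))) > R) clamped_any <- TRUE
    }
    grains$width_cm[g] <- arc_correct(x1, x2, R, warn = FALSE)
  }
  if (clamped_any)
    warning("grain bounding box beyond the ear limb; offsets clamped",
            call. = FALSE)
  grains
}
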