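#' Acquisition plan for roller-driven multi-view ear imaging
#'
#' Describes the geometry of an imaging session in which an ear lies
#' horizontally on two motorized rollers and is rotated between successive
#' shots. Because rolling is assumed slip-free, a roller rotation of
#' `roller_step_angle` degrees turns an ear of diameter \eqn{d} by
#' `roller_step_angle * roller_diameter / d` degrees. Each image captures a
#' fixed arc of the ear circumference (`view_arc` degrees).
#'
#' @param roller_diameter Roller diameter in cm. Default 5.2.
#' @param roller_step_angle Roller rotation between consecutive images,
#'   degrees. Default 58.
#' @param n_views Number of images per ear. Default 6.
#' @param view_arc Arc of the ear circumference visible in one image,
#'   degrees in (0, 360]. Default 120.
#' @return An object of class `acquisition_plan`.
#' @examples
#' plan <- acquisition_plan()
#' ear_rotation_step(plan, ear_diameter = 2)
#' circumference_coverage(plan, ear_diameter = 4)
#' @export
acquisition_plan <- function(roller_diameter = 5.2, roller_step_angle = 58,
                             n_views = 6, view_arc = 120) {
  if (!is.numeric(roller_diameter) || roller_diameter <= 0)
    stop("'roller_diameter' must be a positive length in cm")
  if (!is.numeric(n_views) || n_views < 1)
    stop("'n_views' must be >= 1")
  if (!is.numeric(view_arc) || view_arc <= 0 || view_arc > 360)
    stop("'view_arc' must lie in (0, 360] degrees")
  structure(list(roller_diameter = roller_diameter,
                 roller_step_angle = roller_step_angle,
                 n_views = as.integer(n_views),
                 view_arc = view_arc),
            class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf(paste0("acquisition plan: roller %.2f cm, step %.1f deg, ",
                     "%d views x %.0f deg arc\n"),
              x$roller_diameter, x$roller_step_angle, x$n_views, x$view_arc))
  invisible(x)
}

#' Ear rotation per roller step
#'
#' No-slip rolling contact: the arc travelled on the roller surface equals the
#' arc travelled on the ear surface, so the ear turns by the roller step angle
#' scaled by the diameter ratio.
#'
#' @param plan An [acquisition_plan()].
#' @param ear_diameter Ear diameter(s) in cm, all positive. Vectorized.
#' @return Ear rotation step(s) in degrees.
#' @export
ear_rotation_step <- function(plan, ear_diameter) {
  stopifnot(inherits(plan, "acquisition_plan"))
  if (!is.numeric(ear_diameter) || any(!is.finite(ear_diameter)) ||
      any(ear_diameter <= 0))
    stop("'ear_diameter' must be positive and finite (cm)")
  plan$roller_step_angle * plan$roller_diameter / ear_diameter
}

# Measure of the union of circular arcs (degrees). Arcs are closed intervals
# of width `width` centred at `centres` (degrees), reduced modulo 360 and
# merged analytically so the result carries no discretization artifact.
arc_union_measure <- function(centres, width) {
  if (width >= 360) return(360)
  lo <- (centres - width / 2) %% 360
  hi <- lo + width
  wraps <- hi > 360
  starts <- c(lo[!wraps], lo[wraps], rep(0, sum(wraps)))
  ends <- c(hi[!wraps], rep(360, sum(wraps)), hi[wraps] - 360)
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  total <- 0
  cur_s <- starts[1L]
  cur_e <- ends[1L]
  eps <- 1e-9
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e + eps) {
      cur_e <- max(cur_e, ends[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]
      cur_e <- ends[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Cumulative circumference coverage of a view series
#'
#' Places `n_views` arcs of width `view_arc` at the cumulative ear rotations
#' `0, step, 2*step, ...` (the first image is taken before any rotation),
#' reduces them modulo 360 and returns the union measure as a percentage of
#' the full circumference.
#'
#' @inheritParams ear_rotation_step
#' @return Coverage in percent, in (0, 100]. Vectorized over `ear_diameter`.
#' @export
circumference_coverage <- function(plan, ear_diameter) {
  steps <- ear_rotation_step(plan, ear_diameter)
  vapply(steps, function(step) {
    centres <- (seq_len(plan$n_views) - 1) * step
    100 * arc_union_measure(centres, plan$view_arc) / 360
  }, numeric(1))
}

#' Coverage map over roller step angles and ear diameters
#'
#' Evaluates [circumference_coverage()] on a grid, one row per roller step
#' angle and one column per ear diameter, in input order.
#'
#' @inheritParams ear_rotation_step
#' @param diameters Ear diameters in cm (non-empty, positive).
#' @param step_angles Roller step angles in degrees (non-empty).
#' @return A numeric matrix of coverages in percent, with `step_angles` as
#'   rows and `diameters` as columns (dimnames carry the grid values).
#' @export
coverage_map <- function(plan, diameters, step_angles) {
  stopifnot(inherits(plan, "acquisition_plan"))
  if (length(diameters) == 0 || length(step_angles) == 0)
    stop("'diameters' and 'step_angles' must be non-empty")
  if (any(diameters <= 0)) stop("'diameters' must be positive")
  m <- matrix(NA_real_, nrow = length(step_angles), ncol = length(diameters),
              dimnames = list(step = format(step_angles, trim = TRUE),
                              diameter = format(diameters, trim = TRUE)))
  for (i in seq_along(step_angles)) {
    p <- plan
    p$roller_step_angle <- step_angles[i]
    m[i, ] <- circumference_coverage(p, diameters)
  }
  m
}
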