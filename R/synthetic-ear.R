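#' Parametric specification of a synthetic maize ear
#'
#' The generative model places grains on a cylinder-like ear body as a lattice
#' of cohorts (rings, stacked bottom to apex) by vertical files (rows around
#' the circumference), draws a set/aborted flag per grain from the chosen
#' abortion model, and renders each view by orthographic projection: a grain
#' at angular distance \eqn{\Delta\theta} from the view direction appears at
#' horizontal offset \eqn{R\sin\Delta\theta} from the centreline with its
#' width foreshortened by \eqn{\cos\Delta\theta}. Ground truth (positions,
#' flags, profiles, zone extents) is returned alongside the rasters.
#'
#' Abortion models:
#' \describe{
#'   \item{none}{every ovary sets a grain.}
#'   \item{apical}{set probability drops across a boundary at
#'     `1 - apical_fraction` of ear length, with a logistic transition about
#'     `edge_cohorts` cohorts wide (soft edge).}
#'   \item{apical_basal}{as `apical`, plus a basal aborted zone of
#'     `basal_fraction` of ear length.}
#'   \item{full}{barren ear: no grain sets.}
#'   \item{scattered}{independent per-grain set probability `set_prob` with
#'     positional jitter, mimicking pollination failure.}
#' }
#'
#' @param ear_length Ear length in cm.
#' @param max_diameter Maximum ear diameter in cm.
#' @param diameter_profile_shape One of `"cylinder"`, `"tapered"`, `"barrel"`.
#' @param n_cohorts Number of grain cohorts (rings).
#' @param grains_per_cohort Grains per complete cohort.
#' @param grain_height Grain height (along the ear axis) in cm.
#' @param grain_width Grain width (around the circumference) in cm.
#' @param abortion_model Abortion model, see Details.
#' @param abortion_params List with any of `apical_fraction`, `basal_fraction`
#'   (fractions of ear length aborted at apex/base), `set_prob` (per-grain
#'   set probability for `"scattered"`) and `edge_cohorts` (width of the
#'   logistic set-probability transition across a zone boundary, in cohorts;
#'   default 2, the soft developmental gradient).
#' @param pixel_scale Raster resolution in px per cm.
#' @param curvature Amplitude of the sinusoidal centreline bow in cm.
#' @param position_jitter Standard deviation of vertical grain position
#'   jitter in cm.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `synthetic_ear_spec`.
#' @seealso [generate_ear()], [archetype_spec()]
#' @export
synthetic_ear_spec <- function(ear_length = 12, max_diameter = 4,
                               diameter_profile_shape = c("cylinder", "tapered", "barrel"),
                               n_cohorts = 24, grains_per_cohort = 14,
                               grain_height = 0.45, grain_width = 0.8,
                               abortion_model = c("none", "apical", "apical_basal",
                                                  "full", "scattered"),
                               abortion_params = list(),
                               pixel_scale = 20, curvature = 0.3,
                               position_jitter = 0.02, seed = 1L) {
  diameter_profile_shape <- match.arg(diameter_profile_shape)
  abortion_model <- match.arg(abortion_model)
  dims <- c(ear_length = ear_length, max_diameter = max_diameter,
            grain_height = grain_height, grain_width = grain_width,
            pixel_scale = pixel_scale)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all dimensions and the pixel scale must be positive and finite")
  if (n_cohorts < 1 || grains_per_cohort < 1)
    stop("'n_cohorts' and 'grains_per_cohort' must be >= 1")
  if (n_cohorts * grain_height > ear_length)
    stop("spec cannot fit: n_cohorts * grain_height exceeds ear_length")
  ap <- utils::modifyList(list(apical_fraction = 0.3, basal_fraction = 0.1,
                               set_prob = 0.5, edge_cohorts = 2),
                          abortion_params)
  if (ap$apical_fraction < 0 || ap$basal_fraction < 0 ||
      ap$apical_fraction + ap$basal_fraction > 1)
    stop("aborted fractions must be non-negative and sum to at most 1")
  if (ap$set_prob < 0 || ap$set_prob > 1)
    stop("'set_prob' must lie in [0, 1]")
  if (ap$edge_cohorts <= 0) stop("'edge_cohorts' must be positive")
  structure(list(ear_length = ear_length, max_diameter = max_diameter,
                 diameter_profile_shape = diameter_profile_shape,
                 n_cohorts = as.integer(n_cohorts),
                 grains_per_cohort = as.integer(grains_per_cohort),
                 grain_height = grain_height, grain_width = grain_width,
                 abortion_model = abortion_model, abortion_params = ap,
                 pixel_scale = pixel_scale, curvature = curvature,
                 position_jitter = position_jitter, seed = as.integer(seed)),
            class = "synthetic_ear_spec")
}

#' Abortion archetype specifications
#'
#' Returns `base` modified to one of five canonical abortion patterns of
#' increasing severity, from a fully set ear (1) through apical-only (2),
#' apical plus basal onset (3), wide apical and basal aborted zones (4), to a
#' barren ear (5). The true fertile fraction decreases monotonically with the
#' archetype index (1.00, 0.70, 0.60, 0.40, 0.00 of ear length).
#'
#' @param cluster_id Integer in 1..5.
#' @param base A [synthetic_ear_spec()] supplying all other parameters.
#' @return A `synthetic_ear_spec`.
#' @export
archetype_spec <- function(cluster_id, base = synthetic_ear_spec()) {
  if (!is.numeric(cluster_id) || length(cluster_id) != 1 ||
      !(cluster_id %in% 1:5))
    stop("'cluster_id' must be a single integer in 1..5")
  stopifnot(inherits(base, "synthetic_ear_spec"))
  mods <- switch(as.character(cluster_id),
    "1" = list(abortion_model = "none",
               abortion_params = list(apical_fraction = 0, basal_fraction = 0)),
    "2" = list(abortion_model = "apical",
               abortion_params = list(apical_fraction = 0.30, basal_fraction = 0)),
    "3" = list(abortion_model = "apical_basal",
               abortion_params = list(apical_fraction = 0.30, basal_fraction = 0.10)),
    "4" = list(abortion_model = "apical_basal",
               abortion_params = list(apical_fraction = 0.40, basal_fraction = 0.20)),
    "5" = list(abortion_model = "full",
               abortion_params = list(apical_fraction = 0.5, basal_fraction = 0.5)))
  spec <- base
  spec$abortion_model <- mods$abortion_model
  spec$abortion_params <- utils::modifyList(spec$abortion_params,
                                            mods$abortion_params)
  spec
}

# True diameter (cm) at height z above the ear base.
diameter_at <- function(z, spec) {
  L <- spec$ear_length
  D <- spec$max_diameter
  switch(spec$diameter_profile_shape,
         cylinder = rep(D, length(z)),
         tapered = D * (1 - 0.35 * z / L),
         barrel = D * (1 - 0.30 * (2 * z / L - 1)^2))
}

# Centreline horizontal offset (cm) at height z: a single sinusoidal bow.
centreline_offset_at <- function(z, spec) {
  spec$curvature * sin(pi * z / spec$ear_length)
}

# Per-grain set probability under the spec's abortion model. Soft edges use a
# logistic transition whose 10-90% span covers about `edge_cohorts` cohorts.
set_probability <- function(z, spec) {
  L <- spec$ear_length
  ap <- spec$abortion_params
  s <- ap$edge_cohorts * (L / spec$n_cohorts) / 4
  switch(spec$abortion_model,
         none = rep(1, length(z)),
         full = rep(0, length(z)),
         scattered = rep(ap$set_prob, length(z)),
         apical = stats::plogis((L * (1 - ap$apical_fraction) - z) / s),
         apical_basal = stats::plogis((L * (1 - ap$apical_fraction) - z) / s) *
           stats::plogis((z - L * ap$basal_fraction) / s))
}

# Model-implied fertile/basal-aborted/apical-aborted zone lengths (cm).
true_zones <- function(spec) {
  L <- spec$ear_length
  ap <- spec$abortion_params
  z <- switch(spec$abortion_model,
              none = c(L, 0, 0),
              full = c(0, L / 2, L / 2),
              apical = c(L * (1 - ap$apical_fraction), 0, L * ap$apical_fraction),
              apical_basal = c(L * (1 - ap$apical_fraction - ap$basal_fraction),
                               L * ap$basal_fraction, L * ap$apical_fraction),
              scattered = if (ap$set_prob > 0.5) c(L, 0, 0) else c(0, L / 2, L / 2))
  names(z) <- c("fertile", "basal", "apical")
  z
}

# Shrink neighbouring footprint half-widths so that, after rasterization,
# at least one background pixel separates the two instances.
enforce_gaps <- function(centres, half, min_gap = 2) {
  shrunk <- FALSE
  ord <- order(centres)
  for (j in seq_along(ord)[-1L]) {
    i1 <- ord[j - 1L]
    i2 <- ord[j]
    sep <- centres[i2] - centres[i1]
    if (sep - (half[i1] + half[i2]) < min_gap) {
      f <- max(0, (sep - min_gap)) / (half[i1] + half[i2])
      if (f < 1) {
        half[i1] <- max(0.3, half[i1] * f)
        half[i2] <- max(0.3, half[i2] * f)
        shrunk <- TRUE
      }
    }
  }
  list(half = half, shrunk = shrunk)
}

#' Generate a synthetic multi-view ear with ground truth
#'
#' Renders one ear under an acquisition plan: for each view, grains whose
#' angular distance to the view direction is below half the view arc are drawn
#' as filled ellipses (width foreshortened by the cosine of that distance, a
#' one-pixel gap enforced between instances), clipped to the ear silhouette.
#' The silhouette follows the spec's diameter profile around an optionally
#' bowed centreline.
#'
#' @param spec A [synthetic_ear_spec()].
#' @param plan An [acquisition_plan()]; view k is taken after k-1 rotation
#'   steps computed from the spec's maximum diameter.
#' @param ear_id Identifier stored with the image set.
#' @return A list of class `synthetic_ear` with elements
#' \describe{
#'   \item{views}{per view: rotation `angle` (deg), `ear_mask` (integer 0/1
#'     matrix), `labels` (integer instance raster, grain ids as labels),
#'     `rgb` (H x W x 3 array), `ir` (matrix), and `rendered`, the table of
#'     grains drawn in that view.}
#'   \item{truth}{per-grain table (id, cohort, file, angle, height, set flag),
#'     true ear length along the bowed centreline, per-row diameter profile,
#'     cohort count, set-grain total, model zone extents, and the per-row true
#'     grain-set-ratio profile (bottom to top) implied by the projection
#'     geometry, averaged over views.}
#' }
#' @export
generate_ear <- function(spec, plan = acquisition_plan(), ear_id = "ear_1") {
  stopifnot(inherits(spec, "synthetic_ear_spec"),
            inherits(plan, "acquisition_plan"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  L <- spec$ear_length
  C <- spec$n_cohorts
  K <- spec$grains_per_cohort
  sc <- spec$pixel_scale
  pitch <- L / C
  n <- C * K

  cohort <- rep(seq_len(C), each = K)
  file_i <- rep(seq_len(K), times = C)
  z <- (cohort - 0.5) * pitch + stats::rnorm(n, 0, spec$position_jitter)
  phi <- (file_i - 1) * 360 / K
  if (spec$abortion_model == "scattered") {
    phi <- phi + stats::rnorm(n, 0, 0.25 * 360 / K)
    z <- z + stats::rnorm(n, 0, 0.2 * pitch)
  }
  z <- pmin(pmax(z, spec$grain_height / 2 + 1e-6),
            L - spec$grain_height / 2 - 1e-6)
  phi <- phi %% 360
  set <- stats::runif(n) < set_probability(z, spec)
  grain_col <- matrix(pmin(pmax(rep(c(0.85, 0.72, 0.30), each = n) +
                                  stats::rnorm(3 * n, 0, 0.05), 0), 1),
                      nrow = n)

  marg <- 10L
  Lpx <- round(L * sc)
  H <- Lpx + 2L * marg
  W <- as.integer(round(spec$max_diameter * sc) + 2L * marg +
                    2L * ceiling(abs(spec$curvature) * sc))
  row_base <- marg + Lpx                   # bottom-most ear row (row 1 = top)
  mid <- (W + 1) / 2

  ear_rows <- (marg + 1L):row_base
  z_rows <- (row_base - ear_rows + 0.5) / sc      # top -> bottom over ear_rows
  centre_rows <- mid + centreline_offset_at(z_rows, spec) * sc
  diam_rows_cm <- diameter_at(z_rows, spec)
  half_rows <- diam_rows_cm * sc / 2 - 0.5

  ear_mask <- matrix(0L, H, W)
  for (ii in seq_along(ear_rows)) {
    cl <- ceiling(centre_rows[ii] - half_rows[ii])
    cr <- floor(centre_rows[ii] + half_rows[ii])
    ear_mask[ear_rows[ii], cl:cr] <- 1L
  }
  width_rows_px <- floor(centre_rows + half_rows) -
    ceiling(centre_rows - half_rows) + 1

  step <- ear_rotation_step(plan, spec$max_diameter)
  views <- vector("list", plan$n_views)
  gsr_acc <- numeric(Lpx)                  # bottom -> top
  any_shrunk <- FALSE

  for (k in seq_len(plan$n_views)) {
    psi <- (k - 1) * step
    delta <- ((phi - psi + 180) %% 360) - 180
    vis <- abs(delta) < plan$view_arc / 2 & set
    idx <- which(vis)
    labels <- matrix(0L, H, W)
    rgb <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      pl <- rgb[, , ch]
      pl[ear_mask == 1L] <- c(0.45, 0.30, 0.18)[ch]
      rgb[, , ch] <- pl
    }

    if (length(idx)) {
      zg <- z[idx]
      dg <- delta[idx] * pi / 180
      Rz <- diameter_at(zg, spec) / 2
      r0 <- row_base + 0.5 - zg * sc
      c0 <- mid + centreline_offset_at(zg, spec) * sc + Rz * sin(dg) * sc
      a <- pmax(spec$grain_width * cos(dg) * sc / 2 - 0.5, 0.6)
      b <- pmax(rep(spec$grain_height * sc / 2 - 0.5, length(idx)), 0.6)

      for (co in unique(cohort[idx])) {
        sel <- which(cohort[idx] == co)
        if (length(sel) > 1) {
          eg <- enforce_gaps(c0[sel], a[sel])
          a[sel] <- eg$half
          any_shrunk <- any_shrunk || eg$shrunk
        }
      }
      for (fi in unique(file_i[idx])) {
        sel <- which(file_i[idx] == fi)
        if (length(sel) > 1) {
          eg <- enforce_gaps(r0[sel], b[sel])
          b[sel] <- eg$half
          any_shrunk <- any_shrunk || eg$shrunk
        }
      }

      for (g in seq_along(idx)) {
        id <- idx[g]
        rr <- max(1L, ceiling(r0[g] - b[g])):min(H, floor(r0[g] + b[g]))
        dz <- (rr - r0[g]) / b[g]
        hw <- a[g] * sqrt(pmax(0, 1 - dz^2))
        for (jj in seq_along(rr)) {
          cl <- ceiling(c0[g] - hw[jj])
          cr <- floor(c0[g] + hw[jj])
          if (cl > cr) next
          cols <- cl:cr
          ok <- ear_mask[rr[jj], cols] == 1L & labels[rr[jj], cols] == 0L
          labels[rr[jj], cols[ok]] <- id
          for (ch in 1:3) rgb[cbind(rr[jj], cols[ok], ch)] <- grain_col[id, ch]
        }
        rc <- round(r0[g]); cc <- round(c0[g])
        if (rc >= 1 && rc <= H && cc >= 1 && cc <= W &&
            ear_mask[rc, cc] == 1L && labels[rc, cc] == 0L) {
          labels[rc, cc] <- id
          for (ch in 1:3) rgb[rc, cc, ch] <- grain_col[id, ch]
        }

        # analytic (pre-raster) footprint contribution to the true GSR;
        # the expected pixel count of an interval of length 2*hw is 2*hw
        ib <- (row_base - rr) + 1L          # bottom -> top index
        chord <- 2 * hw
        keep <- ib >= 1 & ib <= Lpx
        gsr_acc[ib[keep]] <- gsr_acc[ib[keep]] +
          chord[keep] / width_rows_px[match(rr[keep], ear_rows)] / plan$n_views
      }
      rendered <- data.frame(id = idx, cohort = cohort[idx],
                             delta_deg = delta[idx], row = r0, col = c0,
                             a_px = a, b_px = b)
    } else {
      rendered <- data.frame(id = integer(), cohort = integer(),
                             delta_deg = numeric(), row = numeric(),
                             col = numeric(), a_px = numeric(), b_px = numeric())
    }

    ir <- 0.15 * ear_mask
    ir[labels > 0L] <- 0.9
    views[[k]] <- list(angle = psi, ear_mask = ear_mask, labels = labels,
                       rgb = rgb, ir = ir, rendered = rendered)
  }
  if (any_shrunk)
    warning("grain footprints shrunk to preserve the inter-grain gap",
            call. = FALSE)

  arclen <- if (spec$curvature == 0) L else
    stats::integrate(function(zz)
      sqrt(1 + (spec$curvature * pi / L * cos(pi * zz / L))^2),
      0, L, rel.tol = 1e-9)$value

  truth <- list(
    grains = data.frame(id = seq_len(n), cohort = cohort, file = file_i,
                        angle_deg = phi, z_cm = z, set = set),
    ear_length_cm = arclen,
    max_diameter_cm = spec$max_diameter,
    diameter_profile_cm = rev(diam_rows_cm),     # bottom -> top
    n_cohorts = C,
    grains_per_cohort = K,
    n_set = sum(set),
    n_total = n,
    zones_cm = true_zones(spec),
    gsr = pmin(gsr_acc, 1),                      # bottom -> top, per ear row
    pixel_scale = sc)

  structure(list(ear_id = ear_id, spec = spec, plan = plan,
                 pixel_scale = sc, views = views, truth = truth),
            class = "synthetic_ear")
}

#' @export
print.synthetic_ear <- function(x, ...) {
  cat(sprintf("synthetic ear '%s': %d views, %d/%d grains set, %.1f cm\n",
              x$ear_id, length(x$views), x$truth$n_set, x$truth$n_total,
              x$spec$ear_length))
  invisible(x)
}

#' Build a panel of synthetic ear specifications across abortion archetypes
#'
#' Draws a reproducible panel of ears spanning realistic trait ranges (ear
#' length 8-16 cm, diameter 3-5 cm, 18-30 cohorts, 10-16 grains per cohort,
#' grain width 80% of the circumferential pitch, mild centreline bow) and
#' cycles the requested abortion archetypes across ears. With
#' `length_gradient = TRUE`, ear length is instead tied to the archetype
#' (12, 11, 10, 9, 8 cm plus 0.3 cm noise for archetypes 1-5), emulating the
#' shorter ears of more stressed plants.
#'
#' @param n Number of ears.
#' @param archetypes Archetype ids cycled over the panel (see
#'   [archetype_spec()]).
#' @param seed Panel seed; ear i receives seed `1000 * seed + i`.
#' @param length_gradient Tie ear length to archetype severity.
#' @param pixel_scale Raster resolution for all ears, px per cm.
#' @return A list of `n` elements, each with `spec` (a
#'   [synthetic_ear_spec()]) and `archetype` (integer).
#' @export
archetype_panel <- function(n = 50, archetypes = 1:4, seed = 1L,
                            length_gradient = FALSE, pixel_scale = 20) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  arch <- rep_len(archetypes, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    L <- if (length_gradient) 13 - arch[i] + stats::rnorm(1, 0, 0.3)
         else stats::runif(1, 8, 16)
    D <- stats::runif(1, 3, 5)
    C <- sample(18:30, 1)
    K <- sample(10:16, 1)
    base <- synthetic_ear_spec(
      ear_length = L, max_diameter = D,
      diameter_profile_shape = sample(c("cylinder", "tapered", "barrel"), 1),
      n_cohorts = C, grains_per_cohort = K,
      grain_height = 0.9 * L / C, grain_width = 0.8 * pi * D / K,
      pixel_scale = pixel_scale, curvature = stats::runif(1, 0, 0.3),
      seed = 1000L * seed + i)
    out[[i]] <- list(spec = archetype_spec(arch[i], base),
                     archetype = arch[i])
  }
  out
}
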