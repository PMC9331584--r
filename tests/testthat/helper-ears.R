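# Shared fixtures, generated in code and cached for the test session.

.ear_cache <- new.env(parent = emptyenv())

cached_ear <- function(key, spec, plan = acquisition_plan()) {
  if (is.null(.ear_cache[[key]]))
    .ear_cache[[key]] <- suppressWarnings(generate_ear(spec, plan, ear_id = key))
  .ear_cache[[key]]
}

# default lattice ear: 24 cohorts x 14 grains, fully set, mild bow
ear_default <- function() cached_ear("default", synthetic_ear_spec())

# fine-raster jitter-free ear for geometric recovery checks
ear_hires <- function() cached_ear(
  "hires", synthetic_ear_spec(pixel_scale = 40, position_jitter = 0))

# ideal fully-set lattice: 30 cohorts x 16 grains, no jitter
ear_ideal <- function() cached_ear(
  "ideal", synthetic_ear_spec(ear_length = 15, max_diameter = 4,
                              n_cohorts = 30, grains_per_cohort = 16,
                              grain_width = 0.72, position_jitter = 0,
                              curvature = 0.2, seed = 7))

# barren ear (full abortion)
ear_barren <- function() cached_ear(
  "barren", archetype_spec(5, synthetic_ear_spec()))

# per-view analysis bundle
view_analysis <- function(v, pixel_scale) {
  axis <- central_axis(v$ear_mask)
  dp <- diameter_profile(v$ear_mask, pixel_scale)
  grains <- extract_grains(v$labels)
  list(axis = axis, dp = dp, grains = grains, n_cols = ncol(v$ear_mask))
}

# Discretized union-of-arcs oracle: mark visited bins on a 36000-bin circle.
coverage_brute <- function(plan, ear_diameter, bins = 36000) {
  step <- plan$roller_step_angle * plan$roller_diameter / ear_diameter
  seen <- logical(bins)
  for (k in seq_len(plan$n_views) - 1) {
    centre <- (k * step) %% 360
    lo <- centre - plan$view_arc / 2
    hi <- centre + plan$view_arc / 2
    ang <- (seq(lo, hi, length.out = max(2, ceiling((hi - lo) * bins / 360) * 4))) %% 360
    seen[pmin(floor(ang * bins / 360), bins - 1) + 1] <- TRUE
  }
  100 * sum(seen) / bins
}
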