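fake_grains <- function(rows, cols = NULL, width = 16, height = 9) {
  n <- length(rows)
  if (n == 0) return(extract_grains(matrix(0L, 2, 2)))
  if (is.null(cols)) cols <- seq(20, by = 20, length.out = n)
  data.frame(label = seq_len(n), row_c = rows, col_c = cols,
             rmin = as.integer(round(rows - height / 2)),
             rmax = as.integer(round(rows + height / 2)),
             cmin = as.integer(round(cols - width / 2)),
             cmax = as.integer(round(cols + width / 2)),
             height_px = height, width_px = width, area_px = width * height)
}

test_that("cohort assignment applies the half-mean-width window rule", {
  g1 <- assign_cohorts(fake_grains(100))
  expect_equal(g1$cohort, 1L)
  # 3 px apart with window 8 (width 16): one cohort
  g2 <- assign_cohorts(fake_grains(c(100, 97)))
  expect_equal(g2$cohort, c(1L, 1L))
  # 9 px apart with window 8: two cohorts, rank 1 at the bottom
  g3 <- assign_cohorts(fake_grains(c(91, 100)))
  expect_equal(g3$cohort, c(2L, 1L))
  # boundary tie (exactly window px) is inclusive
  g4 <- assign_cohorts(fake_grains(c(100, 92)))
  expect_equal(g4$cohort, c(1L, 1L))
  expect_equal(nrow(assign_cohorts(fake_grains(numeric(0)))), 0)
})

test_that("lattice cohorts recover the generator's ground truth", {
  e <- ear_default()
  for (v in e$views[c(1, 4)]) {
    g <- assign_cohorts(extract_grains(v$labels))
    truth <- e$truth$grains$cohort[match(g$label, e$truth$grains$id)]
    expect_equal(g$cohort, truth)
    # partition: contiguous ranks from 1, each grain exactly one rank
    expect_setequal(unique(g$cohort), seq_len(max(g$cohort)))
  }
})

test_that("crossing profile equals a brute-force per-column count", {
  e <- suppressWarnings(generate_ear(
    synthetic_ear_spec(abortion_model = "scattered",
                       abortion_params = list(set_prob = 0.5), seed = 13)))
  v <- e$views[[2]]
  g <- extract_grains(v$labels)
  ccp <- cohort_count_profile(g, ncol(v$ear_mask))
  brute <- vapply(seq_len(ncol(v$ear_mask)), function(col)
    sum(g$cmin <= col & g$cmax >= col), integer(1))
  expect_equal(ccp$counts, brute)
  expect_equal(ccp$max, max(brute))
  expect_equal(cohort_count_profile(g[0, ], 50)$max, 0L)
})

test_that("fully set ears report the exact cohort count across random seeds", {
  for (s in 1:20) {
    sp <- synthetic_ear_spec(ear_length = 8, max_diameter = 3.5,
                             n_cohorts = 16, grains_per_cohort = 12,
                             grain_height = 0.45, grain_width = 0.7,
                             curvature = 0.15, seed = 100 + s)
    e <- suppressWarnings(generate_ear(sp))
    for (v in e$views[c(1, 4)]) {
      g <- extract_grains(v$labels)
      expect_equal(cohort_count_profile(g, ncol(v$ear_mask))$max, 16L)
    }
  }
})

test_that("perimeter-to-gap ratio estimates grains per cohort", {
  e <- cached_ear("gpc14", synthetic_ear_spec(position_jitter = 0))
  sc <- e$pixel_scale
  v <- e$views[[1]]
  va <- view_analysis(v, sc)
  gpc <- grains_per_cohort_profile(va$grains, va$axis, va$dp, sc)
  nz <- earmetrics:::zone_thirds(nrow(gpc))
  med <- gpc$estimate[nz == 2]
  expect_true(all(abs(med[!is.na(med)] - 14) <= 1))
  # rows with fewer than two crossings are undefined
  expect_true(all(is.na(gpc$estimate[gpc$n_cross < 2])))
  expect_true(all(gpc$n_cross[is.na(gpc$estimate)] < 2 |
                    is.na(gpc$dist_cm[is.na(gpc$estimate)])))
})

test_that("grains-per-cohort estimates are pixel-scale invariant", {
  med_est <- function(sc) {
    e <- cached_ear(paste0("scale", sc),
                    synthetic_ear_spec(pixel_scale = sc, position_jitter = 0))
    v <- e$views[[1]]
    va <- view_analysis(v, sc)
    gpc <- grains_per_cohort_profile(va$grains, va$axis, va$dp, sc)
    nz <- earmetrics:::zone_thirds(nrow(gpc))
    mean(gpc$estimate[nz == 2], na.rm = TRUE)
  }
  expect_equal(med_est(20), med_est(40), tolerance = 0.02)
})

test_that("composite estimator recovers grain number on an ideal lattice", {
  e <- ear_ideal()   # 480 grains
  sc <- e$pixel_scale
  ests <- lapply(e$views, function(v) {
    va <- view_analysis(v, sc)
    grain_number_view(va$grains, va$axis, va$dp, sc, va$n_cols)
  })
  gn <- grain_number_per_ear(ests)
  expect_equal(gn, 480, tolerance = 0.05)
  expect_true(all(vapply(ests, `[[`, numeric(1), "n_cohorts") == 30))
})

test_that("barren ears count zero grains", {
  e <- ear_barren()
  sc <- e$pixel_scale
  ests <- lapply(e$views, function(v) {
    va <- view_analysis(v, sc)
    grain_number_view(va$grains, va$axis, va$dp, sc, va$n_cols)
  })
  expect_equal(grain_number_per_ear(ests), 0)
  expect_equal(grain_number_per_ear(list()), 0)
})

test_that("apically aborted ears are estimated within ten percent", {
  sp <- archetype_spec(2, synthetic_ear_spec(seed = 11))
  e <- suppressWarnings(generate_ear(sp))
  sc <- e$pixel_scale
  ests <- lapply(e$views, function(v) {
    va <- view_analysis(v, sc)
    grain_number_view(va$grains, va$axis, va$dp, sc, va$n_cols)
  })
  expect_equal(grain_number_per_ear(ests) / e$truth$n_set, 1, tolerance = 0.1)
})

test_that("the limb-discounted under-estimator never exceeds the over-estimator", {
  for (s in 11:13) {
    sp <- archetype_spec(2, synthetic_ear_spec(seed = s))
    e <- suppressWarnings(generate_ear(sp))
    sc <- e$pixel_scale
    for (v in e$views) {
      va <- view_analysis(v, sc)
      gn <- grain_number_view(va$grains, va$axis, va$dp, sc, va$n_cols,
                              under_strategy = "zonal_mean")
      expect_lte(gn$under, gn$over + 1e-9)
    }
  }
})
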