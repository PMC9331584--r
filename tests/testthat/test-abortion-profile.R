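toy_profiles <- function(ratios) {
  # build a gsr_profile object directly (rows bottom to top)
  out <- data.frame(row = rev(seq_along(ratios)), ratio = ratios)
  class(out) <- c("gsr_profile", "data.frame")
  out
}

test_that("row ratios are grain pixels over silhouette diameter", {
  ear <- matrix(0L, 10, 12); ear[3:8, 3:10] <- 1L
  lab <- matrix(0L, 10, 12)
  lab[3, 3:10] <- 1L          # fully covered row
  lab[4, 3:6] <- 2L           # half covered
  p <- gsr_profile(ear, lab)
  expect_equal(p$ratio[p$row == 3], 1)
  expect_equal(p$ratio[p$row == 4], 0.5)
  expect_equal(p$ratio[p$row == 8], 0)   # bare cob row
  expect_true(all(p$ratio >= 0 & p$ratio <= 1))
  # grain outside the silhouette signals a registration fault
  lab2 <- lab; lab2[1, 1] <- 9L
  expect_warning(gsr_profile(ear, lab2), "registration")
  expect_error(gsr_profile(ear, matrix(0L, 3, 3)), "dimensions")
})

test_that("smoothing is a truncated centred running mean", {
  p <- smooth_gsr(toy_profiles(rep(0.8, 50)), fraction = 0.1)
  expect_equal(p$smoothed, rep(0.8, 50))
  # window of one row is the identity
  p1 <- smooth_gsr(toy_profiles(runif(40)), fraction = 0.02)
  expect_equal(attr(p1, "smoothing_window"), 1L)
  expect_equal(p1$smoothed, p1$ratio)
  # direct convolution oracle on a unit impulse, truncated at the ends
  x <- c(1, rep(0, 99))
  p2 <- smooth_gsr(toy_profiles(x), fraction = 0.05)   # window 5, half 2
  oracle <- vapply(seq_along(x), function(i) {
    lo <- max(i - 2, 1); hi <- min(i + 2, 100)
    mean(x[lo:hi])
  }, numeric(1))
  expect_equal(p2$smoothed, oracle)
  # smoothing stays inside the raw range
  raw <- runif(200)
  p3 <- smooth_gsr(toy_profiles(raw), fraction = 0.04)
  expect_gte(min(p3$smoothed), min(raw))
  expect_lte(max(p3$smoothed), max(raw))
  expect_error(smooth_gsr(toy_profiles(raw), fraction = 0.7), "fraction")
})

test_that("zone segmentation applies the envelope and degenerate rules", {
  low <- smooth_gsr(toy_profiles(rep(0.3, 80)), fraction = 0.02)
  z <- segment_zones(low, ear_length_cm = 10)
  expect_equal(z$fertile_cm, 0)
  expect_equal(z$basal_cm, 5)
  expect_equal(z$apical_cm, 5)
  expect_null(z$fertile_rows)
  high <- smooth_gsr(toy_profiles(rep(0.9, 80)), fraction = 0.02)
  z2 <- segment_zones(high, 10)
  expect_equal(z2$fertile_cm, 10)
  expect_equal(z2$basal_cm + z2$apical_cm, 0)
  # interior dips stay inside the fertile envelope
  mixed <- smooth_gsr(toy_profiles(c(rep(0.1, 20), rep(0.9, 20),
                                     rep(0.2, 10), rep(0.9, 20),
                                     rep(0.1, 10))), fraction = 0.02)
  z3 <- segment_zones(mixed, 8)
  expect_equal(z3$fertile_cm, 8 * 50 / 80)
  # threshold comparison is strict
  att <- smooth_gsr(toy_profiles(rep(0.5, 10)), fraction = 0.1)
  expect_equal(segment_zones(att, 5, threshold = 0.5)$fertile_cm, 0)
})

test_that("zone lengths always partition the ear length", {
  set.seed(6)
  for (i in 1:20) {
    p <- smooth_gsr(toy_profiles(runif(60)), fraction = 0.05)
    z <- segment_zones(p, 12)
    expect_equal(z$fertile_cm + z$basal_cm + z$apical_cm, 12)
  }
})

test_that("raising the threshold never lengthens the fertile zone", {
  e <- suppressWarnings(generate_ear(archetype_spec(3, synthetic_ear_spec(seed = 2))))
  v <- e$views[[1]]
  prof <- smooth_gsr(gsr_profile(v$ear_mask, v$labels))
  len <- ear_length(central_axis(v$ear_mask), e$pixel_scale)
  fl <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    segment_zones(prof, len, threshold = th)$fertile_cm, numeric(1))
  expect_true(all(diff(fl) <= 1e-9))
})

test_that("a sharp apical abortion edge is located within two percent", {
  sp <- synthetic_ear_spec(abortion_model = "apical",
                           abortion_params = list(apical_fraction = 0.3,
                                                  edge_cohorts = 0.2),
                           seed = 1)
  e <- suppressWarnings(generate_ear(sp))
  fz <- vapply(e$views, function(v) {
    prof <- smooth_gsr(gsr_profile(v$ear_mask, v$labels))
    segment_zones(prof, ear_length(central_axis(v$ear_mask), 20))$fertile_cm
  }, numeric(1))
  expect_equal(mean(fz) / (0.7 * 12), 1, tolerance = 0.02)
})

test_that("the soft developmental edge is located within half its width", {
  # the default two-cohort logistic transition (1 cm here) shifts the strict
  # 50% crossing basally; recovery is asserted at half the transition width
  sp <- archetype_spec(2, synthetic_ear_spec(seed = 1))
  e <- suppressWarnings(generate_ear(sp))
  fz <- vapply(e$views, function(v) {
    prof <- smooth_gsr(gsr_profile(v$ear_mask, v$labels))
    segment_zones(prof, ear_length(central_axis(v$ear_mask), 20))$fertile_cm
  }, numeric(1))
  expect_lt(abs(mean(fz) - 0.7 * 12), 0.5)
})
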