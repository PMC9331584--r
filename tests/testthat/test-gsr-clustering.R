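smoothed_profile <- function(values) {
  p <- data.frame(row = rev(seq_along(values)), ratio = values)
  class(p) <- c("gsr_profile", "data.frame")
  smooth_gsr(p, fraction = 1e-6)   # window 1: smoothed == raw
}

# analytic archetype-like step profiles on [0, 1]
step_profile <- function(fertile_from, fertile_to, n = 100) {
  x <- seq(0, 1, length.out = n)
  ifelse(x >= fertile_from & x <= fertile_to, 0.85, 0.05)
}

test_that("profile normalization interpolates onto the unit grid", {
  expect_equal(normalize_profile(smoothed_profile(rep(0.8, 37))),
               rep(0.8, 100))
  ramp <- normalize_profile(smoothed_profile(seq(0, 1, length.out = 500)))
  expect_equal(ramp, seq(0, 1, length.out = 100), tolerance = 1e-6)
  # down-sampling a long smooth profile and re-interpolating is near-lossless
  z <- seq(0, 1, length.out = 1000)
  smoothv <- 0.5 + 0.4 * sin(2 * pi * z)
  down <- normalize_profile(smoothed_profile(smoothv))
  back <- stats::approx(seq(0, 1, length.out = 100), down, xout = z)$y
  expect_lt(sqrt(mean((back - smoothv)^2)), 0.01)
  # single-row profile gives a constant vector
  expect_equal(normalize_profile(smoothed_profile(0.4)), rep(0.4, 100))
})

test_that("side averaging is the pointwise mean", {
  p <- step_profile(0, 0.7)
  expect_equal(average_sides(list(p, p, p)), p)
  expect_equal(average_sides(list(p)), p)
  q <- step_profile(0.1, 0.9)
  expect_equal(average_sides(list(p, q)), (p + q) / 2)
  expect_error(average_sides(list(p, q[1:50])), "same grid")
})

test_that("well-separated duplicated archetypes split perfectly at k = 2", {
  a <- step_profile(0, 0.95)
  b <- step_profile(0.3, 0.5)
  mat <- rbind(a, a, a, b, b, b)
  rownames(mat) <- paste0("e", 1:6)
  res <- cluster_profiles(mat, k = 2)
  expect_equal(unname(res$labels), c(1, 1, 1, 2, 2, 2))
  expect_equal(res$means[1, ], a)        # zero within-cluster spread
  expect_equal(unname(res$sds[1, ]), rep(0, 100))
})

test_that("cluster means equal member means and integrals order labels", {
  set.seed(5)
  mat <- rbind(t(replicate(6, step_profile(0, 0.9) + rnorm(100, 0, 0.03))),
               t(replicate(6, step_profile(0, 0.5) + rnorm(100, 0, 0.03))),
               t(replicate(6, step_profile(0.2, 0.35) + rnorm(100, 0, 0.03))))
  rownames(mat) <- paste0("e", 1:18)
  res <- cluster_profiles(mat, k = 3)
  for (cl in 1:3)
    expect_equal(res$means[cl, ],
                 colMeans(mat[res$labels == cl, , drop = FALSE]))
  expect_true(all(diff(rowMeans(res$means)) < 0))   # 1 least aborted
  # invariant to ear input order
  perm <- sample(nrow(mat))
  res2 <- cluster_profiles(mat[perm, ], k = 3)
  expect_equal(res2$labels[rownames(mat)], res$labels[rownames(mat)])
  # k-means backend agrees on this well-separated panel
  res3 <- cluster_profiles(mat, k = 3, method = "kmeans", seed = 2)
  expect_equal(unname(res3$labels), unname(res$labels))
  expect_error(cluster_profiles(mat, k = 50), "at least k")
})

test_that("with vanishing noise the planted labels are fully recovered", {
  planted <- rep(1:3, each = 5)
  arch <- list(step_profile(0, 0.9), step_profile(0, 0.55),
               step_profile(0.25, 0.4))
  set.seed(9)
  mat <- do.call(rbind, lapply(planted, function(a)
    arch[[a]] + rnorm(100, 0, 1e-4)))
  rownames(mat) <- paste0("e", seq_along(planted))
  res <- cluster_profiles(mat, k = 3)
  expect_equal(unname(res$labels), planted)
})

test_that("summaries report treatment shares and ear-length ANOVA", {
  set.seed(4)
  planted <- rep(1:3, each = 8)
  arch <- list(step_profile(0, 0.9), step_profile(0, 0.55),
               step_profile(0.25, 0.4))
  mat <- do.call(rbind, lapply(planted, function(a)
    arch[[a]] + rnorm(100, 0, 0.02)))
  rownames(mat) <- paste0("e", seq_along(planted))
  res <- cluster_profiles(mat, k = 3)
  lens <- c(12, 10, 8)[planted] + rnorm(24, 0, 0.3)
  treat <- rep(c("WW", "WD"), 12)
  s <- cluster_summaries(res, treatments = treat, ear_lengths = lens)
  expect_true(all(diff(s$length_mean) < 0))
  expect_lt(s$anova$p, 0.001)
  expect_equal(unname(colSums(s$treatment_proportions)), c(1, 1))
  # single populated cluster: ANOVA undefined
  one <- cluster_profiles(mat[planted == 1, ], k = 1)
  s1 <- cluster_summaries(one, ear_lengths = lens[planted == 1])
  expect_true(is.na(s1$anova$p))
})
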