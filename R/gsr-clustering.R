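#' Length-normalized grain-set-ratio profile
#'
#' Interpolates a smoothed profile onto `n_points` equally spaced relative
#' positions on `[0, 1]` (0 = ear base, 1 = apex) so ears of different length
#' become comparable.
#'
#' @param profile A smoothed [gsr_profile()].
#' @param n_points Grid size. Default 100.
#' @return Numeric vector of length `n_points`.
#' @export
normalize_profile <- function(profile, n_points = 100) {
  stopifnot(inherits(profile, "gsr_profile"))
  if (is.null(profile$smoothed))
    stop("profile must be smoothed first (see smooth_gsr)")
  n <- nrow(profile)
  grid <- seq(0, 1, length.out = n_points)
  if (n == 0) return(rep(NA_real_, n_points))
  if (n == 1) return(rep(profile$smoothed, n_points))
  stats::approx(seq(0, 1, length.out = n), profile$smoothed, xout = grid,
                rule = 2)$y
}

#' Average normalized profiles over the views of one ear
#'
#' @param view_profiles List of equal-length numeric vectors (one per view).
#' @return Their pointwise mean.
#' @export
average_sides <- function(view_profiles) {
  stopifnot(length(view_profiles) >= 1)
  lens <- vapply(view_profiles, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("view profiles must share the same grid")
  colMeans(do.call(rbind, view_profiles))
}

#' Cluster ears by their normalized abortion profiles
#'
#' Ward agglomeration on the Euclidean distance matrix of the profiles, cut
#' into `k` clusters (k-means on the same matrix is available as an
#' alternative backend with a fixed seed). Clusters are relabelled 1..k by
#' decreasing mean profile integral, so cluster 1 is always the least aborted
#' and cluster k the most, regardless of backend label arbitrariness.
#'
#' @param mat Numeric matrix, one ear per row, profiles on a common grid with
#'   no missing values; row names identify ears.
#' @param k Number of clusters. Default 5.
#' @param method `"ward"` (hierarchical, ward.D2 on Euclidean distances) or
#'   `"kmeans"`.
#' @param seed Seed for the k-means backend.
#' @return A list of class `gsr_clusters` with `labels` (1..k per ear),
#'   `tree` (hclust object or NULL), `means` and `sds` (per-cluster profile
#'   statistics, k x ncol(mat)), `sizes`, `method`, `k`.
#' @export
cluster_profiles <- function(mat, k = 5, method = c("ward", "kmeans"),
                             seed = 1L) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("profile matrix must not contain missing values")
  if (nrow(mat) < k) stop("need at least k ears to form k clusters")
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  tree <- NULL
  if (method == "ward") {
    tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                          method = "ward.D2")
    raw <- stats::cutree(tree, k = k)
  } else {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    raw <- stats::kmeans(mat, centers = k, nstart = 25, iter.max = 100)$cluster
  }
  integral <- tapply(rowMeans(mat), raw, mean)
  relabel <- integer(k)
  relabel[order(integral, decreasing = TRUE)] <- seq_len(k)
  labels <- relabel[raw]
  names(labels) <- rownames(mat)
  means <- matrix(NA_real_, k, ncol(mat))
  sds <- matrix(NA_real_, k, ncol(mat))
  for (cl in seq_len(k)) {
    sub <- mat[labels == cl, , drop = FALSE]
    means[cl, ] <- colMeans(sub)
    sds[cl, ] <- apply(sub, 2, stats::sd)
  }
  structure(list(labels = labels, tree = tree, means = means, sds = sds,
                 sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
                 method = method, k = k),
            class = "gsr_clusters")
}

#' Per-cluster summaries and ear-length ANOVA
#'
#' Treatment composition per cluster (proportions normalized within each
#' treatment group, so each treatment's shares across clusters sum to 1),
#' mean and standard deviation of ear length per cluster, and a one-way ANOVA
#' of ear length across clusters.
#'
#' @param result A [cluster_profiles()] result.
#' @param treatments Optional factor/character vector of treatment labels
#'   aligned with the clustered ears.
#' @param ear_lengths Optional numeric vector of ear lengths (cm), aligned.
#' @return A list of class `cluster_summary` with `treatment_proportions`
#'   (clusters x treatments, or NULL), `length_mean`, `length_sd`, `n`, and
#'   `anova` (list with `F`, `p`, `df`; NA when fewer than two clusters are
#'   populated).
#' @export
cluster_summaries <- function(result, treatments = NULL, ear_lengths = NULL) {
  stopifnot(inherits(result, "gsr_clusters"))
  labels <- factor(result$labels, levels = seq_len(result$k))
  tp <- NULL
  if (!is.null(treatments)) {
    tab <- table(cluster = labels, treatment = treatments)
    tp <- sweep(tab, 2, pmax(colSums(tab), 1), "/")
  }
  lm_ <- ls_ <- rep(NA_real_, result$k)
  nn <- as.integer(table(labels))
  an <- list(F = NA_real_, p = NA_real_, df = c(NA_real_, NA_real_))
  if (!is.null(ear_lengths)) {
    ok <- !is.na(ear_lengths)
    lm_ <- as.numeric(tapply(ear_lengths[ok], labels[ok], mean))
    ls_ <- as.numeric(tapply(ear_lengths[ok], labels[ok], stats::sd))
    if (nlevels(droplevels(labels[ok])) >= 2) {
      fit <- stats::aov(ear_lengths[ok] ~ droplevels(labels[ok]))
      s <- summary(fit)[[1]]
      an <- list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                 df = s[["Df"]])
    }
  }
  structure(list(treatment_proportions = tp, length_mean = lm_,
                 length_sd = ls_, n = nn, anova = an),
            class = "cluster_summary")
}
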