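#' Raw grain-set-ratio profile
#'
#' For every one-pixel ear section, the ratio of grain pixels to ear diameter
#' pixels (outermost extent), a proxy for the fraction of set versus aborted
#' ovaries at that height. Grain pixels found outside the ear silhouette are
#' still counted but raise a warning, as they signal a registration fault
#' between the two masks.
#'
#' @param ear_mask Binary ear silhouette matrix (non-zero = ear).
#' @param grain_label_mask Integer instance raster co-registered with
#'   `ear_mask`.
#' @return A data frame of class `gsr_profile` with columns `row` (raster row
#'   index, bottom to top), `ratio` in `[0, 1]`, and attribute
#'   `smoothing_window` (NULL until smoothed).
#' @export
gsr_profile <- function(ear_mask, grain_label_mask) {
  if (!all(dim(ear_mask) == dim(grain_label_mask)))
    stop("masks must share dimensions")
  if (any(grain_label_mask > 0 & ear_mask == 0))
    warning("grain pixels outside the ear mask; check mask registration",
            call. = FALSE)
  fg <- which(ear_mask != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    out <- data.frame(row = integer(), ratio = numeric())
  } else {
    lefts <- tapply(fg[, 2], fg[, 1], min)
    rights <- tapply(fg[, 2], fg[, 1], max)
    rows <- as.integer(names(lefts))
    diam <- as.numeric(rights - lefts + 1)
    gcounts <- rowSums(grain_label_mask > 0)[rows]
    ord <- order(rows, decreasing = TRUE)      # bottom -> top
    out <- data.frame(row = rows[ord],
                      ratio = pmin(gcounts[ord] / diam[ord], 1))
  }
  class(out) <- c("gsr_profile", "data.frame")
  out
}

#' Smooth a grain-set-ratio profile
#'
#' Centred running mean over a window of `fraction` of the total vertical
#' (ear) pixels, truncated (not reflected) at the profile ends so no data are
#' invented beyond the ear.
#'
#' @param profile A [gsr_profile()].
#' @param fraction Window size as a fraction of the ear rows, in (0, 0.5].
#'   Default 0.02.
#' @return The profile with an added `smoothed` column and attribute
#'   `smoothing_window` (rows).
#' @export
smooth_gsr <- function(profile, fraction = 0.02) {
  stopifnot(inherits(profile, "gsr_profile"),
            fraction > 0, fraction <= 0.5)
  n <- nrow(profile)
  w <- max(1L, as.integer(round(fraction * n)))
  half <- w %/% 2
  x <- profile$ratio
  if (n == 0) {
    profile$smoothed <- numeric()
  } else {
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    profile$smoothed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  attr(profile, "smoothing_window") <- w
  profile
}

#' Fertile and aborted zone segmentation
#'
#' The fertile zone is the envelope from the first to the last ear row whose
#' smoothed grain-set ratio strictly exceeds the threshold; interior dips
#' remain inside it. The basal aborted zone lies below, the apical aborted
#' zone above, and the three lengths partition the ear length. When no row
#' exceeds the threshold, the fertile length is 0 and the basal and apical
#' aborted zones each take half the total ear length.
#'
#' @param profile A smoothed [gsr_profile()] (see [smooth_gsr()]).
#' @param ear_length_cm Ear length in cm used to express zone lengths.
#' @param threshold Grain-set-ratio threshold; comparison is strict. Default
#'   0.5.
#' @return A list of class `zone_summary` with `fertile_cm`, `basal_cm`,
#'   `apical_cm` and `fertile_rows` (raster row bounds, NULL when barren).
#' @export
segment_zones <- function(profile, ear_length_cm, threshold = 0.5) {
  stopifnot(inherits(profile, "gsr_profile"), ear_length_cm >= 0)
  if (is.null(profile$smoothed))
    stop("profile must be smoothed first (see smooth_gsr)")
  n <- nrow(profile)
  above <- which(profile$smoothed > threshold)
  if (n == 0 || length(above) == 0) {
    out <- list(fertile_cm = 0, basal_cm = ear_length_cm / 2,
                apical_cm = ear_length_cm / 2, fertile_rows = NULL)
  } else {
    first <- min(above)                       # bottom-most crossing
    last <- max(above)
    n_fert <- last - first + 1L
    n_bas <- first - 1L
    n_api <- n - last
    out <- list(fertile_cm = ear_length_cm * n_fert / n,
                basal_cm = ear_length_cm * n_bas / n,
                apical_cm = ear_length_cm * n_api / n,
                fertile_rows = c(profile$row[first], profile$row[last]))
  }
  structure(out, class = "zone_summary")
}
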