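#' Baseline grain segmentation from pseudo-RGB and IR renders
#'
#' A deliberately simple watershed baseline so the pipeline can run end to end
#' from photographic-style channels: the RGB luminance and the IR channel are
#' merged (IR-weighted, since grains are bright and cob dark at 940 nm),
#' thresholded inside the ear silhouette, and touching grains are separated by
#' a watershed on the distance transform. Downstream modules accept label
#' masks from any source, so a stronger instance segmenter can be swapped in.
#'
#' @param rgb H x W x 3 array in `[0, 1]` (or NULL to use `ir` alone).
#' @param ir H x W matrix in `[0, 1]`.
#' @param ear_mask Binary ear silhouette matrix.
#' @param ir_weight Weight of the IR channel in the merge. Default 0.6.
#' @param threshold Optional fixed intensity threshold; by default Otsu's
#'   threshold computed inside the ear mask, floored at `threshold_floor`.
#' @param threshold_floor Lower bound on the automatic threshold, keeping
#'   barren ears (cob only, no bright pixels) label-free. Default 0.4.
#' @param tolerance Watershed merge tolerance (distance-map units). Default 1.
#' @return Integer label matrix, labels 1..n restricted to the ear mask;
#'   all zeros when the ear mask or the thresholded foreground is empty.
#' @export
segment_grains <- function(rgb, ir, ear_mask, ir_weight = 0.6,
                           threshold = NULL, threshold_floor = 0.4,
                           tolerance = 1) {
  stopifnot(all(dim(ir) == dim(ear_mask)))
  if (ir_weight < 0 || ir_weight > 1) stop("'ir_weight' must be in [0, 1]")
  lum <- if (is.null(rgb)) ir else (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  merged <- ir_weight * ir + (1 - ir_weight) * lum
  inside <- ear_mask != 0
  if (!any(inside)) return(matrix(0L, nrow(ir), ncol(ir)))
  if (is.null(threshold)) {
    vals <- merged[inside]
    threshold <- tryCatch(
      max(EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)), range = c(0, 1)),
          threshold_floor),
      error = function(e) threshold_floor)
  }
  binary <- merged > threshold & inside
  if (!any(binary)) return(matrix(0L, nrow(ir), ncol(ir)))
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(ir), ncol(ir))
  lab[!inside] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[] <- match(lab, ids, nomatch = 0L)
  lab
}
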