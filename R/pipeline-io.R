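#' Read and write label and silhouette rasters
#'
#' Label masks round-trip losslessly: TIFF files are written with 16 bits per
#' sample (labels up to 65535); PNG output is 8-bit, so writing more than 255
#' labels to PNG is rejected as a format-limit error (16-bit PNGs produced
#' elsewhere are read correctly).
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_label_mask`: an integer matrix (row 1 = image top).
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported raster format '", ext, "' for ", path))
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (anyNA(img)) stop("raster '", path, "' contains missing values")
  bits <- attr(img, "bits.per.sample")
  scale <- if (!is.null(bits)) 2^bits - 1 else
    if (max(img) <= 1 && ext == "png") 65535 else 65535
  # png::readPNG always rescales to [0,1]; infer depth from the value grid
  if (ext == "png") {
    v <- img * 255
    scale <- if (max(abs(v - round(v))) < 1e-9) 255 else 65535
  }
  matrix(as.integer(round(img * scale)), nrow(img), ncol(img))
}

#' @rdname read_label_mask
#' @param mask Non-negative integer matrix, background 0.
#' @export
write_label_mask <- function(mask, path) {
  if (any(mask < 0) || any(mask != round(mask)))
    stop("label mask must contain non-negative integers")
  ext <- tolower(tools::file_ext(path))
  mx <- max(mask, 0)
  if (ext == "png") {
    if (mx > 255)
      stop("PNG output is 8-bit: ", mx,
           " labels exceed 255; write a 16-bit TIFF instead")
    png::writePNG(mask / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (mx > 65535) stop("more than 65535 labels cannot be stored in 16 bits")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "deflate")
  } else stop("unsupported raster format '", ext, "'")
  invisible(path)
}

#' Run configuration for the traits pipeline
#'
#' @param input_dir Directory holding one sub-directory per ear with view
#'   rasters (`view_<k>_ear.*`, `view_<k>_labels.*`).
#' @param output_dir Directory for traits, profile and log outputs.
#' @param pixel_scale Raster resolution, px per cm (never encoded in the
#'   rasters themselves, so it is a required calibration input).
#' @param smoothing_fraction Grain-set-ratio smoothing window as a fraction
#'   of ear rows. Default 0.02.
#' @param gsr_threshold Fertile-zone threshold on the smoothed grain-set
#'   ratio. Default 0.5.
#' @param cohort_window_factor Cohort grouping window as a fraction of mean
#'   grain width. Default 0.5.
#' @param under_strategy Under-estimator variant, see [grain_number_view()].
#' @param n_norm_points Grid size for length-normalized profiles. Default 100.
#' @param cluster_k,cluster_method Clustering backend settings.
#' @param seed Seed forwarded to seeded backends.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, output_dir = NULL, pixel_scale = 20,
                       smoothing_fraction = 0.02, gsr_threshold = 0.5,
                       cohort_window_factor = 0.5,
                       under_strategy = "zonal_max", n_norm_points = 100,
                       cluster_k = 5, cluster_method = "ward", seed = 1L) {
  stopifnot(pixel_scale > 0, smoothing_fraction > 0, smoothing_fraction <= 0.5,
            gsr_threshold >= 0, gsr_threshold <= 1, cohort_window_factor > 0)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 pixel_scale = pixel_scale,
                 smoothing_fraction = smoothing_fraction,
                 gsr_threshold = gsr_threshold,
                 cohort_window_factor = cohort_window_factor,
                 under_strategy = under_strategy,
                 n_norm_points = n_norm_points, cluster_k = cluster_k,
                 cluster_method = cluster_method, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config()` fields.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Analyse the views of a single ear in memory
#'
#' Runs the per-view chain (central axis, diameter profile, grain extraction,
#' cohort assignment, grain dimensions, grains-per-cohort and cohort-count
#' profiles, composite grain number, grain-set-ratio smoothing, zone
#' segmentation, profile normalization) and aggregates to ear scale: traits
#' are means over views, and the cohort count is the mean of the per-view
#' maxima.
#'
#' @param views List of views; each a list with `ear_mask` and `labels`
#'   matrices (co-registered).
#' @param config A [run_config()].
#' @param ear_id Identifier for the traits row.
#' @return A list with `traits` (one-row data frame), `per_view` details and
#'   `norm_profile` (side-averaged length-normalized grain-set ratio).
#' @export
process_ear_views <- function(views, config = run_config(), ear_id = "ear") {
  stopifnot(length(views) >= 1)
  sc <- config$pixel_scale
  dims <- vapply(views, function(v) dim(v$ear_mask), integer(2))
  if (any(dims != dims[, 1]))
    stop("mismatched raster sizes across the views of ear '", ear_id, "'")
  pv <- vector("list", length(views))
  for (k in seq_along(views)) {
    v <- views[[k]]
    axis <- central_axis(v$ear_mask)
    if (length(axis$rows) == 0)
      stop("empty ear mask in view ", k, " of ear '", ear_id, "'")
    dp <- diameter_profile(v$ear_mask, sc)
    len <- ear_length(axis, sc)
    grains <- assign_cohorts(extract_grains(v$labels),
                             window_factor = config$cohort_window_factor)
    grains <- grain_dimensions(grains, axis, dp, sc)
    gn <- grain_number_view(grains, axis, dp, sc, ncol(v$ear_mask),
                            under_strategy = config$under_strategy)
    prof <- smooth_gsr(gsr_profile(v$ear_mask, v$labels),
                       fraction = config$smoothing_fraction)
    zones <- segment_zones(prof, len, threshold = config$gsr_threshold)
    nz <- zone_thirds(nrow(gn$gpc))
    gpc_zone <- vapply(1:3, function(z) {
      vals <- gn$gpc$estimate[nz == z]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, numeric(1))
    pv[[k]] <- list(length_cm = len,
                    max_diameter_cm = max(dp$diameter_cm),
                    n_cohorts = gn$n_cohorts,
                    over = gn$over, under = gn$under, estimate = gn$estimate,
                    zones = zones, gpc_zone = gpc_zone, grains = grains,
                    profile = prof,
                    norm_profile = normalize_profile(prof,
                                                     config$n_norm_points))
  }
  mv <- function(f) mean(vapply(pv, f, numeric(1)))
  mz <- function(z) {
    vals <- vapply(pv, function(x) x$gpc_zone[z], numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  traits <- data.frame(
    ear_id = ear_id,
    ear_length_cm = mv(function(x) x$length_cm),
    max_diameter_cm = mv(function(x) x$max_diameter_cm),
    n_cohorts = mv(function(x) x$n_cohorts),
    gpc_basal = mz(1), gpc_median = mz(2), gpc_apical = mz(3),
    grain_number = mv(function(x) x$estimate),
    fertile_cm = mv(function(x) x$zones$fertile_cm),
    basal_aborted_cm = mv(function(x) x$zones$basal_cm),
    apical_aborted_cm = mv(function(x) x$zones$apical_cm),
    n_views = length(views))
  list(traits = traits, per_view = pv,
       norm_profile = average_sides(lapply(pv, function(x) x$norm_profile)))
}

# Deterministic (C-locale) sorted listing.
sort_c <- function(x) sort(x, method = "radix")

#' Write a generated ear to a view-raster directory
#'
#' Creates `<dir>/<ear_id>/` with per-view ear and label rasters (16-bit TIFF)
#' plus pseudo-RGB and IR renders (PNG), and the ground truth as JSON and a
#' per-grain CSV.
#'
#' @param ear A [generate_ear()] result.
#' @param dir Output root.
#' @return The ear directory, invisibly.
#' @export
write_ear_dataset <- function(ear, dir) {
  stopifnot(inherits(ear, "synthetic_ear"))
  ed <- file.path(dir, ear$ear_id)
  dir.create(ed, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ear$views)) {
    v <- ear$views[[k]]
    write_label_mask(v$ear_mask, file.path(ed, sprintf("view_%d_ear.tif", k)))
    write_label_mask(v$labels, file.path(ed, sprintf("view_%d_labels.tif", k)))
    png::writePNG(v$rgb, file.path(ed, sprintf("view_%d_rgb.png", k)))
    png::writePNG(v$ir, file.path(ed, sprintf("view_%d_ir.png", k)))
  }
  tr <- ear$truth
  jsonlite::write_json(
    list(ear_id = ear$ear_id, pixel_scale = tr$pixel_scale,
         ear_length_cm = tr$ear_length_cm, n_cohorts = tr$n_cohorts,
         grains_per_cohort = tr$grains_per_cohort, n_set = tr$n_set,
         n_total = tr$n_total, zones_cm = as.list(tr$zones_cm),
         gsr = tr$gsr),
    file.path(ed, "truth.json"), auto_unbox = TRUE, digits = 10)
  utils::write.csv(tr$grains, file.path(ed, "truth_grains.csv"),
                   row.names = FALSE)
  invisible(ed)
}

#' Run the traits pipeline over a directory of per-ear view rasters
#'
#' For every ear sub-directory of `config$input_dir`, reads the co-registered
#' ear and label rasters, runs [process_ear_views()], and writes
#' `traits.csv`, per-ear normalized profiles (`profiles.csv`, ears in rows)
#' and a deterministic run log echoing the configuration. Ears with missing
#' or unreadable views are skipped with a logged reason; outputs are
#' byte-identical across reruns with the same inputs and configuration.
#'
#' @param config A [run_config()] with `input_dir` and `output_dir` set.
#' @return The traits data frame, invisibly.
#' @export
run_traits <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$input_dir) || is.null(config$output_dir))
    stop("config must set 'input_dir' and 'output_dir'")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ears <- sort_c(list.dirs(config$input_dir, recursive = FALSE,
                           full.names = FALSE))
  log_lines <- c("run_traits", paste0("config: ", config_echo(config)),
                 paste0("ears_found: ", length(ears)))
  rows <- list()
  profiles <- list()
  for (eid in ears) {
    ed <- file.path(config$input_dir, eid)
    masks <- sort_c(list.files(ed, pattern = "^view_[0-9]+_ear\\."))
    views <- list()
    ok <- TRUE
    for (m in masks) {
      lab_f <- sub("_ear\\.", "_labels.", m)
      if (!file.exists(file.path(ed, lab_f))) {
        log_lines <- c(log_lines,
                       paste0("skip ", eid, ": missing ", lab_f))
        ok <- FALSE
        break
      }
      views[[length(views) + 1L]] <-
        list(ear_mask = read_label_mask(file.path(ed, m)),
             labels = read_label_mask(file.path(ed, lab_f)))
    }
    if (!ok || length(views) == 0) {
      if (length(views) == 0 && ok)
        log_lines <- c(log_lines, paste0("skip ", eid, ": no view rasters"))
      next
    }
    res <- process_ear_views(views, config, ear_id = eid)
    rows[[eid]] <- res$traits
    profiles[[eid]] <- res$norm_profile
    log_lines <- c(log_lines, paste0("ear ", eid, ": ", length(views),
                                     " views"))
  }
  traits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ear_id = character())
  rownames(traits) <- NULL
  utils::write.csv(traits, file.path(config$output_dir, "traits.csv"),
                   row.names = FALSE)
  if (length(profiles)) {
    pm <- do.call(rbind, profiles)
    utils::write.csv(data.frame(ear_id = names(profiles), pm,
                                check.names = FALSE),
                     file.path(config$output_dir, "profiles.csv"),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  if (nrow(traits) == 0)
    warning("no ears processed from '", config$input_dir, "'", call. = FALSE)
  invisible(traits)
}

# Analysis parameters only: run locations are deliberately excluded so logs
# from identical analyses are byte-identical wherever they are written.
config_echo <- function(config) {
  flat <- config[setdiff(names(config), c("input_dir", "output_dir"))]
  flat <- flat[!vapply(flat, is.null, logical(1))]
  paste(names(flat), vapply(flat, function(x) paste(format(x), collapse = ","),
                            character(1)),
        sep = "=", collapse = " ")
}
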