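#' Run the full synthetic pipeline
#'
#' Executes simulate -> detect -> track -> segment -> crop -> classify
#' (-> FRET) from a single configuration, writing every intermediate
#' artifact (CSV/TIFF), a JSON summary and a parameter log into `out_dir`.
#' Fully deterministic for a fixed `config$seed`.
#'
#' @param config configuration list, see [default_config()].
#' @param out_dir output directory (created if missing).
#' @return the summary list, invisibly (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sc <- config$simulate
  seed <- config$seed

  geometry <- stage("simulate", generate_scs_geometry(
    shape = sc$shape, voxel_size = sc$voxel_size,
    wall_thickness = sc$wall_thickness, lumen_thickness = sc$lumen_thickness,
    curvature = sc$curvature, frame_interval = sc$frame_interval,
    seed = seed))

  fret_on <- isTRUE(config$fret$enabled)
  anchors <- if (fret_on)
    macrophage_anchors(geometry, config$fret$n_anchors, seed = seed)
  contact <- if (fret_on)
    list(anchors = anchors, n_contact = config$fret$n_contact,
         clear_dist = 25)

  gt <- stage("simulate", simulate_tracks(
    geometry,
    n_per_fate = unlist(sc$n_per_fate),
    motion = list(speed = sc$speed, persistence = sc$persistence,
                  dwell_frames = config$fret$dwell_frames %||% 4),
    n_frames = sc$n_frames, margin = config$classify$margin,
    contact = contact, min_spacing = sc$min_spacing %||% 0, seed = seed))
  write_ground_truth(gt, file.path(out_dir, "ground_truth.csv"))

  channel_spec <- list(cells = list(source = "cells",
                                    amplitude = sc$amplitude))
  if (fret_on) {
    channel_spec$donor <- list(source = "fret_donor",
                               amplitude = sc$amplitude)
    channel_spec$acceptor <- list(source = "fret_acceptor",
                                  amplitude = sc$amplitude)
    channel_spec$macro <- list(source = "macrophages",
                               amplitude = sc$amplitude)
  }
  nm <- if (is.null(sc$noise)) NULL else
    noise_model(sc$noise$photon_scale, sc$noise$read_sigma,
                sc$noise$background_level)
  movie <- stage("simulate", render_movie(
    geometry, gt, channel_spec = channel_spec, anchors = anchors,
    fret = list(r_min = config$fret$r_min, r_max = config$fret$r_max),
    noise = nm, n_frames = sc$n_frames, seed = seed))
  write_movie(movie, file.path(out_dir, "movie.tif"))
  write_labels(geometry$class_volume, file.path(out_dir, "geometry.tif"))

  spots <- stage("detect", detect_spots(
    movie, channel = "cells", radius = config$detect$radius,
    quality_threshold = config$detect$quality_threshold))
  write_spots(spots, file.path(out_dir, "spots.csv"))

  tracks <- stage("track", track_spots(
    spots, config$track$max_link_dist, config$track$max_gap_dist,
    config$track$max_gap_frames, config$track$min_length))
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))

  maps <- stage("segment", probability_maps_from_geometry(
    geometry, n_frames = sc$n_frames, label_noise = sc$label_noise %||% 0,
    factor = sc$map_factor %||% 1L, seed = seed))
  if ((config$segment$downsample %||% 1L) > 1L)
    maps <- stage("segment", downsample_xy(maps, config$segment$downsample))
  maps <- stage("segment", smooth_probability_maps(maps,
                                                   config$segment$window))
  regions <- stage("segment", build_scs_mask(assign_classes(maps)))
  write_labels(regions$mask + 0L, file.path(out_dir, "scs_mask.tif"))
  write_labels(regions$sidedness, file.path(out_dir, "sidedness.tif"))

  cl <- config$classify
  movie_c <- crop_consistent(movie, cl$z_slices, cl$time_points)
  regions_c <- crop_consistent(regions, cl$z_slices, cl$time_points)
  tracks_c <- crop_consistent(tracks, cl$z_slices, cl$time_points,
                              voxel_size = movie$voxel_size,
                              min_length = config$track$min_length)

  classes <- stage("classify", classify_tracks(tracks_c, regions_c,
                                               cl$margin))
  write_table_csv(classes, file.path(out_dir, "classes.csv"), "classes")
  fractions <- stage("classify", summarize_fractions(classes))
  write_fractions(fractions, file.path(out_dir, "fractions.csv"))

  summary <- list(
    parameters = config,
    n_spots = nrow(spots),
    n_tracks = length(unique(tracks$track_id)),
    n_tracks_classified = nrow(classes),
    fractions = as.list(fractions[1, grepl("^frac_", names(fractions))])
  )

  if (fret_on) {
    masks <- stage("fret", cell_masks_from_tracks(
      gt, geometry$shape, geometry$voxel_size,
      radius = config$fret$cell_radius, n_frames = sc$n_frames))
    records <- stage("fret", cell_records(
      movie, masks, "donor", "acceptor", "macro",
      background = if (is.null(nm)) 0 else nm$background_level))
    thr <- config$fret$threshold
    if (is.null(thr)) {
      h <- coloc_histogram(records)
      thr <- tryCatch(fit_decay_threshold(h)$threshold,
                      error = function(e) NA_real_)
      if (is.na(thr)) thr <- stats::median(records$coloc_intensity[
        records$coloc_intensity > 0]) %||% 1
    }
    records <- assign_groups(records, thr)
    write_table_csv(records, file.path(out_dir, "fret_records.csv"),
                    "fret-records")
    gm <- tapply(records$ratio, records$group, mean, na.rm = TRUE)
    summary$fret <- list(threshold = thr,
                         group_means = as.list(gm))
  }

  summary$log <- list(r_version = as.character(getRversion()),
                      package_version =
                        as.character(utils::packageVersion("scstrack")),
                      seed = seed, timestamp_utc = "fixed-for-determinism")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Histogram of colocalization intensities
#'
#' Bins the per-cell colocalization intensities of contacting cells
#' (intensity > 0) for [fit_decay_threshold()].
#'
#' @param records data.frame from [cell_records()].
#' @param n_bins number of bins.
#' @return data.frame with `x` (bin centres) and `count`.
#' @export
coloc_histogram <- function(records, n_bins = 50L) {
  v <- records$coloc_intensity[records$coloc_intensity > 0]
  if (!length(v)) stop("no nonzero colocalization intensities")
  br <- seq(0, max(v) * 1.0001, length.out = n_bins + 1)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  data.frame(x = h$mids, count = h$counts)
}
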