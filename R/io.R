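SCHEMA_VERSION <- "v1"

#' Write a movie as multi-page TIFF with a YAML sidecar
#'
#' Pages are ordered t-major, then channel, then z; intensities are scaled
#' into `[0, 1]` and stored at 32 bits per sample; the scale factor, axes,
#' voxel sizes (um), frame interval and channel names go into a
#' `<path>.yaml` sidecar so the reader can restore physical units.
#'
#' @param movie an [scs_movie()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  scale <- max(movie$data, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0
  for (f in seq_len(d[1]))
    for (ci in seq_len(d[2]))
      for (iz in seq_len(d[3])) {
        k <- k + 1
        pages[[k]] <- pmin(pmax(
          matrix(movie$data[f, ci, iz, , ], d[4], d[5]) / scale, 0), 1)
      }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(schema = paste("scstrack-movie", SCHEMA_VERSION),
               axes = "TCZYX", shape = as.integer(d),
               voxel_size = movie$voxel_size,
               frame_interval = movie$frame_interval,
               channels = movie$channels, intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' Axis order, voxel sizes and intensity scale come from the YAML sidecar;
#' `voxel_size` and `frame_interval` arguments override it. Without a
#' sidecar, both overrides plus `shape` are required.
#'
#' @param path `.tif` path.
#' @param voxel_size optional um-per-voxel override `(z, y, x)`.
#' @param frame_interval optional seconds override.
#' @param shape optional `(t, c, z, y, x)` when no sidecar exists.
#' @param channels optional channel names.
#' @return an [scs_movie()].
#' @export
read_movie <- function(path, voxel_size = NULL, frame_interval = NULL,
                       shape = NULL, channels = NULL) {
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  if (is.null(voxel_size)) voxel_size <- meta$voxel_size
  if (is.null(voxel_size))
    stop("no voxel size: sidecar missing and no override given")
  if (is.null(frame_interval))
    frame_interval <- meta$frame_interval %||% 35
  if (is.null(shape)) shape <- meta$shape
  if (is.null(shape)) stop("no shape metadata and no `shape` override")
  scale <- meta$intensity_scale %||% 1
  if (is.null(channels)) channels <- meta$channels
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != prod(shape[1:3]))
    stop("page count does not match the declared shape")
  dat <- array(0, dim = shape)
  k <- 0
  for (f in seq_len(shape[1]))
    for (ci in seq_len(shape[2]))
      for (iz in seq_len(shape[3])) {
        k <- k + 1
        dat[f, ci, iz, , ] <- pages[[k]] * scale
      }
  scs_movie(dat, voxel_size, frame_interval, channels)
}

#' Write / read small integer label volumes as 8-bit TIFF
#'
#' Used for geometry class volumes, sinus masks and sidedness labels
#' (values 0-255). 3D `(z, y, x)` or 4D `(t, z, y, x)` arrays.
#'
#' @param labels integer array.
#' @param path `.tif` path.
#' @return `path` invisibly / the label array.
#' @export
write_labels <- function(labels, path) {
  d <- dim(labels)
  if (length(d) == 3L) { labels <- array(labels, c(1L, d)); d <- dim(labels) }
  pages <- vector("list", d[1] * d[2])
  k <- 0
  for (f in seq_len(d[1]))
    for (iz in seq_len(d[2])) {
      k <- k + 1
      pages[[k]] <- matrix(labels[f, iz, , ], d[3], d[4]) / 255
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  yaml::write_yaml(list(schema = paste("scstrack-labels", SCHEMA_VERSION),
                        axes = "TZYX", shape = as.integer(d)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  shape <- meta$shape
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(0L, dim = shape)
  k <- 0
  for (f in seq_len(shape[1]))
    for (iz in seq_len(shape[2])) {
      k <- k + 1
      out[f, iz, , ] <- as.integer(round(pages[[k]] * 255))
    }
  if (shape[1] == 1L) out <- array(out, shape[2:4])
  out
}

# ---- CSV round trips ------------------------------------------------------

write_table_csv <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scstrack-%s %s", what, SCHEMA_VERSION), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' CSV writers/readers for pipeline artifacts
#'
#' Spots, tracks, ground truth, classifications, fraction tables and FRET
#' records are stored as headered CSV with a schema-version comment line.
#'
#' @param x the object to write.
#' @param path file path.
#' @name scs-csv
NULL

#' @rdname scs-csv
#' @export
write_spots <- function(x, path) write_table_csv(x, path, "spots")
#' @rdname scs-csv
#' @export
read_spots <- function(path) read_table_csv(path)
#' @rdname scs-csv
#' @export
write_tracks <- function(x, path) write_table_csv(as.data.frame(x), path,
                                                  "tracks")
#' @rdname scs-csv
#' @export
read_tracks <- function(path) {
  out <- read_table_csv(path)
  class(out) <- c("scs_tracks", "data.frame")
  out
}
#' @rdname scs-csv
#' @export
write_ground_truth <- function(x, path)
  write_table_csv(as.data.frame(x), path, "ground-truth")
#' @rdname scs-csv
#' @export
read_ground_truth <- function(path) {
  out <- read_table_csv(path)
  class(out) <- c("scs_ground_truth", "data.frame")
  out
}
#' @rdname scs-csv
#' @export
write_fractions <- function(x, path) write_table_csv(x, path, "fractions")
#' @rdname scs-csv
#' @export
read_fractions <- function(path) read_table_csv(path)

# ---- run configuration ----------------------------------------------------

#' Default pipeline configuration
#'
#' All stage parameters with their paper-style defaults: detection radius
#' 10 um, LAP caps 20 um / 20 um / 2 frames, minimum track length 5,
#' 3-frame temporal smoothing, 4x xy down-sampling for classification,
#' 5 um entering/leaving margin, 13 z-slice x 32 time-point crop.
#'
#' @return a nested list; serialize with [write_config()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      shape = c(13L, 128L, 128L), voxel_size = c(4, 2, 2),
      frame_interval = 35, n_frames = 32L,
      wall_thickness = c(4, 4), lumen_thickness = 8, curvature = 0.0005,
      n_per_fate = list(entering = 5L, leaving = 5L, internal = 5L,
                        parenchymal = 5L),
      speed = 6, persistence = 0.6, min_spacing = 20,
      amplitude = 50,
      noise = list(photon_scale = 1, read_sigma = 2, background_level = 5),
      label_noise = 0.02, map_factor = 2L
    ),
    detect = list(radius = 10, quality_threshold = 10),
    track = list(max_link_dist = 20, max_gap_dist = 20, max_gap_frames = 2L,
                 min_length = 5L),
    segment = list(window = 3L, downsample = 1L),
    classify = list(margin = 5, z_slices = 13L, time_points = 32L),
    fret = list(enabled = FALSE, r_min = 0.2, r_max = 0.7,
                n_anchors = 12L, n_contact = 4L, dwell_frames = 4L,
                cell_radius = 6, threshold = NULL)
  )
}

#' @rdname default_config
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' @rdname default_config
#' @export
validate_config <- function(config) {
  pos <- function(x, nm) if (!is.null(x) && any(x <= 0))
    stop(sprintf("config field `%s` must be positive", nm))
  pos(config$detect$radius, "detect.radius")
  pos(config$track$max_link_dist, "track.max_link_dist")
  pos(config$track$max_gap_dist, "track.max_gap_dist")
  pos(config$classify$margin, "classify.margin")
  pos(config$classify$z_slices, "classify.z_slices")
  pos(config$classify$time_points, "classify.time_points")
  pos(config$simulate$voxel_size, "simulate.voxel_size")
  invisible(config)
}
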