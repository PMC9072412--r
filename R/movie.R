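#' Multi-channel time-lapse volume
#'
#' Lightweight container for an intravital movie: a 5D intensity array in
#' `(t, c, z, y, x)` order plus the physical calibration needed downstream.
#'
#' @param data numeric 5D array, dimensions `(t, c, z, y, x)`.
#' @param voxel_size numeric length-3, micrometres per voxel along `(z, y, x)`.
#' @param frame_interval seconds between consecutive z-stacks.
#' @param channels optional character vector of channel names.
#' @return an object of class `scs_movie`.
#' @export
scs_movie <- function(data, voxel_size, frame_interval = 35,
                      channels = NULL) {
  if (length(dim(data)) != 5L)
    stop("`data` must be a 5D (t, c, z, y, x) array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values (z, y, x) in um")
  stopifnot_scalar(frame_interval, "frame_interval")
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  if (length(channels) != dim(data)[2])
    stop("length(channels) must match the channel dimension")
  structure(list(
    data = data,
    voxel_size = as.numeric(voxel_size),
    frame_interval = as.numeric(frame_interval),
    channels = as.character(channels)
  ), class = "scs_movie")
}

#' @export
print.scs_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<scs_movie> %d frames x %d channels x (%d z, %d y, %d x) voxels\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  voxel size (z,y,x): %s um; frame interval: %gs\n",
              paste(signif(x$voxel_size, 3), collapse = " x "),
              x$frame_interval))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.scs_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[1]

#' Extract one 3D channel volume from a movie frame
#'
#' @param movie an [scs_movie()].
#' @param frame frame index (1-based).
#' @param channel channel index or name.
#' @return numeric 3D array `(z, y, x)`.
#' @export
movie_frame <- function(movie, frame, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, movie$channels)
  d <- dim(movie$data)
  if (is.na(channel) || channel < 1 || channel > d[2])
    stop("channel not present in movie")
  if (frame < 1 || frame > d[1]) stop("frame out of range")
  array(movie$data[frame, channel, , , ], dim = d[3:5])
}

# physical extent (um) of the volume along (z, y, x): voxel centres span
# [0, (n - 1) * voxel_size]
movie_extent <- function(shape, voxel_size) (shape - 1) * voxel_size
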