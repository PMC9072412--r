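#' Scale-normalized Laplacian-of-Gaussian response
#'
#' Filters a 3D volume with an anisotropic Gaussian of physical scale
#' `sigma = radius / sqrt(3)` um (the scale at which the 3D LoG response of a
#' ball of the given radius peaks), takes second differences along each axis
#' in physical units, and returns the sign-flipped, `sigma^2`-normalized
#' response so that bright blobs give positive peaks.
#'
#' @param volume numeric 3D array `(z, y, x)`.
#' @param radius blob radius in um.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @return numeric 3D response array of the same shape.
#' @export
log_response <- function(volume, radius, voxel_size) {
  stopifnot_scalar(radius, "radius")
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  sigma <- radius / sqrt(3)
  sv <- sigma / voxel_size
  if (any(sv < 0.5))
    stop(sprintf(
      "scale sigma = %.2f um is undersampled (< 0.5 voxel) on some axis",
      sigma))
  s <- smooth3d(volume, sv)
  resp <- second_diff(s, 0, voxel_size[1]) +
    second_diff(s, 1, voxel_size[2]) +
    second_diff(s, 2, voxel_size[3])
  -sigma^2 * resp
}

# greedy non-maximum suppression: keep the higher-quality maximum when two
# are closer than `radius` um apart
nms_spots <- function(df, radius) {
  if (nrow(df) <= 1) return(df)
  ord <- order(-df$quality, df$z_um, df$y_um, df$x_um)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  p <- as.matrix(df[, c("z_um", "y_um", "x_um")])
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      j <- (i + 1):nrow(df)
      d <- sqrt(colSums((t(p[j, , drop = FALSE]) - p[i, ])^2))
      keep[j][d < radius & keep[j]] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

#' Detect cells as LoG maxima in every frame
#'
#' Finds strict 26-neighbourhood local maxima of the [log_response()] above a
#' quality threshold, merges maxima closer than `radius` um (keeping the
#' higher quality), and reports positions at voxel centres in physical um.
#' Detections on the outermost voxel layer are kept but flagged `border`.
#'
#' The quality is the scale-normalized LoG response at the maximum; its
#' units depend on the image intensity scale, so thresholds ported from
#' other software (e.g. the value 15 used with TrackMate) are accepted via
#' configuration but are not unit-compatible guarantees.
#'
#' @param movie an [scs_movie()].
#' @param channel channel index or name.
#' @param radius blob radius in um (10 um for the B-cell data this pipeline
#'   models).
#' @param quality_threshold minimum response at the maximum.
#' @param frames frames to process (default all).
#' @return data.frame with columns
#'   `frame, z_um, y_um, x_um, quality, border`, sorted by frame then
#'   decreasing quality.
#' @export
detect_spots <- function(movie, channel = 1L, radius = 10,
                         quality_threshold = 10, frames = NULL) {
  d <- dim(movie$data)
  if (is.null(frames)) frames <- seq_len(d[1])
  vs <- movie$voxel_size
  out <- list()
  for (f in frames) {
    vol <- movie_frame(movie, f, channel)
    if (anyNA(vol)) stop("NaN voxels in frame ", f)
    resp <- log_response(vol, radius, vs)
    idx <- .local_maxima_3d(resp, quality_threshold)
    if (!length(idx)) next
    shape <- dim(vol)
    iz <- (idx - 1) %% shape[1] + 1
    iy <- ((idx - 1) %/% shape[1]) %% shape[2] + 1
    ix <- (idx - 1) %/% (shape[1] * shape[2]) + 1
    df <- data.frame(
      frame = f,
      z_um = (iz - 1) * vs[1], y_um = (iy - 1) * vs[2],
      x_um = (ix - 1) * vs[3],
      quality = resp[idx],
      border = iz == 1 | iz == shape[1] | iy == 1 | iy == shape[2] |
        ix == 1 | ix == shape[3])
    out[[length(out) + 1]] <- nms_spots(df, radius)
  }
  if (!length(out))
    return(data.frame(frame = integer(), z_um = numeric(), y_um = numeric(),
                      x_um = numeric(), quality = numeric(),
                      border = logical()))
  res <- do.call(rbind, out)
  res <- res[order(res$frame, -res$quality, res$z_um, res$y_um, res$x_um), ]
  rownames(res) <- NULL
  res
}
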