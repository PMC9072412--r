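#' Crop movies, maps, regions or tracks to a consistent analysis window
#'
#' Keeps the first `z_slices` z-planes and the first `time_points` frames,
#' the windowing used to make per-movie track fractions comparable across
#' acquisitions (13 z-slices and 32 time points in the study this pipeline
#' models).
#'
#' @param x an [scs_movie()], `scs_probmaps`, `scs_regions`, or a
#'   `scs_tracks` data.frame.
#' @param z_slices number of z-planes to keep.
#' @param time_points number of frames to keep.
#' @param voxel_size needed for track cropping only: um per voxel `(z,y,x)`.
#' @param min_length tracks left with fewer spots after cropping are dropped
#'   (their count is attached as attribute `dropped_tracks`).
#' @return the cropped object, same type.
#' @export
crop_consistent <- function(x, z_slices = 13L, time_points = 32L,
                            voxel_size = NULL, min_length = 5L) {
  UseMethod("crop_consistent")
}

check_crop <- function(nt, nz, time_points, z_slices) {
  if (time_points > nt || z_slices > nz)
    stop(sprintf("crop %dx%d exceeds data size %dx%d (t x z)",
                 time_points, z_slices, nt, nz))
}

#' @export
crop_consistent.scs_movie <- function(x, z_slices = 13L, time_points = 32L,
                                      voxel_size = NULL, min_length = 5L) {
  d <- dim(x$data)
  check_crop(d[1], d[3], time_points, z_slices)
  x$data <- x$data[seq_len(time_points), , seq_len(z_slices), , ,
                   drop = FALSE]
  x
}

#' @export
crop_consistent.scs_probmaps <- function(x, z_slices = 13L,
                                         time_points = 32L,
                                         voxel_size = NULL, min_length = 5L) {
  d <- dim(x$probs)
  check_crop(d[1], d[3], time_points, z_slices)
  x$probs <- x$probs[seq_len(time_points), , seq_len(z_slices), , ,
                     drop = FALSE]
  x$full_shape <- c(z_slices, x$full_shape[2:3])
  x
}

#' @export
crop_consistent.scs_regions <- function(x, z_slices = 13L, time_points = 32L,
                                        voxel_size = NULL, min_length = 5L) {
  d <- dim(x$mask)
  tp <- if (x$static) 1L else time_points
  check_crop(d[1], d[2], tp, z_slices)
  x$mask <- x$mask[seq_len(tp), seq_len(z_slices), , , drop = FALSE]
  x$distance <- x$distance[seq_len(tp), seq_len(z_slices), , , drop = FALSE]
  x$sidedness <- x$sidedness[seq_len(tp), seq_len(z_slices), , ,
                             drop = FALSE]
  x
}

#' @export
crop_consistent.scs_tracks <- function(x, z_slices = 13L, time_points = 32L,
                                       voxel_size = NULL, min_length = 5L) {
  if (is.null(voxel_size))
    stop("track cropping needs `voxel_size` to bound z")
  zmax <- (z_slices - 0.5) * voxel_size[1] # nearest voxel still in window
  keep <- x$frame <= time_points & x$z_um < zmax
  out <- x[keep, , drop = FALSE]
  n_by <- table(out$track_id)
  ok <- names(n_by)[n_by >= min_length]
  dropped <- length(unique(x$track_id)) - length(ok)
  out <- out[out$track_id %in% as.integer(ok), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scs_tracks", "data.frame")
  attr(out, "dropped_tracks") <- dropped
  out
}

region_frame_index <- function(regions, frame) {
  if (regions$static) 1L else frame
}

spot_state <- function(pos, frame, regions) {
  shape <- dim(regions$mask)[2:4]
  vox <- pos_to_voxel(pos, shape, regions$voxel_size)
  if (anyNA(vox)) stop("spot outside volume bounds")
  fi <- region_frame_index(regions, frame)
  if (fi > dim(regions$mask)[1]) stop("track frame not covered by regions")
  if (regions$mask[fi, vox[1], vox[2], vox[3]])
    list(state = "inside", distance = 0)
  else
    list(state = c("parenchymal", "extranodal")[
           regions$sidedness[fi, vox[1], vox[2], vox[3]]],
         distance = regions$distance[fi, vox[1], vox[2], vox[3]])
}

#' Classify one track's relationship to the sinus
#'
#' Evaluates the first and last detection against the frame-matched sinus
#' mask: `entering` tracks start at least `min_outside_dist` um into the
#' parenchyma and end inside the sinus; `leaving` tracks start inside and
#' end at least `min_outside_dist` um from the sinus (either side);
#' `internal` tracks start and end inside; everything else is
#' `non_interacting`.
#'
#' @param track data.frame rows of one track (`frame, z_um, y_um, x_um`).
#' @param regions an `scs_regions` from [build_scs_mask()].
#' @param min_outside_dist margin in um (the "at least 5 um" rule).
#' @return list with `label`, `start_state`, `start_distance`, `end_state`,
#'   `end_distance`.
#' @export
classify_track <- function(track, regions, min_outside_dist = 5) {
  if (!nrow(track)) stop("track has no spots")
  track <- track[order(track$frame), , drop = FALSE]
  first <- track[1, ]; last <- track[nrow(track), ]
  s0 <- spot_state(c(first$z_um, first$y_um, first$x_um), first$frame,
                   regions)
  s1 <- spot_state(c(last$z_um, last$y_um, last$x_um), last$frame, regions)
  label <- if (s0$state == "parenchymal" &&
               s0$distance >= min_outside_dist && s1$state == "inside")
    "entering"
  else if (s0$state == "inside" && s1$state != "inside" &&
           s1$distance >= min_outside_dist)
    "leaving"
  else if (s0$state == "inside" && s1$state == "inside")
    "internal"
  else "non_interacting"
  list(label = label,
       start_state = s0$state, start_distance = s0$distance,
       end_state = s1$state, end_distance = s1$distance)
}

#' Classify every track in a movie
#'
#' @param tracks a `scs_tracks` data.frame.
#' @param regions an `scs_regions`.
#' @param min_outside_dist margin in um.
#' @return data.frame with one row per track: `track_id, label,
#'   start_state, start_distance, end_state, end_distance`.
#' @export
classify_tracks <- function(tracks, regions, min_outside_dist = 5) {
  ids <- unique(tracks$track_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    cl <- classify_track(tracks[tracks$track_id == id, , drop = FALSE],
                         regions, min_outside_dist)
    data.frame(track_id = id, label = cl$label,
               start_state = cl$start_state,
               start_distance = cl$start_distance,
               end_state = cl$end_state, end_distance = cl$end_distance)
  }))
  if (is.null(out))
    out <- data.frame(track_id = integer(), label = character(),
                      start_state = character(), start_distance = numeric(),
                      end_state = character(), end_distance = numeric())
  out
}

#' Per-movie label counts and fractions
#'
#' @param classifications either a single classification data.frame (from
#'   [classify_tracks()]), or a named list of them, one per movie.
#' @return data.frame with one row per movie: `movie`, `n_tracks`, a count
#'   and a fraction column per label. Fractions sum to one per movie;
#'   movies with zero tracks are excluded with a warning.
#' @export
summarize_fractions <- function(classifications) {
  if (is.data.frame(classifications))
    classifications <- list(movie1 = classifications)
  if (!length(classifications)) stop("at least one movie is required")
  if (is.null(names(classifications)))
    names(classifications) <- paste0("movie", seq_along(classifications))
  rows <- list()
  for (nm in names(classifications)) {
    cl <- classifications[[nm]]
    n <- nrow(cl)
    if (n == 0) {
      warning(sprintf("movie '%s' has zero tracks and was excluded", nm))
      next
    }
    counts <- vapply(TRACK_LABELS, function(l) sum(cl$label == l), 0L)
    row <- data.frame(movie = nm, n_tracks = n)
    for (l in TRACK_LABELS) {
      row[[paste0("n_", l)]] <- counts[[l]]
      row[[paste0("frac_", l)]] <- counts[[l]] / n
    }
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no movie had any classified tracks")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare a label's per-movie fraction between two conditions
#'
#' Unpaired two-sample t test (equal variances by default) on per-movie
#' fractions, one- or two-tailed — the statistic behind condition contrasts
#' such as control vs ACKR4-deficient sinus recycling.
#'
#' @param table_a,table_b fraction tables from [summarize_fractions()].
#' @param metric which label's fraction to compare.
#' @param alternative `"two.sided"`, `"greater"` (A > B) or `"less"`.
#' @param var_equal use the pooled-variance t test (default) or Welch.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `alternative`.
#' @export
compare_conditions <- function(table_a, table_b, metric = "leaving",
                               alternative = c("two.sided", "greater",
                                               "less"),
                               var_equal = TRUE) {
  alternative <- match.arg(alternative)
  col <- paste0("frac_", metric)
  if (!col %in% names(table_a) || !col %in% names(table_b))
    stop("unknown metric: ", metric)
  a <- table_a[[col]]; b <- table_b[[col]]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 movies per condition")
  tt <- t.test(a, b, alternative = alternative, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       alternative = alternative)
}
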