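LAP_BIG <- 1e12

# Jaqaman-style augmented square assignment: rows = n1 sources + n2 target
# dummies, cols = n2 targets + n1 source dummies. Top-left holds the real
# costs (LAP_BIG where forbidden), the two diagonal blocks price the
# "no link" alternative at cap^2, and the bottom-right block is free.
# Returns an integer vector: for source i, the matched target j or NA.
solve_augmented_lap <- function(cost, cap2) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  m <- matrix(LAP_BIG, n1 + n2, n2 + n1)
  m[seq_len(n1), seq_len(n2)] <- cost
  for (i in seq_len(n1)) m[i, n2 + i] <- cap2
  for (j in seq_len(n2)) m[n1 + j, j] <- cap2
  m[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  asg <- .solve_lap(m)
  link <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- asg[i]
    if (j <= n2 && cost[i, j] < LAP_BIG) link[i] <- j
  }
  link
}

canonical_spot_order <- function(spots) {
  spots[order(spots$frame, spots$z_um, spots$y_um, spots$x_um), ,
        drop = FALSE]
}

#' Link per-frame detections into tracklets
#'
#' For every consecutive frame pair, solves a linear assignment problem with
#' squared Euclidean distances as costs and a "no link" alternative priced
#' at `max_link_dist^2`; links longer than `max_link_dist` are forbidden.
#' Every spot ends up in exactly one tracklet.
#'
#' @param spots data.frame from [detect_spots()] (columns
#'   `frame, z_um, y_um, x_um`, optionally `quality`).
#' @param max_link_dist maximum frame-to-frame link distance in um.
#' @return a `scs_tracks` data.frame: spot rows plus a `track_id` column.
#' @export
link_frames <- function(spots, max_link_dist = 20) {
  stopifnot_scalar(max_link_dist, "max_link_dist")
  spots <- canonical_spot_order(as.data.frame(spots))
  n <- nrow(spots)
  track_of <- rep(NA_integer_, n)
  next_id <- 0L
  if (n > 0) {
    frames <- sort(unique(spots$frame))
    rows_f <- split(seq_len(n), factor(spots$frame, levels = frames))
    # spots in the first frame (and any never linked) start new tracklets
    for (fi in seq_along(frames)) {
      rows2 <- rows_f[[fi]]
      linked2 <- rep(FALSE, length(rows2))
      if (fi > 1 && frames[fi] == frames[fi - 1] + 1) {
        rows1 <- rows_f[[fi - 1]]
        p1 <- as.matrix(spots[rows1, c("z_um", "y_um", "x_um")])
        p2 <- as.matrix(spots[rows2, c("z_um", "y_um", "x_um")])
        d2 <- outer(rowSums(p1^2), rowSums(p2^2), `+`) - 2 * p1 %*% t(p2)
        d2 <- pmax(d2, 0)
        cost <- ifelse(d2 <= max_link_dist^2, d2, LAP_BIG)
        link <- solve_augmented_lap(cost, max_link_dist^2)
        for (i in seq_along(rows1)) {
          if (!is.na(link[i])) {
            track_of[rows2[link[i]]] <- track_of[rows1[i]]
            linked2[link[i]] <- TRUE
          }
        }
      }
      for (k in which(!linked2)) {
        next_id <- next_id + 1L
        track_of[rows2[k]] <- next_id
      }
    }
  }
  out <- cbind(track_id = track_of, spots)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scs_tracks", "data.frame")
  out
}

track_endpoints <- function(tracks) {
  ids <- unique(tracks$track_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    data.frame(track_id = id,
               first_frame = tr$frame[1], last_frame = tr$frame[nrow(tr)],
               z0 = tr$z_um[1], y0 = tr$y_um[1], x0 = tr$x_um[1],
               z1 = tr$z_um[nrow(tr)], y1 = tr$y_um[nrow(tr)],
               x1 = tr$x_um[nrow(tr)])
  }))
}

#' Close temporal gaps between tracklets
#'
#' Solves one global assignment over all (tracklet end, tracklet start)
#' pairs whose frame difference is in `[1, max_gap_frames]` and whose
#' distance is at most `max_gap_dist` um, with cost equal to the squared
#' distance and the no-merge alternative priced at `max_gap_dist^2`.
#' Merged tracks keep the earlier tracklet's id. With the paper-style
#' setting of two frames, a segment ending at frame 10 can be joined to one
#' starting at frame 12 (one missing frame) but not at frame 13.
#'
#' @param tracklets a `scs_tracks` data.frame from [link_frames()].
#' @param max_gap_dist maximum gap-closing distance in um.
#' @param max_gap_frames maximum frame difference between the end of one
#'   segment and the start of the next.
#' @return a `scs_tracks` data.frame with gaps closed.
#' @export
close_gaps <- function(tracklets, max_gap_dist = 20, max_gap_frames = 2L) {
  stopifnot_scalar(max_gap_dist, "max_gap_dist")
  if (max_gap_frames < 1) stop("max_gap_frames must be >= 1")
  tracks <- as.data.frame(tracklets)
  if (!nrow(tracks)) return(tracklets)
  key <- paste(tracks$frame, tracks$z_um, tracks$y_um, tracks$x_um)
  owners <- tapply(tracks$track_id, key, function(v) length(unique(v)))
  if (any(owners > 1)) stop("tracklets share a spot")
  ep <- track_endpoints(tracks)
  nseg <- nrow(ep)
  if (nseg > 1) {
    dframe <- outer(ep$last_frame, ep$first_frame,
                    function(a, b) b - a)
    ends <- as.matrix(ep[, c("z1", "y1", "x1")])
    starts <- as.matrix(ep[, c("z0", "y0", "x0")])
    d2 <- outer(rowSums(ends^2), rowSums(starts^2), `+`) -
      2 * ends %*% t(starts)
    d2 <- pmax(d2, 0)
    ok <- dframe >= 1 & dframe <= max_gap_frames & d2 <= max_gap_dist^2
    diag(ok) <- FALSE
    if (any(ok)) {
      cost <- ifelse(ok, d2, LAP_BIG)
      link <- solve_augmented_lap(cost, max_gap_dist^2)
      succ <- link # successor segment of each segment (by index), or NA
      # follow chains from segments that are not anyone's successor
      is_succ <- rep(FALSE, nseg)
      is_succ[stats::na.omit(succ)] <- TRUE
      newid <- rep(NA_integer_, nseg)
      for (s in seq_len(nseg)) {
        if (is_succ[s]) next
        id <- ep$track_id[s]
        cur <- s
        while (!is.na(cur)) {
          newid[cur] <- id
          cur <- succ[cur]
        }
      }
      map <- setNames(newid, ep$track_id)
      tracks$track_id <- map[as.character(tracks$track_id)]
    }
  }
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  class(tracks) <- c("scs_tracks", "data.frame")
  tracks
}

#' Discard short tracks
#'
#' Retains tracks with at least `min_length` detections (the paper-style
#' rule discards all tracks of fewer than 5 frames); order and ids are
#' preserved.
#'
#' @param tracks a `scs_tracks` data.frame.
#' @param min_length minimum number of detections.
#' @return the filtered `scs_tracks`.
#' @export
filter_tracks <- function(tracks, min_length = 5L) {
  if (!nrow(tracks)) return(tracks)
  n_by <- table(tracks$track_id)
  keep <- names(n_by)[n_by >= min_length]
  out <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scs_tracks", "data.frame")
  out
}

#' Full LAP tracking: link, close gaps, filter
#'
#' @param spots detections from [detect_spots()].
#' @param max_link_dist,max_gap_dist,max_gap_frames,min_length see
#'   [link_frames()], [close_gaps()], [filter_tracks()]. Defaults follow the
#'   paper-style settings 20 um / 20 um / 2 frames / 5 detections.
#' @return a `scs_tracks` data.frame.
#' @export
track_spots <- function(spots, max_link_dist = 20, max_gap_dist = 20,
                        max_gap_frames = 2L, min_length = 5L) {
  filter_tracks(
    close_gaps(link_frames(spots, max_link_dist), max_gap_dist,
               max_gap_frames),
    min_length)
}
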