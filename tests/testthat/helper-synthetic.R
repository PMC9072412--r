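# Shared fixtures and independent oracles, all built in code at test time.

small_geometry <- function(seed = 1L, shape = c(13, 64, 64),
                           voxel_size = c(4, 2, 2), ...) {
  generate_scs_geometry(shape = shape, voxel_size = voxel_size, seed = seed,
                        ...)
}

# flat-slab geometry: shell parallel to the z = 0 face, no roughness
slab_geometry <- function(shape = c(13, 32, 32), voxel_size = c(4, 2, 2)) {
  generate_scs_geometry(shape = shape, voxel_size = voxel_size,
                        curvature = 0, roughness_amplitude = 0,
                        min_parenchyma = 0, seed = 1)
}

# plant non-overlapping Gaussian blobs at random continuous positions and
# return the movie plus the planted centres (one frame per call)
plant_blobs <- function(n, shape = c(13, 128, 128), voxel_size = c(4, 2, 2),
                        spacing = 20, amplitude = 50, sigma = 10 / sqrt(3),
                        noise = noise_model(1, 2, 5), n_frames = 1,
                        seed = 1) {
  set.seed(seed)
  ext <- (shape - 1) * voxel_size
  centres <- list()
  for (f in seq_len(n_frames)) {
    pts <- matrix(NA_real_, n, 3)
    k <- 0; tries <- 0
    while (k < n && tries < 50000) {
      tries <- tries + 1
      # keep blobs away from the lateral borders for clean localization
      p <- c(runif(1, 0.15, 0.85) * ext[1],
             runif(1, 0.08, 0.92) * ext[2],
             runif(1, 0.08, 0.92) * ext[3])
      if (k > 0 &&
          min(sqrt(colSums((t(pts[seq_len(k), , drop = FALSE]) - p)^2))) <
            spacing) next
      k <- k + 1
      pts[k, ] <- p
    }
    stopifnot(k == n)
    centres[[f]] <- pts
  }
  tracks <- do.call(rbind, lapply(seq_len(n_frames), function(f)
    data.frame(track_id = seq_len(n), fate = "parenchymal", frame = f,
               z_um = centres[[f]][, 1], y_um = centres[[f]][, 2],
               x_um = centres[[f]][, 3], contact = FALSE, calcium = 0)))
  geom <- list(shape = as.integer(shape), voxel_size = voxel_size,
               frame_interval = 35)
  class(geom) <- "scs_geometry"
  movie <- render_movie(geom, tracks,
                        channel_spec = list(cells = list(source = "cells",
                                                         amplitude = amplitude)),
                        blob_sigma = rep(sigma, 3), noise = noise,
                        n_frames = n_frames, seed = seed)
  list(movie = movie, centres = centres, tracks = tracks)
}

# match detections to planted centres within `tol` um; returns recall,
# precision and per-axis RMSE in voxel units
score_detections <- function(spots, centres, voxel_size, tol = 10) {
  tp <- 0; fp <- 0; err <- matrix(numeric(0), 0, 3)
  n_planted <- sum(vapply(centres, nrow, 0L))
  for (f in seq_along(centres)) {
    det <- spots[spots$frame == f, , drop = FALSE]
    truth <- centres[[f]]
    used <- rep(FALSE, nrow(truth))
    for (i in seq_len(nrow(det))) {
      d <- sqrt(colSums((t(truth) - c(det$z_um[i], det$y_um[i],
                                      det$x_um[i]))^2))
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= tol) {
        used[j] <- TRUE
        tp <- tp + 1
        err <- rbind(err, (c(det$z_um[i], det$y_um[i], det$x_um[i]) -
                             truth[j, ]) / voxel_size)
      } else fp <- fp + 1
    }
  }
  list(recall = tp / n_planted, precision = tp / max(tp + fp, 1),
       rmse_vox = sqrt(colMeans(err^2)))
}

# ---- exhaustive-enumeration oracles for the LAP stages --------------------

# minimum cost one-to-one partial matching: cost matrix (Inf = forbidden),
# unmatched rows and columns each pay `cap2`
enum_min_matching <- function(cost, cap2) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  if (n1 == 0 || n2 == 0) return((n1 + n2) * cap2)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n1) {
      total <- acc + cap2 * sum(!used)
      if (total < best) best <<- total
      return()
    }
    rec(i + 1, used, acc + cap2) # row i unmatched
    for (j in which(!used)) {
      if (is.finite(cost[i, j])) {
        used2 <- used; used2[j] <- TRUE
        rec(i + 1, used2, acc + cost[i, j])
      }
    }
  }
  rec(1, rep(FALSE, n2), 0)
  best
}

# objective value realized by a set of tracks for the frame-linking stage
linking_cost <- function(tracks, max_link_dist) {
  frames <- sort(unique(tracks$frame))
  total <- 0
  for (fi in seq_along(frames)[-1]) {
    if (frames[fi] != frames[fi - 1] + 1) next
    a <- tracks[tracks$frame == frames[fi - 1], , drop = FALSE]
    b <- tracks[tracks$frame == frames[fi], , drop = FALSE]
    linked <- intersect(a$track_id, b$track_id)
    nl <- 0
    for (id in linked) {
      pa <- a[a$track_id == id, c("z_um", "y_um", "x_um")]
      pb <- b[b$track_id == id, c("z_um", "y_um", "x_um")]
      total <- total + sum((as.numeric(pa) - as.numeric(pb))^2)
      nl <- nl + 1
    }
    total <- total + max_link_dist^2 * ((nrow(a) - nl) + (nrow(b) - nl))
  }
  total
}

# brute-force optimum of the frame-linking objective for a spot set
oracle_linking_cost <- function(spots, max_link_dist) {
  frames <- sort(unique(spots$frame))
  total <- 0
  for (fi in seq_along(frames)[-1]) {
    if (frames[fi] != frames[fi - 1] + 1) next
    a <- spots[spots$frame == frames[fi - 1], , drop = FALSE]
    b <- spots[spots$frame == frames[fi], , drop = FALSE]
    pa <- as.matrix(a[, c("z_um", "y_um", "x_um")])
    pb <- as.matrix(b[, c("z_um", "y_um", "x_um")])
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * pa %*% t(pb)
    d2[d2 > max_link_dist^2] <- Inf
    total <- total + enum_min_matching(d2, max_link_dist^2)
  }
  total
}

# gap-closing objective: every tracklet end and start either pays the
# cap^2 no-merge price or joins at squared distance; compares the realized
# solution against the enumerated optimum
gap_cost_pair <- function(tracklets, merged, max_gap_dist, max_gap_frames) {
  tl <- as.data.frame(tracklets)
  mg <- as.data.frame(merged)
  spot_key <- function(df) paste(df$frame, df$z_um, df$y_um, df$x_um)
  seg_of <- setNames(tl$track_id, spot_key(tl))
  ep <- scstrack:::track_endpoints(tl)
  nseg <- nrow(ep)
  realized <- 0; n_merged <- 0
  for (id in unique(mg$track_id)) {
    sub <- mg[mg$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    segs <- unname(seg_of[spot_key(sub)])
    joins <- which(segs[-1] != segs[-length(segs)])
    for (j in joins) {
      realized <- realized +
        sum((as.numeric(sub[j, c("z_um", "y_um", "x_um")]) -
               as.numeric(sub[j + 1, c("z_um", "y_um", "x_um")]))^2)
      n_merged <- n_merged + 1
    }
  }
  realized <- realized + max_gap_dist^2 * 2 * (nseg - n_merged)
  starts <- as.matrix(ep[, c("z0", "y0", "x0")])
  ends <- as.matrix(ep[, c("z1", "y1", "x1")])
  d2 <- pmax(outer(rowSums(ends^2), rowSums(starts^2), `+`) -
               2 * ends %*% t(starts), 0)
  dfr <- outer(ep$last_frame, ep$first_frame, function(a, b) b - a)
  allowed <- dfr >= 1 & dfr <= max_gap_frames & d2 <= max_gap_dist^2
  diag(allowed) <- FALSE
  cost <- ifelse(allowed, d2, Inf)
  oracle <- enum_min_matching(cost, max_gap_dist^2)
  list(realized = realized, oracle = oracle)
}

random_spot_instance <- function(seed, max_spots = 5, n_frames = 6,
                                 extent = 60) {
  set.seed(seed)
  rows <- list()
  for (f in seq_len(n_frames)) {
    n <- sample(0:max_spots, 1)
    if (!n) next
    rows[[length(rows) + 1]] <- data.frame(
      frame = f, z_um = runif(n, 0, extent / 2),
      y_um = runif(n, 0, extent), x_um = runif(n, 0, extent),
      quality = runif(n, 10, 30))
  }
  if (!length(rows)) return(data.frame(frame = integer(), z_um = numeric(),
                                       y_um = numeric(), x_um = numeric(),
                                       quality = numeric()))
  do.call(rbind, rows)
}
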