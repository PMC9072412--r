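#' @section Synthetic ground truth:
#' Tracks are stored in long format: one row per (track, frame) with columns
#' `track_id, fate, frame, z_um, y_um, x_um, contact, calcium`. The planted
#' fate is one of `entering`, `leaving`, `internal`, `parenchymal`; the
#' generator self-checks every realized trajectory against the same geometric
#' rules the classifier uses, so planted labels are exact by construction.
#' @name synthetic-tracks
NULL

GT_FATES <- c("entering", "leaving", "internal", "parenchymal")

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

rand_dir <- function() unit3(rnorm(3))

# rejection-sample a physical position satisfying `predicate`
sample_region <- function(geometry, predicate, max_tries = 4000) {
  ext <- movie_extent(geometry$shape, geometry$voxel_size)
  for (i in seq_len(max_tries)) {
    p <- runif(3) * ext
    if (predicate(p)) return(p)
  }
  stop("requested fate is geometrically impossible in the given scene",
       call. = FALSE)
}

# persistent random walk of fixed step length, confined by `inside`
confined_walk <- function(p0, n_steps, step, persistence, inside, ext) {
  out <- matrix(NA_real_, n_steps + 1, 3)
  out[1, ] <- p0
  dir <- rand_dir()
  p <- p0
  for (i in seq_len(n_steps)) {
    moved <- FALSE
    d <- dir
    for (try in 1:60) {
      q <- p + step * d
      if (all(q >= 0) && all(q <= ext) && inside(q)) {
        p <- q; dir <- d; moved <- TRUE; break
      }
      d <- unit3(persistence * dir + (1 - persistence) * rand_dir() +
                   0.3 * rand_dir())
      if (try > 20) d <- rand_dir()
    }
    if (!moved) dir <- rand_dir() # stuck: stand still this frame
    out[i + 1, ] <- p
  }
  out
}

# walk from p0 toward `target` with persistent noise; returns positions for
# frames 1..n_frames; once `arrived(p)` is TRUE, remaining frames are a
# confined walk inside `hold`
directed_walk <- function(p0, target, n_frames, step, persistence,
                          arrived, hold, ext) {
  pos <- matrix(NA_real_, n_frames, 3)
  pos[1, ] <- p0
  p <- p0
  dir <- unit3(target - p0)
  for (i in 2:n_frames) {
    remaining <- n_frames - i + 1
    to_t <- target - p
    dist <- sqrt(sum(to_t^2))
    if (arrived(p)) {
      rest <- confined_walk(p, n_frames - i + 1, step, persistence, hold, ext)
      pos[i:n_frames, ] <- rest[-1, , drop = FALSE]
      return(pos)
    }
    bias <- if (dist > 0.8 * step * remaining) 1 else 0.45
    d <- unit3((1 - bias) * (persistence * dir +
                               (1 - persistence) * rand_dir()) +
                 bias * unit3(to_t))
    q <- p + step * min(step, max(dist, 1e-6)) / step * d
    q <- pmin(pmax(q, 0), ext)
    dir <- unit3(q - p + 1e-9 * rand_dir())
    p <- q
    pos[i, ] <- p
  }
  pos
}

#' Place macrophage anchor points lining the sinus floor
#'
#' Samples lateral positions with a minimum spacing and drops each anchor
#' into the middle of the inner (floor) wall, emulating the CD169+
#' macrophages that line the subcapsular sinus floor.
#'
#' @param geometry an `scs_geometry`.
#' @param n number of anchors.
#' @param spacing minimum lateral spacing in um.
#' @param seed integer seed.
#' @return numeric matrix `n x 3` of `(z, y, x)` positions in um.
#' @export
macrophage_anchors <- function(geometry, n = 20, spacing = 15, seed = 1L) {
  with_seed(seed + 101L, {
    ext <- movie_extent(geometry$shape, geometry$voxel_size)
    tt <- geometry$thickness
    depth <- tt["outer"] + tt["lumen"] + tt["inner"] / 2
    pts <- matrix(NA_real_, n, 3)
    k <- 0; tries <- 0
    while (k < n && tries < 20000) {
      tries <- tries + 1
      yx <- runif(2) * ext[2:3]
      if (k > 0) {
        dd <- sqrt(colSums((t(pts[seq_len(k), 2:3, drop = FALSE]) - yx)^2))
        if (min(dd) < spacing) next
      }
      k <- k + 1
      p <- c(0, yx)
      p[1] <- scs_depth(geometry, c(0, yx)) * -1 + depth # surface + depth
      pts[k, ] <- p
    }
    if (k < n) stop("could not place the requested number of anchors")
    colnames(pts) <- c("z_um", "y_um", "x_um")
    pts
  })
}

#' Simulate cell trajectories with planted sinus-interaction fates
#'
#' Generates persistent-random-walk trajectories whose endpoint geometry
#' guarantees a requested fate with respect to the sinus shell: `entering`
#' (starts >= `margin` um into the parenchyma, ends inside the sinus),
#' `leaving` (the converse), `internal` (never leaves the shell) and
#' `parenchymal` (never touches it). Every realized track is re-classified
#' with [classify_track()] against the true geometry and re-sampled on
#' disagreement, so the returned fates are exact ground truth.
#'
#' @param geometry an `scs_geometry`.
#' @param n_per_fate named integer vector with any of
#'   `entering, leaving, internal, parenchymal`.
#' @param motion list with `speed` (um/min), `persistence` (0-1 directional
#'   memory) and `dwell_frames` (frames a contacting cell is held at a
#'   macrophage anchor).
#' @param n_frames number of time points (>= 5).
#' @param margin classification margin in um (the "at least 5 um" rule).
#' @param contact optional list enabling macrophage contacts:
#'   `anchors` (matrix from [macrophage_anchors()]), `n_contact` (number of
#'   internal cells pinned to an anchor), `clear_dist` (um; non-contacting
#'   cells are kept at least this far from every anchor).
#' @param min_spacing minimum distance (um) between starting positions.
#' @param seed integer seed.
#' @return a `data.frame` of ground-truth tracks in long format (see
#'   *Synthetic ground truth*), with `calcium` = 1 during contact frames.
#' @export
simulate_tracks <- function(geometry,
                            n_per_fate = c(entering = 5, leaving = 5,
                                           internal = 5, parenchymal = 5),
                            motion = list(speed = 6, persistence = 0.6,
                                          dwell_frames = 4),
                            n_frames = 32L,
                            margin = 5,
                            contact = NULL,
                            min_spacing = 0,
                            seed = 1L) {
  if (n_frames < 5) stop("n_frames must be >= 5")
  speed <- motion$speed %||% 6
  if (speed < 0) stop("speed must be non-negative")
  persistence <- motion$persistence %||% 0.6
  dwell <- motion$dwell_frames %||% 4
  counts <- setNames(integer(4), GT_FATES)
  counts[names(n_per_fate)] <- as.integer(n_per_fate)
  if (any(is.na(counts)) || any(counts < 0) ||
      !all(names(n_per_fate) %in% GT_FATES))
    stop("n_per_fate must use names entering/leaving/internal/parenchymal")

  ext <- movie_extent(geometry$shape, geometry$voxel_size)
  tt <- geometry$thickness
  total <- sum(tt)
  step <- speed * geometry$frame_interval / 60
  # cells travel mid-sinus rather than hugging the endothelium; the buffer
  # also keeps endpoints clear of voxel-rounding at the mask boundary
  buf <- max(geometry$voxel_size) / 2 + 2
  inside_safe <- function(p) {
    d <- scs_depth(geometry, p)
    d >= buf && d <= total - buf
  }
  paren_safe <- function(p) parenchymal_depth(geometry, p) >= buf
  paren_deep <- function(p) parenchymal_depth(geometry, p) >= margin + 4
  paren_exit <- function(p) parenchymal_depth(geometry, p) >= margin + 1.5

  # single-frame region series from the true geometry, used for the
  # generator-side self check of every realized fate
  regions <- region_mask_from_geometry(geometry)

  clear_of_anchors <- function(p) {
    if (is.null(contact)) return(TRUE)
    cd <- contact$clear_dist %||% 25
    min(sqrt(colSums((t(contact$anchors) - p)^2))) >= cd
  }

  expected_label <- c(entering = "entering", leaving = "leaving",
                      internal = "internal", parenchymal = "non_interacting")

  with_seed(seed, {
    rows <- list()
    starts <- matrix(numeric(0), 0, 3)
    tid <- 0L
    contact_left <- if (is.null(contact)) 0L else as.integer(contact$n_contact)
    anchor_pool <- if (!is.null(contact)) sample(nrow(contact$anchors))
    for (fate in GT_FATES) {
      for (i in seq_len(counts[[fate]])) {
        tid <- tid + 1L
        this_contact <- fate == "internal" && contact_left > 0L
        anchor <- NULL
        if (this_contact) {
          contact_left <- contact_left - 1L
          if (!length(anchor_pool)) anchor_pool <- sample(nrow(contact$anchors))
          anchor <- contact$anchors[anchor_pool[1], ]
          anchor_pool <- anchor_pool[-1]
        }
        ok <- FALSE
        for (attempt in 1:25) {
          res <- simulate_one_track(
            geometry, fate, n_frames, step, persistence, ext,
            inside_safe, paren_safe, paren_deep, paren_exit,
            this_contact, anchor, dwell, clear_of_anchors,
            starts, min_spacing)
          cls <- classify_track(
            data.frame(frame = seq_len(n_frames), z_um = res$pos[, 1],
                       y_um = res$pos[, 2], x_um = res$pos[, 3]),
            regions, min_outside_dist = margin)
          if (cls$label == expected_label[[fate]]) { ok <- TRUE; break }
        }
        if (!ok)
          stop(sprintf("could not realize a '%s' track in this scene", fate))
        starts <- rbind(starts, res$pos[1, , drop = FALSE])
        rows[[tid]] <- data.frame(
          track_id = tid, fate = fate, frame = seq_len(n_frames),
          z_um = res$pos[, 1], y_um = res$pos[, 2], x_um = res$pos[, 3],
          contact = res$contact, calcium = as.numeric(res$contact))
      }
    }
    gt <- do.call(rbind, rows)
    if (is.null(gt))
      gt <- data.frame(track_id = integer(), fate = character(),
                       frame = integer(), z_um = numeric(), y_um = numeric(),
                       x_um = numeric(), contact = logical(),
                       calcium = numeric())
    class(gt) <- c("scs_ground_truth", "data.frame")
    gt
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_one_track <- function(geometry, fate, n_frames, step, persistence,
                               ext, inside_safe, paren_safe, paren_deep,
                               paren_exit, this_contact, anchor, dwell,
                               clear_of_anchors, starts, min_spacing) {
  spaced <- function(p) {
    nrow(starts) == 0 || min_spacing <= 0 ||
      min(sqrt(colSums((t(starts) - p)^2))) >= min_spacing
  }
  tt <- geometry$thickness
  lumen_mid <- function(yx) {
    s <- -scs_depth(geometry, c(0, yx)) # surface height at (y,x)
    c(s + tt["outer"] + tt["lumen"] / 2, yx)
  }
  contact_frames <- rep(FALSE, n_frames)
  if (fate == "internal") {
    if (this_contact) {
      a <- anchor
      pin <- lumen_mid(a[2:3] + runif(2, -1.5, 1.5))
      pin[1] <- pin[1] + tt["lumen"] / 2 - 1.5 # just above the floor
      f0 <- sample(seq(2, max(2, n_frames - dwell)), 1)
      win <- f0:min(n_frames, f0 + dwell - 1)
      pin <- pmin(pmax(pin, 0), ext)
      pos <- matrix(NA_real_, n_frames, 3)
      pos[win, ] <- matrix(rep(pin, length(win)), ncol = 3, byrow = TRUE) +
        matrix(runif(3 * length(win), -0.3, 0.3), ncol = 3)
      pos[win, ] <- pmin(pmax(pos[win, , drop = FALSE], 0),
                         matrix(ext, length(win), 3, byrow = TRUE))
      # walk outward from both ends of the pinned window
      if (win[1] > 1) {
        back <- confined_walk(pos[win[1], ], win[1] - 1, step, persistence,
                              inside_safe, ext)
        pos[rev(seq_len(win[1] - 1)), ] <- back[-1, , drop = FALSE]
      }
      last <- win[length(win)]
      if (last < n_frames) {
        fwd <- confined_walk(pos[last, ], n_frames - last, step, persistence,
                             inside_safe, ext)
        pos[(last + 1):n_frames, ] <- fwd[-1, , drop = FALSE]
      }
      contact_frames[win] <- TRUE
    } else {
      start_ok <- function(p) inside_safe(p) && spaced(p) && clear_of_anchors(p)
      p0 <- sample_region(geometry, start_ok)
      keep <- function(p) inside_safe(p) && clear_of_anchors(p)
      pos <- confined_walk(p0, n_frames - 1, step, persistence, keep, ext)
    }
  } else if (fate == "parenchymal") {
    start_ok <- function(p) paren_safe(p) && spaced(p)
    p0 <- sample_region(geometry, start_ok)
    pos <- confined_walk(p0, n_frames - 1, step, persistence, paren_safe, ext)
  } else if (fate == "entering") {
    start_ok <- function(p) paren_deep(p) && spaced(p)
    p0 <- sample_region(geometry, start_ok)
    target <- lumen_mid(p0[2:3] + runif(2, -8, 8))
    pos <- directed_walk(p0, target, n_frames, step, persistence,
                         arrived = inside_safe, hold = inside_safe, ext = ext)
  } else { # leaving
    start_ok <- function(p) inside_safe(p) && spaced(p)
    p0 <- sample_region(geometry, start_ok)
    target_yx <- p0[2:3] + runif(2, -8, 8)
    s <- -scs_depth(geometry, c(0, target_yx))
    target <- c(min(s + sum(tt) + 5 + 4 + 2, ext[1]), target_yx)
    pos <- directed_walk(p0, target, n_frames, step, persistence,
                         arrived = paren_exit, hold = paren_exit, ext = ext)
  }
  list(pos = pos, contact = contact_frames)
}

#' Noise model for synthetic rendering
#'
#' @param photon_scale expected photons per intensity unit (Poisson shot
#'   noise); larger values mean less noise.
#' @param read_sigma Gaussian read-noise standard deviation, intensity units.
#' @param background_level constant background, intensity units.
#' @return a `noise_model` list.
#' @export
noise_model <- function(photon_scale = 1, read_sigma = 2,
                        background_level = 5) {
  stopifnot_scalar(photon_scale, "photon_scale")
  if (read_sigma < 0) stop("read_sigma must be >= 0")
  if (background_level < 0) stop("background_level must be >= 0")
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 background_level = background_level),
            class = "noise_model")
}

add_blob <- function(vol, centre, sigma, amplitude, voxel_size) {
  shape <- dim(vol)
  lo <- pmax(1L, floor((centre - 4 * sigma) / voxel_size) + 1L)
  hi <- pmin(shape, ceiling((centre + 4 * sigma) / voxel_size) + 1L)
  if (any(lo > hi)) return(vol)
  gz <- exp(-((seq(lo[1], hi[1]) - 1) * voxel_size[1] - centre[1])^2 /
              (2 * sigma[1]^2))
  gy <- exp(-((seq(lo[2], hi[2]) - 1) * voxel_size[2] - centre[2])^2 /
              (2 * sigma[2]^2))
  gx <- exp(-((seq(lo[3], hi[3]) - 1) * voxel_size[3] - centre[3])^2 /
              (2 * sigma[3]^2))
  blob <- amplitude * (gz %o% gy %o% gx)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + blob
  vol
}

#' Render a synthetic multi-channel movie from ground-truth tracks
#'
#' Cells are rendered as anisotropic Gaussian blobs at their ground-truth
#' positions; optional channels add CD169-like macrophage blobs lining the
#' sinus floor and a FRET donor/acceptor pair whose acceptor fraction follows
#' the per-frame calcium state (`r = r_min + (r_max - r_min) * calcium`).
#' Poisson shot noise and Gaussian read noise are applied last.
#'
#' @param geometry an `scs_geometry`.
#' @param tracks ground-truth tracks from [simulate_tracks()].
#' @param channel_spec named list; each element is a list with `source`
#'   (one of `"cells"`, `"macrophages"`, `"fret_donor"`, `"fret_acceptor"`),
#'   `amplitude`, and optionally `sigma` (um triple).
#' @param blob_sigma default Gaussian sigma triple in um.
#' @param anchors macrophage anchor matrix (required for a macrophage
#'   channel).
#' @param fret list with `r_min`, `r_max`: acceptor fraction at calcium 0 / 1.
#' @param noise a [noise_model()], or `NULL` to render noiselessly.
#' @param n_frames number of frames; defaults to the track range.
#' @param seed integer seed (noise only).
#' @return an [scs_movie()].
#' @export
render_movie <- function(geometry, tracks,
                         channel_spec = list(cells = list(source = "cells",
                                                          amplitude = 50)),
                         blob_sigma = rep(10 / sqrt(3), 3),
                         anchors = NULL,
                         fret = list(r_min = 0.2, r_max = 0.7),
                         noise = noise_model(),
                         n_frames = NULL,
                         seed = 1L) {
  shape <- geometry$shape
  vs <- geometry$voxel_size
  ext <- movie_extent(shape, vs)
  if (nrow(tracks) > 0) {
    p <- as.matrix(tracks[, c("z_um", "y_um", "x_um")])
    if (any(p < -1e-9) || any(t(p) > ext + 1e-9))
      stop("track positions outside the volume bounds")
  }
  if (is.null(n_frames))
    n_frames <- if (nrow(tracks)) max(tracks$frame) else 1L
  nch <- length(channel_spec)
  if (nch == 0) stop("channel_spec must contain at least one channel")
  srcs <- vapply(channel_spec, function(s) s$source, "")
  if (!any(srcs %in% c("cells", "fret_donor", "fret_acceptor")))
    stop("channel_spec must include a cell channel")
  if ("macrophages" %in% srcs && is.null(anchors))
    stop("a macrophage channel needs `anchors`")
  bg <- if (is.null(noise)) 0 else noise$background_level
  dat <- array(0, dim = c(n_frames, nch, shape))
  # static macrophage layer, rendered once
  macro_layer <- NULL
  if ("macrophages" %in% srcs) {
    macro_layer <- array(0, dim = shape)
    mi <- which(srcs == "macrophages")[1]
    msig <- channel_spec[[mi]]$sigma %||% (blob_sigma * 1.2)
    for (k in seq_len(nrow(anchors)))
      macro_layer <- add_blob(macro_layer, anchors[k, ], msig,
                              channel_spec[[mi]]$amplitude, vs)
  }
  for (f in seq_len(n_frames)) {
    sub <- tracks[tracks$frame == f, , drop = FALSE]
    for (ci in seq_len(nch)) {
      sp <- channel_spec[[ci]]
      sig <- sp$sigma %||% blob_sigma
      vol <- array(bg, dim = shape)
      if (sp$source == "macrophages") {
        vol <- vol + macro_layer
      } else if (nrow(sub) > 0) {
        for (r in seq_len(nrow(sub))) {
          amp <- sp$amplitude
          if (sp$source %in% c("fret_donor", "fret_acceptor")) {
            rr <- fret$r_min + (fret$r_max - fret$r_min) * sub$calcium[r]
            amp <- amp * if (sp$source == "fret_acceptor") rr else (1 - rr)
          }
          vol <- add_blob(vol, c(sub$z_um[r], sub$y_um[r], sub$x_um[r]),
                          sig, amp, vs)
        }
      }
      dat[f, ci, , , ] <- vol
    }
  }
  if (!is.null(noise)) {
    dat <- with_seed(seed + 977L, {
      n <- length(dat)
      counts <- rpois(n, noise$photon_scale * pmax(dat, 0)) /
        noise$photon_scale
      if (noise$read_sigma > 0) counts <- counts + rnorm(n, 0, noise$read_sigma)
      array(counts, dim = dim(dat))
    })
  }
  scs_movie(dat, vs, geometry$frame_interval, names(channel_spec))
}

#' Build 4-class probability maps from the true geometry
#'
#' Produces per-frame one-hot probability maps from the geometry's class
#' volume, optionally corrupted with symmetric label noise (each voxel's
#' label is replaced by a uniformly random *other* class with probability
#' `label_noise`, independently per frame) and optionally block-majority
#' down-sampled in xy, emulating the output of an external pixel classifier.
#'
#' @param geometry an `scs_geometry`.
#' @param n_frames number of frames.
#' @param label_noise per-voxel label-flip probability in `[0, 1)`.
#' @param factor integer xy down-sampling factor (1 = none).
#' @param seed integer seed.
#' @return an `scs_probmaps` object: `probs` array
#'   `(t, 4, z, y, x)` with channels ordered
#'   `background, inner_wall, lumen, outer_wall`; `voxel_size`; `factor`.
#' @export
probability_maps_from_geometry <- function(geometry, n_frames = 1L,
                                           label_noise = 0, factor = 1L,
                                           seed = 1L) {
  cls <- geometry$class_volume
  vs <- geometry$voxel_size
  if (factor > 1) {
    cls <- block_majority_labels(cls, as.integer(factor))
    vs <- vs * c(1, factor, factor)
  }
  shape <- dim(cls)
  probs <- array(0, dim = c(n_frames, 4, shape))
  with_seed(seed + 553L, {
    for (f in seq_len(n_frames)) {
      lab <- cls
      if (label_noise > 0) {
        flip <- which(runif(length(lab)) < label_noise)
        if (length(flip)) {
          # uniformly one of the three *other* classes
          lab[flip] <- (lab[flip] + sample(1:3, length(flip),
                                           replace = TRUE)) %% 4L
        }
      }
      for (k in 0:3) probs[f, k + 1, , , ] <- as.numeric(lab == k)
    }
  })
  structure(list(probs = probs, voxel_size = vs, factor = as.integer(factor),
                 full_shape = geometry$shape,
                 full_voxel_size = geometry$voxel_size),
            class = "scs_probmaps")
}

# majority label in each (factor x factor) xy block (ties -> smallest code)
block_majority_labels <- function(cls, factor) {
  d <- dim(cls)
  ny <- d[2] %/% factor; nx <- d[3] %/% factor
  out <- array(0L, dim = c(d[1], ny, nx))
  for (iz in seq_len(d[1])) {
    sl <- cls[iz, seq_len(ny * factor), seq_len(nx * factor), drop = TRUE]
    counts <- vapply(0:3, function(k) {
      m <- matrix(as.numeric(sl == k), ny * factor, nx * factor)
      block_mean_2d(m, factor)
    }, matrix(0, ny, nx))
    out[iz, , ] <- apply(counts, c(1, 2), which.max) - 1L
  }
  out
}

block_mean_2d <- function(m, factor) {
  ny <- nrow(m) %/% factor; nx <- ncol(m) %/% factor
  m <- m[seq_len(ny * factor), seq_len(nx * factor), drop = FALSE]
  a <- array(m, dim = c(factor, ny, factor, nx))
  apply(a, c(2, 4), mean)
}

#' Voxelized cell masks from ground-truth tracks
#'
#' Labels an ellipsoid of radius `radius` um around every track position;
#' where two cells overlap, the nearer centre wins.
#'
#' @param tracks ground-truth tracks (long format).
#' @param shape volume voxel counts `(z, y, x)`.
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param radius cell radius in um.
#' @param n_frames number of frames to label.
#' @return integer array `(t, z, y, x)`; 0 = background, otherwise track_id.
#' @export
cell_masks_from_tracks <- function(tracks, shape, voxel_size, radius = 6,
                                   n_frames = max(tracks$frame)) {
  masks <- array(0L, dim = c(n_frames, shape))
  dist <- array(Inf, dim = shape)
  for (f in seq_len(n_frames)) {
    sub <- tracks[tracks$frame == f, , drop = FALSE]
    if (!nrow(sub)) next
    lab <- array(0L, dim = shape)
    dist[] <- Inf
    for (r in seq_len(nrow(sub))) {
      ctr <- c(sub$z_um[r], sub$y_um[r], sub$x_um[r])
      lo <- pmax(1L, floor((ctr - radius) / voxel_size) + 1L)
      hi <- pmin(shape, ceiling((ctr + radius) / voxel_size) + 1L)
      zz <- (seq(lo[1], hi[1]) - 1) * voxel_size[1] - ctr[1]
      yy <- (seq(lo[2], hi[2]) - 1) * voxel_size[2] - ctr[2]
      xx <- (seq(lo[3], hi[3]) - 1) * voxel_size[3] - ctr[3]
      d2 <- outer(zz^2, outer(yy^2, xx^2, `+`), `+`)
      sel <- d2 <= radius^2
      blk <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      dbl <- dist[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
      win <- sel & d2 < dbl
      blk[win] <- sub$track_id[r]
      dbl[win] <- d2[win]
      lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
      dist[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- dbl
    }
    masks[f, , , ] <- lab
  }
  masks
}
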