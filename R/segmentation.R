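#' Down-sample a movie or probability-map series in xy
#'
#' Block-mean pooling by an integer factor in y and x (trailing rows/columns
#' that do not fill a block are truncated). Voxel sizes are scaled
#' accordingly. The paper-style pipeline classifies pixels at 4x reduced xy
#' resolution.
#'
#' @param x an [scs_movie()] or `scs_probmaps`.
#' @param factor integer >= 1; 1 is the identity.
#' @return the same type at reduced xy resolution.
#' @export
downsample_xy <- function(x, factor = 4L) {
  if (factor < 1 || factor != round(factor)) stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  UseMethod("downsample_xy")
}

#' @export
downsample_xy.scs_movie <- function(x, factor = 4L) {
  factor <- as.integer(factor)
  d <- dim(x$data)
  ny <- d[4] %/% factor; nx <- d[5] %/% factor
  out <- array(0, dim = c(d[1], d[2], d[3], ny, nx))
  for (f in seq_len(d[1]))
    for (ci in seq_len(d[2]))
      for (iz in seq_len(d[3]))
        out[f, ci, iz, , ] <-
          block_mean_2d(matrix(x$data[f, ci, iz, , ], d[4], d[5]), factor)
  scs_movie(out, x$voxel_size * c(1, factor, factor), x$frame_interval,
            x$channels)
}

#' @export
downsample_xy.scs_probmaps <- function(x, factor = 4L) {
  factor <- as.integer(factor)
  d <- dim(x$probs)
  ny <- d[4] %/% factor; nx <- d[5] %/% factor
  out <- array(0, dim = c(d[1], d[2], d[3], ny, nx))
  for (f in seq_len(d[1]))
    for (ci in seq_len(d[2]))
      for (iz in seq_len(d[3]))
        out[f, ci, iz, , ] <-
          block_mean_2d(matrix(x$probs[f, ci, iz, , ], d[4], d[5]), factor)
  structure(list(probs = out, voxel_size = x$voxel_size * c(1, factor, factor),
                 factor = x$factor * factor, full_shape = x$full_shape,
                 full_voxel_size = x$full_voxel_size),
            class = "scs_probmaps")
}

#' Temporally smooth probability maps
#'
#' Per-voxel, per-class rolling mean over a centred window of frames.
#' Windows are shrunk (not padded) at the sequence ends, so probabilities
#' still sum to one everywhere. A 3-frame window suppresses classifier
#' noise while following slow sinus drift.
#'
#' @param series an `scs_probmaps`.
#' @param window odd window length in frames (1 = identity).
#' @return a smoothed `scs_probmaps`.
#' @export
smooth_probability_maps <- function(series, window = 3L) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  nt <- dim(series$probs)[1]
  if (window > nt) stop("window exceeds the number of frames")
  if (window == 1L) return(series)
  h <- (window - 1L) / 2L
  m <- matrix(series$probs, nrow = nt) # t is the fastest-varying dim
  cs <- apply(m, 2, cumsum)
  if (nt == 1) cs <- matrix(cs, nrow = 1)
  lo <- pmax(1L, seq_len(nt) - h); hi <- pmin(nt, seq_len(nt) + h)
  sm <- (cs[hi, , drop = FALSE] -
           rbind(0, cs)[lo, , drop = FALSE]) / (hi - lo + 1)
  out <- series
  out$probs <- array(sm, dim = dim(series$probs))
  out
}

#' Assign each voxel its maximum-probability class
#'
#' Per-voxel argmax over the four classes; exact ties are broken by the
#' fixed priority inner_wall > lumen > outer_wall > background.
#'
#' @param series an `scs_probmaps`.
#' @return an `scs_labels` object: `labels` array `(t, z, y, x)` with codes
#'   0 background / 1 inner wall / 2 lumen / 3 outer wall.
#' @export
assign_classes <- function(series) {
  p <- series$probs
  if (anyNA(p)) stop("NaN probabilities")
  d <- dim(p)
  # channel order in probs: background, inner, lumen, outer (codes 0..3);
  # visit in tie priority order so earlier classes win exact ties
  prio_ch <- c(2L, 3L, 4L, 1L) # inner, lumen, outer, background
  prio_code <- c(1L, 2L, 3L, 0L)
  best <- array(p[, prio_ch[1], , , ], dim = d[c(1, 3, 4, 5)])
  lab <- array(prio_code[1], dim = d[c(1, 3, 4, 5)])
  for (k in 2:4) {
    pk <- array(p[, prio_ch[k], , , ], dim = d[c(1, 3, 4, 5)])
    upd <- pk > best
    lab[upd] <- prio_code[k]
    best[upd] <- pk[upd]
  }
  structure(list(labels = lab, voxel_size = series$voxel_size,
                 factor = series$factor %||% 1L,
                 full_shape = series$full_shape %||% dim(lab)[2:4],
                 full_voxel_size = series$full_voxel_size %||%
                   series$voxel_size),
            class = "scs_labels")
}

# nearest-neighbour upsample of one 3D volume in xy by an integer factor,
# padded/cropped to `target` (z, y, x)
upsample_xy_nn <- function(vol, factor, target) {
  if (factor == 1L) return(vol)
  d <- dim(vol)
  out <- vol[, rep(seq_len(d[2]), each = factor),
             rep(seq_len(d[3]), each = factor), drop = FALSE]
  # truncated blocks at the far edge: extend with the last row/column
  oy <- dim(out)[2]; ox <- dim(out)[3]
  if (oy < target[2])
    out <- out[, c(seq_len(oy), rep(oy, target[2] - oy)), , drop = FALSE]
  if (ox < target[3])
    out <- out[, , c(seq_len(ox), rep(ox, target[3] - ox)), drop = FALSE]
  out[, seq_len(target[2]), seq_len(target[3]), drop = FALSE]
}

largest_component <- function(mask) {
  lab <- .label3d(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  if (n == 1L) return(lab == 1L)
  sizes <- tabulate(lab, n)
  # component labels are ordered by smallest linear index, so on a size tie
  # which.max keeps the component with the smallest minimum index
  lab == which.max(sizes)
}

fill_holes_3d <- function(mask) {
  bg <- !mask
  lab <- .label3d(bg)
  if (max(lab) <= 1L) return(mask)
  d <- dim(mask)
  border <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  hole <- bg & !(lab %in% border)
  dim(hole) <- d
  mask | hole
}

#' Build the sinus mask, distance field and sidedness labels
#'
#' Implements the post-processing chain applied to argmax class labels,
#' per frame: (1) for each non-background class keep only the largest
#' 26-connected component; (2) merge inner wall, lumen and outer wall into
#' one binary sinus mask; (3) fill fully enclosed 3D holes; (4) if the
#' labels were produced at reduced xy resolution, upsample the mask by
#' nearest neighbour to the full grid; (5) compute the anisotropic Euclidean
#' distance (um) from every voxel to the mask; (6) label every non-mask
#' voxel `parenchymal` (beneath the floor) or `extranodal` (beyond the
#' ceiling) according to whether its nearest inner-wall voxel is closer than
#' its nearest outer-wall voxel.
#'
#' @param labels an `scs_labels` from [assign_classes()].
#' @return an `scs_regions` object: `mask` logical `(t, z, y, x)` at full
#'   resolution, `distance` (um, 0 on the mask), `sidedness` (0 mask /
#'   1 parenchymal / 2 extranodal), `voxel_size`, `static` flag.
#' @export
build_scs_mask <- function(labels) {
  lab <- labels$labels
  nt <- dim(lab)[1]
  shape_ds <- dim(lab)[2:4]
  factor <- labels$factor %||% 1L
  target <- if (factor > 1L) labels$full_shape else shape_ds
  vs <- if (factor > 1L) labels$full_voxel_size else labels$voxel_size
  mask <- array(FALSE, dim = c(nt, target))
  dist <- array(0, dim = c(nt, target))
  side <- array(0L, dim = c(nt, target))
  for (f in seq_len(nt)) {
    lf <- array(lab[f, , , ], dim = shape_ds)
    if (!any(lf != SCS_CLASSES[["background"]]))
      stop(sprintf("frame %d is unsegmentable: no sinus-class voxels", f))
    keep <- list()
    for (cl in c("inner_wall", "lumen", "outer_wall")) {
      cm <- lf == SCS_CLASSES[[cl]]
      keep[[cl]] <- if (any(cm)) largest_component(cm) else cm
    }
    m <- keep$inner_wall | keep$lumen | keep$outer_wall
    m <- fill_holes_3d(m)
    if (factor > 1L) {
      m <- upsample_xy_nn(m, factor, target)
      keep <- lapply(keep, upsample_xy_nn, factor = factor, target = target)
    }
    storage.mode(m) <- "logical"
    d <- .edt3d(m, vs)
    inner <- keep$inner_wall & m
    outer <- keep$outer_wall & m
    di <- if (any(inner)) .edt3d(inner, vs) else array(Inf, dim = target)
    do <- if (any(outer)) .edt3d(outer, vs) else array(Inf, dim = target)
    s <- array(0L, dim = target)
    s[!m] <- ifelse(di[!m] <= do[!m], 1L, 2L)
    mask[f, , , ] <- m
    dist[f, , , ] <- d
    side[f, , , ] <- s
  }
  structure(list(mask = mask, distance = dist, sidedness = side,
                 voxel_size = vs, static = nt == 1L),
            class = "scs_regions")
}

#' Region series straight from a synthetic geometry
#'
#' Builds the same `scs_regions` structure as [build_scs_mask()] but from
#' the generator's true class volume (a single static frame). Used for
#' ground-truth classification and generator self-checks.
#'
#' @param geometry an `scs_geometry`.
#' @return an `scs_regions` with one static frame.
#' @export
region_mask_from_geometry <- function(geometry) {
  maps <- probability_maps_from_geometry(geometry, n_frames = 1L)
  build_scs_mask(assign_classes(maps))
}

# ---- optional built-in pixel classifier -----------------------------------

# analytic eigenvalues of symmetric 3x3 matrices, vectorized;
# returns n x 3 matrix, sorted decreasing
sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  r <- rep(0, length(a11))
  nz <- p > 1e-12
  if (any(nz)) {
    b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
    b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
  }
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3)
}

gaussian_kernel_1d <- function(sigma_vox) {
  h <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

smooth3d <- function(vol, sigma_vox) {
  for (ax in 0:2)
    vol <- .conv3d_axis(vol, gaussian_kernel_1d(sigma_vox[ax + 1]), ax)
  vol
}

second_diff <- function(vol, axis, h) {
  .conv3d_axis(vol, c(1, -2, 1) / h^2, axis)
}

central_diff <- function(vol, axis, h) {
  .conv3d_axis(vol, c(1, 0, -1) / (2 * h), axis)
}

# feature bank at one scale: smoothed intensity, gradient magnitude,
# Laplacian, and the three Hessian eigenvalues (texture), physical units
scale_features <- function(vol, scale_um, voxel_size) {
  sv <- pmax(scale_um / voxel_size, 0.3)
  s <- smooth3d(vol, sv)
  gz <- central_diff(s, 0, voxel_size[1])
  gy <- central_diff(s, 1, voxel_size[2])
  gx <- central_diff(s, 2, voxel_size[3])
  hzz <- second_diff(s, 0, voxel_size[1])
  hyy <- second_diff(s, 1, voxel_size[2])
  hxx <- second_diff(s, 2, voxel_size[3])
  hzy <- central_diff(gz, 1, voxel_size[2])
  hzx <- central_diff(gz, 2, voxel_size[3])
  hyx <- central_diff(gy, 2, voxel_size[3])
  ev <- sym3_eigenvalues(as.numeric(hzz), as.numeric(hyy), as.numeric(hxx),
                         as.numeric(hzy), as.numeric(hzx), as.numeric(hyx))
  cbind(smooth = as.numeric(s),
        gradmag = sqrt(as.numeric(gz)^2 + as.numeric(gy)^2 +
                         as.numeric(gx)^2),
        laplacian = as.numeric(hzz + hyy + hxx),
        hess1 = ev[, 1], hess2 = ev[, 2], hess3 = ev[, 3])
}

feature_bank <- function(vol, scales, voxel_size) {
  feats <- cbind(intensity = as.numeric(vol))
  for (s in scales) {
    f <- scale_features(vol, s, voxel_size)
    colnames(f) <- paste0(colnames(f), "_s", s)
    feats <- cbind(feats, f)
  }
  feats
}

#' Train the built-in random-forest pixel classifier
#'
#' A self-contained stand-in for an external interactive pixel classifier:
#' a random forest over a multi-scale feature bank (Gaussian-smoothed
#' intensity, gradient magnitude, Laplacian and Hessian-eigenvalue texture
#' at each scale) mapping sparse voxel annotations to 4-class probabilities.
#'
#' @param frames list of 3D intensity volumes (one per annotated time point,
#'   at least 3).
#' @param annotations data.frame with columns `frame, z, y, x` (1-based
#'   voxel indices) and `class` (codes 0-3); every class must be annotated.
#' @param scales numeric vector of feature scales in um (non-empty).
#' @param voxel_size um per voxel `(z, y, x)`.
#' @param n_trees forest size.
#' @return an `scs_pixel_classifier` model.
#' @export
train_pixel_classifier <- function(frames, annotations, scales,
                                   voxel_size, n_trees = 100L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("the optional pixel classifier needs the randomForest package")
  if (length(scales) == 0) stop("`scales` must be non-empty")
  if (length(frames) < 3)
    stop("at least 3 annotated frames are required for training")
  cls <- sort(unique(annotations$class))
  if (!all(SCS_CLASSES %in% cls))
    stop("every class (0-3) must have at least one annotation")
  xs <- list(); ys <- list()
  for (fi in seq_along(frames)) {
    ann <- annotations[annotations$frame == fi, , drop = FALSE]
    if (!nrow(ann)) next
    feats <- feature_bank(frames[[fi]], scales, voxel_size)
    shape <- dim(frames[[fi]])
    idx <- ann$z + shape[1] * (ann$y - 1) + shape[1] * shape[2] * (ann$x - 1)
    xs[[fi]] <- feats[idx, , drop = FALSE]
    ys[[fi]] <- ann$class
  }
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = SCS_CLASSES)
  model <- randomForest::randomForest(x, y, ntree = n_trees)
  structure(list(model = model, scales = scales, voxel_size = voxel_size),
            class = "scs_pixel_classifier")
}

#' Predict 4-class probability maps with the built-in classifier
#'
#' @param classifier an `scs_pixel_classifier`.
#' @param frames list of 3D intensity volumes (time points).
#' @return an `scs_probmaps` series.
#' @export
predict_probability_maps <- function(classifier, frames) {
  shape <- dim(frames[[1]])
  nt <- length(frames)
  probs <- array(0, dim = c(nt, 4, shape))
  for (fi in seq_len(nt)) {
    feats <- feature_bank(frames[[fi]], classifier$scales,
                          classifier$voxel_size)
    p <- stats::predict(classifier$model, feats, type = "prob")
    for (k in 0:3)
      probs[fi, k + 1, , , ] <- array(p[, as.character(k)], dim = shape)
  }
  structure(list(probs = probs, voxel_size = classifier$voxel_size,
                 factor = 1L, full_shape = shape,
                 full_voxel_size = classifier$voxel_size),
            class = "scs_probmaps")
}
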