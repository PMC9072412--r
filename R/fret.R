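#' Linear spectral unmixing
#'
#' Removes channel crosstalk by inverting a mixing matrix per voxel:
#' `true = M^-1 %*% observed`, clipped at zero. With `M = I` this is the
#' identity. Used to strip red antibody-staining bleed-through out of the
#' citrine (acceptor) channel before computing FRET ratios.
#'
#' @param movie an [scs_movie()] whose channel count equals `nrow(M)`.
#' @param model an [unmixing_model()].
#' @return an [scs_movie()] of true-channel estimates.
#' @export
unmix <- function(movie, model) {
  M <- model$M
  d <- dim(movie$data)
  if (d[2] != nrow(M))
    stop("observed channel count must equal nrow(M)")
  Minv <- solve(M)
  # voxels x channels
  obs <- matrix(aperm(movie$data, c(1, 3, 4, 5, 2)), ncol = d[2])
  true <- pmax(obs %*% t(Minv), 0)
  out <- aperm(array(true, dim = c(d[1], d[3], d[4], d[5], ncol(M))),
               c(1, 5, 2, 3, 4))
  scs_movie(out, movie$voxel_size, movie$frame_interval,
            movie$channels[seq_len(ncol(M))])
}

#' Spectral unmixing model
#'
#' @param M square mixing matrix (observed = M %*% true), non-negative
#'   entries, invertible.
#' @param correction positive per-channel instrument correction factors
#'   `(donor, acceptor)` applied inside [fret_ratio()].
#' @return an `unmixing_model` list.
#' @export
unmixing_model <- function(M = diag(2), correction = c(1, 1)) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("mixing matrix entries must be >= 0")
  if (abs(det(M)) < 1e-12) stop("mixing matrix is singular")
  if (any(correction <= 0)) stop("correction factors must be positive")
  structure(list(M = M, correction = as.numeric(correction)),
            class = "unmixing_model")
}

#' Relative FRET ratio
#'
#' `ratio = (g * acceptor) / (b * donor + g * acceptor)` with `(b, g)` the
#' instrument correction factors: the acceptor (citrine) gain divided by
#' total donor + acceptor emission, a monotone readout of intracellular
#' calcium for troponin-based FRET indicators.
#'
#' @param donor,acceptor non-negative background-subtracted intensities
#'   (vectorized).
#' @param correction positive length-2 `(donor, acceptor)` factors.
#' @return ratio in `[0, 1]`; `NA` (with a warning) where both inputs are 0.
#' @export
fret_ratio <- function(donor, acceptor, correction = c(1, 1)) {
  if (any(donor < 0) || any(acceptor < 0))
    stop("intensities must be non-negative")
  if (any(correction <= 0)) stop("correction factors must be positive")
  num <- correction[2] * acceptor
  den <- correction[1] * donor + num
  bad <- den == 0
  if (any(bad)) warning("ratio undefined where donor = acceptor = 0")
  ifelse(bad, NA_real_, num / den)
}

#' Per-cell FRET and macrophage-contact records
#'
#' For every labelled cell in every frame: background-subtracted donor and
#' acceptor sums over the cell mask, the relative FRET ratio, and the
#' colocalization intensity (mean macrophage-channel signal over the mask,
#' the contact proxy).
#'
#' @param movie an [scs_movie()] (already unmixed if needed).
#' @param cell_masks integer array `(t, z, y, x)`; 0 background, otherwise
#'   cell id (e.g. from [cell_masks_from_tracks()]).
#' @param donor_channel,acceptor_channel,macro_channel channel indices or
#'   names.
#' @param correction length-2 instrument correction `(donor, acceptor)`.
#' @param background constant background level subtracted per voxel before
#'   summing (clipped at zero).
#' @return data.frame with one row per (cell, frame):
#'   `cell_id, frame, donor_sum, acceptor_sum, ratio, coloc_intensity,
#'   group` (`group` starts `"unassigned"`; see [assign_groups()]).
#' @export
cell_records <- function(movie, cell_masks, donor_channel, acceptor_channel,
                         macro_channel, correction = c(1, 1),
                         background = 0) {
  d <- dim(movie$data)
  if (!all(dim(cell_masks) == d[c(1, 3, 4, 5)]))
    stop("cell_masks must align with the movie frames")
  rows <- list()
  for (f in seq_len(d[1])) {
    lab <- array(cell_masks[f, , , ], dim = d[3:5])
    ids <- sort(unique(lab[lab > 0L]))
    if (!length(ids)) next
    don <- movie_frame(movie, f, donor_channel)
    acc <- movie_frame(movie, f, acceptor_channel)
    mac <- movie_frame(movie, f, macro_channel)
    for (id in ids) {
      sel <- lab == id
      if (!any(sel)) stop("empty mask for cell ", id)
      ds <- sum(pmax(don[sel] - background, 0))
      as_ <- sum(pmax(acc[sel] - background, 0))
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = id, frame = f, donor_sum = ds, acceptor_sum = as_,
        ratio = suppressWarnings(fret_ratio(ds, as_, correction)),
        coloc_intensity = mean(pmax(mac[sel] - background, 0)),
        group = "unassigned")
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = integer(), frame = integer(),
                      donor_sum = numeric(), acceptor_sum = numeric(),
                      ratio = numeric(), coloc_intensity = numeric(),
                      group = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

biexp <- function(x, A1, tau1, A2, tau2, c0 = 0) {
  A1 * exp(-x / tau1) + A2 * exp(-x / tau2) + c0
}

#' Fit a biexponential decay to a histogram and find the plateau crossing
#'
#' Fits `count = A1 exp(-x/tau1) + A2 exp(-x/tau2) (+ c)` to the decaying
#' flank of a histogram (all bins after the global mode) by least squares
#' with multiple deterministic initializations, estimates the plateau level
#' `c` either as a free additive constant (`plateau_mode = "fit"`) or as the
#' median count over the top-decile-x tail bins (`"tail_median"`, default),
#' and returns the smallest `x > 0` where the fitted decay meets the
#' plateau, located by bracketing and bisection to 1e-6 relative tolerance.
#' This is the construction that turns a colocalization-intensity histogram
#' into a contact threshold (the study it models reported a plateau of 9509
#' counts crossed at 717 AU).
#'
#' @param histogram data.frame with columns `x` (bin centres, AU) and
#'   `count` (non-negative), at least 8 nonzero bins.
#' @param plateau_mode `"tail_median"` or `"fit"`.
#' @param n_starts number of deterministic initializations (>= 10 used).
#' @return a `decay_fit` list: `A1, tau1, A2, tau2, plateau, threshold,
#'   residual, converged` (amplitudes/constants in counts, `tau` and
#'   `threshold` in AU; `tau1 < tau2`; `threshold` is `NA` if the decay
#'   never reaches the plateau).
#' @export
fit_decay_threshold <- function(histogram,
                                plateau_mode = c("tail_median", "fit"),
                                n_starts = 12L) {
  plateau_mode <- match.arg(plateau_mode)
  x <- histogram$x; y <- histogram$count
  if (any(y < 0)) stop("counts must be non-negative")
  if (sum(y > 0) < 8) stop("need at least 8 nonzero bins")
  mode_i <- which.max(y)
  sel <- seq(mode_i, length(x)) # decaying flank: from the mode on
  xd <- x[sel]; yd <- y[sel]
  x0 <- xd[1]
  xs <- xd - x0 # fit in shifted coordinates for conditioning
  span <- max(xs)
  plateau_fixed <- if (plateau_mode == "tail_median") {
    tail_sel <- xd >= stats::quantile(xd, 0.9)
    stats::median(yd[tail_sel])
  } else NA_real_
  ymax <- max(yd)
  dat <- data.frame(xs = xs, yd = yd)
  tau_grid <- span / c(2, 4, 8, 16, 32, 64)
  starts <- list()
  for (i in seq_along(tau_grid))
    for (j in seq_along(tau_grid))
      if (tau_grid[i] > tau_grid[j])
        starts[[length(starts) + 1]] <- c(t1 = tau_grid[j],
                                          t2 = tau_grid[i])
  if (length(starts) > n_starts)
    starts <- starts[round(seq(1, length(starts), length.out = n_starts))]
  best <- NULL
  for (st in starts) {
    fit <- tryCatch({
      if (plateau_mode == "fit") {
        minpack.lm::nlsLM(
          yd ~ A1 * exp(-xs / tau1) + A2 * exp(-xs / tau2) + c0,
          data = dat,
          start = list(A1 = ymax * 0.7, tau1 = st[["t1"]],
                       A2 = ymax * 0.3, tau2 = st[["t2"]],
                       c0 = min(yd)),
          lower = c(0, 1e-9, 0, 1e-9, 0),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        ydc <- pmax(yd - plateau_fixed, 0)
        minpack.lm::nlsLM(
          ydc ~ A1 * exp(-xs / tau1) + A2 * exp(-xs / tau2),
          data = cbind(dat, ydc = ydc),
          start = list(A1 = ymax * 0.7, tau1 = st[["t1"]],
                       A2 = ymax * 0.3, tau2 = st[["t2"]]),
          lower = c(0, 1e-9, 0, 1e-9),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # degenerate data (e.g. plateau swamps the decay): log-linear
    # single-exponential fallback with A2 -> 0
    ydc <- if (plateau_mode == "fit") yd - min(yd) else
      pmax(yd - plateau_fixed, 0)
    posi <- which(ydc > 0)
    if (length(posi) >= 2) {
      lf <- stats::lm(log(ydc[posi]) ~ xs[posi])
      tau <- -1 / min(stats::coef(lf)[2], -1e-9)
      cf <- c(A1 = unname(exp(stats::coef(lf)[1])), tau1 = tau,
              A2 = 0, tau2 = tau * 2)
    } else {
      cf <- c(A1 = 0, tau1 = 1, A2 = 0, tau2 = 2)
    }
    if (plateau_mode == "fit") cf <- c(cf, c0 = min(yd))
    best <- list(rss = sum((biexp(xs, cf[["A1"]], cf[["tau1"]], cf[["A2"]],
                                  cf[["tau2"]],
                                  if (plateau_mode == "fit") cf[["c0"]]
                                  else plateau_fixed) - yd)^2))
    coefs <- cf
  } else coefs <- stats::coef(best$fit)
  cf <- coefs
  c0 <- if (plateau_mode == "fit") cf[["c0"]] else plateau_fixed
  # report tau1 < tau2
  if (cf[["tau1"]] > cf[["tau2"]]) {
    cf <- c(A1 = cf[["A2"]], tau1 = cf[["tau2"]],
            A2 = cf[["A1"]], tau2 = cf[["tau1"]])
  }
  decay <- function(z) cf[["A1"]] * exp(-(z - x0) / cf[["tau1"]]) +
    cf[["A2"]] * exp(-(z - x0) / cf[["tau2"]])
  # smallest x > x0 where the decay meets the plateau
  threshold <- NA_real_
  if (decay(x0) > c0 && c0 > 0) {
    hi <- x0 + span
    while (decay(hi) > c0 && hi < x0 + 1000 * span) hi <- hi + span
    if (decay(hi) <= c0) {
      lo <- x0
      while ((hi - lo) > 1e-6 * max(abs(hi), 1)) {
        mid <- (lo + hi) / 2
        if (decay(mid) > c0) lo <- mid else hi <- mid
      }
      threshold <- (lo + hi) / 2
    }
  }
  structure(list(A1 = cf[["A1"]], tau1 = cf[["tau1"]],
                 A2 = cf[["A2"]], tau2 = cf[["tau2"]],
                 plateau = c0, threshold = threshold,
                 residual = best$rss, plateau_mode = plateau_mode,
                 x_mode = x0),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> A1=%.3g tau1=%.3g A2=%.3g tau2=%.3g plateau=%.3g (%s)\n",
    x$A1, x$tau1, x$A2, x$tau2, x$plateau, x$plateau_mode))
  cat(sprintf("  threshold: %s AU (residual %.3g)\n",
              if (is.na(x$threshold)) "no crossing"
              else sprintf("%.4g", x$threshold), x$residual))
  invisible(x)
}

#' Assign cells to macrophage-contact groups
#'
#' Cells with colocalization intensity exactly 0 form the non-contacting
#' `minus` group; cells above the threshold form the tight-contact `plus`
#' group; cells in `(0, threshold]` stay `unassigned` and are excluded from
#' downstream FRET comparisons.
#'
#' @param records data.frame from [cell_records()].
#' @param threshold contact threshold in AU (> 0), e.g. the `threshold`
#'   from [fit_decay_threshold()].
#' @return `records` with the `group` column set.
#' @export
assign_groups <- function(records, threshold) {
  stopifnot_scalar(threshold, "threshold")
  records$group <- ifelse(records$coloc_intensity == 0, "minus",
                          ifelse(records$coloc_intensity > threshold,
                                 "plus", "unassigned"))
  records
}
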