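test_that("unmixing inverts the mixing matrix and clips at zero", {
  set.seed(1)
  truth <- array(runif(2 * 2 * 4 * 6 * 6, 0, 50), dim = c(2, 2, 4, 6, 6))
  mv_true <- scs_movie(truth, c(4, 2, 2))
  expect_equal(unmix(mv_true, unmixing_model(diag(2)))$data, truth,
               tolerance = 1e-12)
  M <- matrix(c(1, 0, 0.2, 1), 2, 2) # acceptor bleeds into channel 1
  mixed <- truth
  for (f in 1:2) for (iz in 1:4) {
    v <- rbind(as.numeric(truth[f, 1, iz, , ]),
               as.numeric(truth[f, 2, iz, , ]))
    w <- M %*% v
    mixed[f, 1, iz, , ] <- w[1, ]
    mixed[f, 2, iz, , ] <- w[2, ]
  }
  rec <- unmix(scs_movie(mixed, c(4, 2, 2)), unmixing_model(M))
  expect_equal(rec$data, truth, tolerance = 1e-9)
  # values driven negative by the inverse are clamped
  neg <- scs_movie(array(c(0, 10), dim = c(1, 2, 1, 1, 1)), c(4, 2, 2))
  out <- unmix(neg, unmixing_model(M))
  expect_true(all(out$data >= 0))
  expect_error(unmixing_model(matrix(1, 2, 2)), "singular")
})

test_that("mix-then-unmix is the identity for random well-conditioned M", {
  set.seed(7)
  for (i in 1:10) {
    repeat {
      M <- matrix(runif(4, 0, 1), 2, 2) + diag(2)
      if (kappa(M) <= 100) break
    }
    truth <- array(runif(1 * 2 * 3 * 4 * 4, 0, 100), dim = c(1, 2, 3, 4, 4))
    mixed <- truth
    v <- rbind(matrix(aperm(truth, c(1, 3, 4, 5, 2)), ncol = 2)[, 1],
               matrix(aperm(truth, c(1, 3, 4, 5, 2)), ncol = 2)[, 2])
    w <- t(M %*% v)
    mixed <- aperm(array(w, dim = c(1, 3, 4, 4, 2)), c(1, 5, 2, 3, 4))
    rec <- unmix(scs_movie(mixed, c(4, 2, 2)), unmixing_model(M))
    expect_lt(max(abs(rec$data - truth)), 1e-9)
  }
})

test_that("FRET ratio arithmetic, bounds and monotonicity", {
  expect_equal(fret_ratio(5, 0), 0)
  expect_equal(fret_ratio(3, 3), 0.5)
  expect_equal(fret_ratio(2, 6), 0.75)
  expect_warning(r0 <- fret_ratio(0, 0))
  expect_true(is.na(r0))
  # correction factors rescale the channels
  expect_equal(fret_ratio(2, 2, correction = c(1, 3)), 0.75)
  set.seed(2)
  d <- runif(200, 0, 100); a <- runif(200, 0, 100)
  r <- fret_ratio(d, a)
  expect_true(all(r >= 0 & r <= 1))
  # strictly increasing in acceptor, decreasing in donor
  expect_true(all(fret_ratio(d, a + 1) > r))
  expect_true(all(fret_ratio(d + 1, a) < r))
  expect_error(fret_ratio(-1, 2), "non-negative")
})

test_that("cell records measure contact and calcium as constructed", {
  g <- small_geometry(seed = 5)
  anchors <- macrophage_anchors(g, n = 4, spacing = 30, seed = 5)
  gt <- simulate_tracks(g, n_per_fate = c(internal = 6),
                        motion = list(speed = 6, persistence = 0.6,
                                      dwell_frames = 6),
                        n_frames = 6,
                        contact = list(anchors = anchors, n_contact = 3,
                                       clear_dist = 30),
                        seed = 6)
  spec <- list(donor = list(source = "fret_donor", amplitude = 60),
               acceptor = list(source = "fret_acceptor", amplitude = 60),
               macro = list(source = "macrophages", amplitude = 40,
                            sigma = rep(4, 3)))
  mv <- render_movie(g, gt, channel_spec = spec, anchors = anchors,
                     noise = NULL, seed = 2)
  masks <- cell_masks_from_tracks(gt, g$shape, g$voxel_size, radius = 5)
  rec <- cell_records(mv, masks, "donor", "acceptor", "macro")
  contact_ids <- unique(gt$track_id[gt$contact])
  free_ids <- setdiff(unique(gt$track_id), contact_ids)
  rec_contact <- rec[rec$cell_id %in% contact_ids & rec$frame > 1, ]
  rec_free <- rec[rec$cell_id %in% free_ids, ]
  # free cells sit outside the rendered macrophage support: coloc exactly 0
  expect_true(all(rec_free$coloc_intensity == 0))
  expect_true(all(rec_contact$coloc_intensity > 0))
  # elevated calcium during contact raises the ratio (noiseless, exact)
  expect_gt(min(rec_contact$ratio), max(rec_free$ratio))
})

test_that("identical cells give identical records", {
  g <- slab_geometry()
  pos <- c(24, 20, 20)
  gt <- rbind(
    data.frame(track_id = 1L, fate = "internal", frame = 1L, z_um = pos[1],
               y_um = pos[2], x_um = pos[3], contact = FALSE, calcium = 0.3),
    data.frame(track_id = 2L, fate = "internal", frame = 1L, z_um = pos[1],
               y_um = pos[2] + 24, x_um = pos[3] + 24, contact = FALSE,
               calcium = 0.3))
  spec <- list(donor = list(source = "fret_donor", amplitude = 60),
               acceptor = list(source = "fret_acceptor", amplitude = 60),
               macro = list(source = "cells", amplitude = 0))
  mv <- render_movie(g, gt, channel_spec = spec, noise = NULL, seed = 1)
  masks <- cell_masks_from_tracks(gt, g$shape, g$voxel_size, radius = 5)
  rec <- cell_records(mv, masks, "donor", "acceptor", "macro")
  expect_equal(rec$ratio[1], rec$ratio[2], tolerance = 1e-12)
  expect_equal(rec$donor_sum[1], rec$donor_sum[2], tolerance = 1e-9)
})

test_that("single-exponential threshold matches the closed form", {
  x <- seq(0, 250, by = 2)
  A <- 4000; tau <- 25; c0 <- 60
  h <- data.frame(x = x, count = A * exp(-x / tau) + c0)
  fit <- fit_decay_threshold(h, plateau_mode = "fit")
  expect_equal(fit$threshold, tau * log(A / c0), tolerance = 1e-4)
  expect_equal(fit$plateau, c0, tolerance = 1e-2)
})

test_that("biexponential threshold recovery from Poisson-sampled counts", {
  set.seed(11)
  t1 <- 15; t2 <- 75; A1 <- 7000; A2 <- 3000; cc <- 0.1 * (A1 + A2)
  xmax <- t2 * log(A2 / (0.01 * cc))
  x <- seq(0, xmax, length.out = 80)
  y <- rpois(length(x), A1 * exp(-x / t1) + A2 * exp(-x / t2) + cc)
  fit <- fit_decay_threshold(data.frame(x = x, count = y))
  truth <- uniroot(function(z) A1 * exp(-z / t1) + A2 * exp(-z / t2) - cc,
                   c(1e-6, xmax))$root
  expect_lt(abs(fit$threshold - truth) / truth, 0.1)
  expect_lt(fit$tau1, fit$tau2)
})

test_that("degenerate histograms are handled", {
  x <- seq(0, 100, by = 5)
  expect_error(fit_decay_threshold(data.frame(x = x[1:5],
                                              count = c(9, 7, 5, 3, 1))),
               "8 nonzero")
  # plateau above the whole decay: no crossing
  h <- data.frame(x = x, count = 100 * exp(-x / 10) + 500)
  fit <- fit_decay_threshold(h, plateau_mode = "tail_median")
  expect_true(is.na(fit$threshold))
})

test_that("contact groups follow the zero / threshold rules", {
  rec <- data.frame(cell_id = 1:3, frame = 1,
                    donor_sum = 1, acceptor_sum = 1, ratio = 0.5,
                    coloc_intensity = c(0, 800, 300), group = "unassigned")
  out <- assign_groups(rec, threshold = 717)
  expect_identical(out$group, c("minus", "plus", "unassigned"))
})
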