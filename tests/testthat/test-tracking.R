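test_that("a single stationary spot per frame forms one tracklet", {
  spots <- data.frame(frame = 1:6, z_um = 10, y_um = 20, x_um = 30,
                      quality = 15)
  tr <- link_frames(spots, max_link_dist = 20)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(tr$frame, 1:6)
})

test_that("frame-to-frame links attain the exhaustive-enumeration optimum", {
  for (seed in 1:40) {
    spots <- random_spot_instance(seed)
    if (!nrow(spots)) next
    tr <- link_frames(spots, max_link_dist = 20)
    expect_equal(linking_cost(tr, 20), oracle_linking_cost(spots, 20),
                 tolerance = 1e-9)
  }
})

test_that("links beyond the distance cap are refused", {
  # 25 um apart with a 20 um cap: two separate tracklets
  spots <- data.frame(frame = c(1, 2), z_um = c(10, 10), y_um = c(20, 45),
                      x_um = c(30, 30), quality = 15)
  tr <- link_frames(spots, max_link_dist = 20)
  expect_equal(length(unique(tr$track_id)), 2L)
})

test_that("gap closing honours the two-frame interval rule", {
  seg <- function(frames, y) data.frame(frame = frames, z_um = 10,
                                        y_um = y, x_um = 30, quality = 15)
  # end at frame 10, restart at frame 12, 5 um away: merged (1-frame gap)
  tl <- link_frames(rbind(seg(8:10, 20), seg(12:14, 25)), 20)
  expect_equal(length(unique(tl$track_id)), 2L)
  merged <- close_gaps(tl, max_gap_dist = 20, max_gap_frames = 2)
  expect_equal(length(unique(merged$track_id)), 1L)
  expect_equal(unique(merged$track_id), min(tl$track_id)) # earlier id kept
  # end at frame 10, restart at frame 13: interval exceeded, not merged
  tl2 <- link_frames(rbind(seg(8:10, 20), seg(13:15, 25)), 20)
  merged2 <- close_gaps(tl2, 20, 2)
  expect_equal(length(unique(merged2$track_id)), 2L)
  # no gaps anywhere: output identical to input
  tl3 <- link_frames(seg(1:5, 20), 20)
  expect_identical(as.data.frame(close_gaps(tl3, 20, 2)),
                   as.data.frame(tl3))
})

test_that("gap closing solves the global assignment optimally", {
  for (seed in 41:70) {
    spots <- random_spot_instance(seed)
    if (!nrow(spots)) next
    tl <- link_frames(spots, max_link_dist = 12)
    merged <- close_gaps(tl, max_gap_dist = 15, max_gap_frames = 2)
    gc <- gap_cost_pair(tl, merged, 15, 2)
    expect_equal(gc$realized, gc$oracle, tolerance = 1e-9)
  }
})

test_that("tracklets sharing a spot are rejected", {
  bad <- data.frame(track_id = c(1L, 2L), frame = c(3, 3), z_um = 1,
                    y_um = 2, x_um = 3, quality = 15)
  class(bad) <- c("scs_tracks", "data.frame")
  expect_error(close_gaps(bad, 20, 2), "share")
})

test_that("the minimum-length filter keeps 5 and discards 4 detections", {
  mk <- function(id, n) data.frame(track_id = id, frame = seq_len(n),
                                   z_um = id, y_um = 0, x_um = 0)
  tracks <- rbind(mk(1L, 4), mk(2L, 5), mk(3L, 7))
  class(tracks) <- c("scs_tracks", "data.frame")
  kept <- filter_tracks(tracks, min_length = 5)
  expect_setequal(unique(kept$track_id), c(2L, 3L))
  expect_identical(filter_tracks(tracks[0, ], 5), tracks[0, ])
})

test_that("track sets are invariant to spot input order", {
  spots <- random_spot_instance(99)
  tr1 <- track_spots(spots, 20, 20, 2, min_length = 2)
  set.seed(1)
  tr2 <- track_spots(spots[sample(nrow(spots)), ], 20, 20, 2,
                     min_length = 2)
  sig <- function(tr) sort(vapply(split(tr, tr$track_id), function(s)
    paste(s$frame, s$z_um, s$y_um, s$x_um, collapse = ";"), ""))
  expect_identical(sig(tr1), sig(tr2))
})

test_that("planted trajectories are recovered as single tracks", {
  g <- small_geometry(seed = 6)
  gt <- simulate_tracks(g, n_per_fate = c(internal = 3, parenchymal = 3),
                        n_frames = 10, min_spacing = 30, seed = 12)
  mv <- render_movie(g, gt, noise = noise_model(1, 2, 5), seed = 2)
  sp <- detect_spots(mv, "cells", 10, 10)
  tr <- track_spots(sp, 20, 20, 2, 5)
  expect_equal(length(unique(tr$track_id)), 6L)
  # each recovered track follows one planted track closely
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    d <- vapply(split(gt, gt$track_id), function(g2) {
      m <- merge(sub, g2, by = "frame")
      mean(sqrt((m$z_um.x - m$z_um.y)^2 + (m$y_um.x - m$y_um.y)^2 +
                  (m$x_um.x - m$x_um.y)^2))
    }, 0)
    expect_lt(min(d), 4)
    expect_gte(sum(tr$track_id == id), 9) # >= 90% of 10 spots
  }
})
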