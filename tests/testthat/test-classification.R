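slab_regions <- function() region_mask_from_geometry(slab_geometry())

# build a two-spot track between physical positions a and b
two_spot_track <- function(a, b, frames = c(1L, 8L)) {
  df <- data.frame(track_id = 1L, frame = frames,
                   z_um = c(a[1], b[1]), y_um = c(a[2], b[2]),
                   x_um = c(a[3], b[3]))
  class(df) <- c("scs_tracks", "data.frame")
  df
}

test_that("entering/leaving/internal rules follow the 5 um margins", {
  g <- slab_geometry()
  regions <- slab_regions()
  floor_z <- sum(g$thickness) # inner surface depth for the flat slab
  inside <- c(floor_z - 6, 30, 30)
  # starting 6 um into the parenchyma and ending inside: entering
  cl <- classify_track(two_spot_track(c(floor_z + 6, 30, 30), inside),
                       regions)
  expect_identical(cl$label, "entering")
  # starting inside, ending 7 um into the parenchyma: leaving
  cl2 <- classify_track(two_spot_track(inside, c(floor_z + 7, 30, 30)),
                        regions)
  expect_identical(cl2$label, "leaving")
  # a start on the first parenchymal voxel plane (4 um from the sinus)
  # fails the "at least 5 um" rule; states are evaluated at voxel centres
  cl3 <- classify_track(two_spot_track(c(floor_z, 30, 30), inside),
                        regions)
  expect_identical(cl3$start_state, "parenchymal")
  expect_lt(cl3$start_distance, 5)
  expect_identical(cl3$label, "non_interacting")
  # both endpoints inside: internal
  cl4 <- classify_track(two_spot_track(inside, inside + c(0, 5, 5)),
                        regions)
  expect_identical(cl4$label, "internal")
  # both endpoints deep in the parenchyma: non-interacting
  cl5 <- classify_track(two_spot_track(c(floor_z + 10, 20, 20),
                                       c(floor_z + 12, 40, 40)), regions)
  expect_identical(cl5$label, "non_interacting")
  expect_error(classify_track(two_spot_track(c(500, 30, 30), inside),
                              regions), "bounds")
})

test_that("the leaving margin accepts either side of the sinus", {
  # geometry with extranodal space above the outer wall: push the shell
  # deeper with a curved surface
  g <- generate_scs_geometry(shape = c(18, 48, 48), voxel_size = c(4, 2, 2),
                             curvature = 0.004, roughness_amplitude = 0,
                             seed = 1)
  regions <- region_mask_from_geometry(g)
  side <- regions$sidedness[1, , , ]
  expect_true(any(side == 2L)) # extranodal voxels exist off-apex
  ex <- which(side == 2L & regions$distance[1, , , ] >= 6, arr.ind = TRUE)
  expect_gt(nrow(ex), 0)
  ex1 <- (ex[1, ] - 1) * g$voxel_size
  inside <- which(regions$mask[1, , , ], arr.ind = TRUE)
  # pick an inside voxel in the same lateral area
  d <- abs(inside[, 2] - ex[1, 2]) + abs(inside[, 3] - ex[1, 3])
  in1 <- (inside[which.min(d), ] - 1) * g$voxel_size
  cl <- classify_track(two_spot_track(in1, ex1), regions)
  expect_identical(cl$label, "leaving")
  # but an extranodal *start* cannot count as entering
  cl2 <- classify_track(two_spot_track(ex1, in1), regions)
  expect_identical(cl2$label, "non_interacting")
})

test_that("cropping truncates tracks and drops the ones left too short", {
  g <- slab_geometry()
  mk <- function(id, frames, z) {
    data.frame(track_id = id, frame = frames, z_um = z, y_um = 30,
               x_um = 30, quality = 15)
  }
  tracks <- rbind(mk(1L, 1:20, 10),   # 12 in-window spots after t-crop
                  mk(2L, 14:20, 10),  # entirely outside the 12-frame window
                  mk(3L, 1:8, 10))
  class(tracks) <- c("scs_tracks", "data.frame")
  out <- crop_consistent(tracks, z_slices = 13, time_points = 12,
                         voxel_size = g$voxel_size, min_length = 5)
  expect_setequal(unique(out$track_id), c(1L, 3L))
  expect_equal(sum(out$track_id == 1L), 12L)
  expect_equal(attr(out, "dropped_tracks"), 1L)
  # movies/maps: identity when the data already match the crop
  mv <- render_movie(g, mk(1L, 1:3, 10) |>
                       transform(fate = "x", contact = FALSE, calcium = 0),
                     noise = NULL, seed = 1)
  expect_equal(crop_consistent(mv, 13, 3), mv)
  expect_error(crop_consistent(mv, 14, 3), "exceeds")
})

test_that("fraction tables are exact and conserve track counts", {
  cl <- data.frame(track_id = 1:4,
                   label = c("internal", "internal", "entering", "leaving"))
  tab <- summarize_fractions(cl)
  expect_equal(tab$frac_internal, 0.5)
  expect_equal(tab$frac_entering, 0.25)
  expect_equal(tab$frac_leaving, 0.25)
  expect_equal(tab$frac_non_interacting, 0)
  expect_equal(tab$n_internal + tab$n_entering + tab$n_leaving +
                 tab$n_non_interacting, tab$n_tracks)
  all_int <- data.frame(track_id = 1:3, label = "internal")
  expect_equal(summarize_fractions(all_int)$frac_internal, 1)
  two <- summarize_fractions(list(a = cl, b = all_int))
  expect_equal(nrow(two), 2L)
  sums <- rowSums(two[, paste0("frac_", c("entering", "leaving",
                                          "internal", "non_interacting"))])
  expect_equal(sums, c(1, 1))
  expect_warning(summarize_fractions(list(a = cl, b = cl[0, ])),
                 "zero tracks")
})

test_that("condition comparison reproduces the closed-form t test", {
  ta <- data.frame(movie = c("a1", "a2", "a3"),
                   frac_leaving = c(0.1, 0.2, 0.3))
  tb <- data.frame(movie = c("b1", "b2", "b3"),
                   frac_leaving = c(0.4, 0.5, 0.6))
  two <- compare_conditions(ta, tb, "leaving", "two.sided")
  expect_equal(two$t, -3.674, tolerance = 1e-3)
  expect_equal(two$p_value, 0.0213, tolerance = 1e-2)
  # one-tailed p in the hypothesized direction is half the two-tailed p
  one <- compare_conditions(ta, tb, "leaving", "less")
  expect_equal(one$p_value, two$p_value / 2, tolerance = 1e-12)
  # identical groups with nonzero variance: t = 0, p = 1
  eq <- compare_conditions(ta, ta, "leaving", "two.sided")
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)
  expect_error(compare_conditions(ta[1, ], tb, "leaving"), "2 movies")
})
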