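#' Generate a synthetic subcapsular-sinus geometry
#'
#' Builds a labelled voxel volume containing a gently curved sinus shell near
#' the shallow (`z = 0`) face: an outer wall (capsule-side endothelium), a
#' lumen, and an inner wall (floor) facing the parenchyma. The shell follows
#' a paraboloid sag with a seeded low-amplitude roughness field, mimicking
#' the dome-shaped floor/ceiling topology seen under the lymph-node capsule.
#'
#' Class codes in `class_volume`: 0 background, 1 inner wall, 2 lumen,
#' 3 outer wall. Background covers both the extranodal space above the outer
#' wall and the parenchyma below the inner wall.
#'
#' @param shape integer length-3 voxel counts `(z, y, x)`.
#' @param voxel_size numeric length-3, um per voxel `(z, y, x)`.
#' @param wall_thickness numeric length-2, um: `(inner, outer)` wall thickness.
#' @param lumen_thickness lumen thickness in um.
#' @param curvature paraboloid curvature of the shell in 1/um (0 = flat slab).
#' @param roughness_amplitude amplitude (um) of the seeded surface roughness.
#' @param roughness_wavelength characteristic lateral wavelength (um) of the
#'   roughness field.
#' @param frame_interval seconds between frames, carried into downstream
#'   simulation.
#' @param min_parenchyma minimum depth (um) of parenchyma that must remain
#'   below the deepest point of the shell.
#' @param seed integer seed for the roughness field.
#' @return an `scs_geometry` object with elements `shape`, `voxel_size`,
#'   `class_volume`, `surface` (outer-surface depth map, um, `(y, x)`),
#'   `thickness` (named um: outer, lumen, inner), `frame_interval`.
#' @export
generate_scs_geometry <- function(shape = c(13L, 256L, 256L),
                                  voxel_size = c(4, 1, 1),
                                  wall_thickness = c(4, 4),
                                  lumen_thickness = 8,
                                  curvature = 0.0005,
                                  roughness_amplitude = 1,
                                  roughness_wavelength = 40,
                                  frame_interval = 35,
                                  min_parenchyma = 20,
                                  seed = 1L) {
  shape <- as.integer(shape)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (any(wall_thickness <= 0) || lumen_thickness <= 0)
    stop("thicknesses must be positive")
  t_in <- wall_thickness[1]; t_out <- wall_thickness[2]
  # each layer must be at least one voxel thick along z
  if (any(c(t_in, t_out, lumen_thickness) < voxel_size[1]))
    stop("each shell layer must be at least one z-voxel thick")
  total <- t_in + t_out + lumen_thickness
  ext <- movie_extent(shape, voxel_size)
  y <- (seq_len(shape[2]) - 1) * voxel_size[2]
  x <- (seq_len(shape[3]) - 1) * voxel_size[3]
  yc <- ext[2] / 2; xc <- ext[3] / 2
  r2 <- outer((y - yc)^2, rep(1, shape[3])) +
        outer(rep(1, shape[2]), (x - xc)^2)
  sag <- curvature / 2 * r2
  rough <- with_seed(seed, {
    if (roughness_amplitude > 0) {
      k <- 2 * pi / roughness_wavelength
      f <- matrix(0, shape[2], shape[3])
      for (i in 1:6) {
        th <- runif(1, 0, 2 * pi); ph <- runif(1, 0, 2 * pi)
        amp <- runif(1, 0.5, 1)
        f <- f + amp * cos(k * (outer(y * cos(th), rep(1, shape[3])) +
                                outer(rep(1, shape[2]), x * sin(th))) + ph)
      }
      f * roughness_amplitude / max(abs(f))
    } else matrix(0, shape[2], shape[3])
  })
  surface <- sag + rough - min(sag + rough) # outer surface depth, apex at z=0
  deepest <- max(surface) + total
  if (deepest + min_parenchyma > ext[1])
    stop(sprintf(paste0("shell (deepest point %.1f um) leaves < %g um of ",
                        "parenchyma in a %.0f um deep volume"),
                 deepest, min_parenchyma, ext[1]))
  z <- (seq_len(shape[1]) - 1) * voxel_size[1]
  # depth of each voxel relative to the local outer surface
  cls <- array(0L, dim = shape)
  for (iz in seq_len(shape[1])) {
    d <- z[iz] - surface                       # (y, x) matrix
    lab <- matrix(0L, shape[2], shape[3])
    lab[d >= 0 & d < t_out] <- SCS_CLASSES[["outer_wall"]]
    lab[d >= t_out & d < t_out + lumen_thickness] <- SCS_CLASSES[["lumen"]]
    lab[d >= t_out + lumen_thickness & d < total] <- SCS_CLASSES[["inner_wall"]]
    cls[iz, , ] <- lab
  }
  structure(list(
    shape = shape,
    voxel_size = as.numeric(voxel_size),
    class_volume = cls,
    surface = surface,
    thickness = c(outer = t_out, lumen = lumen_thickness, inner = t_in),
    frame_interval = frame_interval,
    curvature = curvature,
    seed = as.integer(seed)
  ), class = "scs_geometry")
}

#' @export
print.scs_geometry <- function(x, ...) {
  cat(sprintf("<scs_geometry> (%s) voxels at (%s) um\n",
              paste(x$shape, collapse = ", "),
              paste(x$voxel_size, collapse = ", ")))
  cat(sprintf("  shell: outer %g um | lumen %g um | inner %g um; curvature %g 1/um\n",
              x$thickness["outer"], x$thickness["lumen"], x$thickness["inner"],
              x$curvature))
  invisible(x)
}

# signed depth (um) of a physical position below the local outer surface;
# bilinear interpolation of the stored surface map
scs_depth <- function(geometry, pos) {
  vs <- geometry$voxel_size
  ny <- geometry$shape[2]; nx <- geometry$shape[3]
  fy <- pos[2] / vs[2]; fx <- pos[3] / vs[3]
  iy <- min(max(floor(fy), 0), ny - 2); ix <- min(max(floor(fx), 0), nx - 2)
  wy <- min(max(fy - iy, 0), 1); wx <- min(max(fx - ix, 0), 1)
  s <- geometry$surface
  surf <- (1 - wy) * (1 - wx) * s[iy + 1, ix + 1] +
          wy * (1 - wx) * s[iy + 2, ix + 1] +
          (1 - wy) * wx * s[iy + 1, ix + 2] +
          wy * wx * s[iy + 2, ix + 2]
  pos[1] - surf
}

# TRUE if a physical position falls in the merged sinus shell
in_scs_shell <- function(geometry, pos) {
  d <- scs_depth(geometry, pos)
  tt <- geometry$thickness
  d >= 0 && d < sum(tt)
}

# depth below the inner (floor) surface: positive in parenchyma
parenchymal_depth <- function(geometry, pos) {
  scs_depth(geometry, pos) - sum(geometry$thickness)
}

#' Check the structural invariants of a synthetic sinus geometry
#'
#' Verifies mutual exclusivity of classes, that the lumen is a single
#' connected component sandwiched between the walls, that the inner wall
#' touches parenchymal background, and that the outer wall reaches the
#' shallow volume face.
#'
#' @param geometry an `scs_geometry`.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_geometry <- function(geometry) {
  cls <- geometry$class_volume
  if (!all(cls %in% SCS_CLASSES)) stop("unknown class labels present")
  lum <- cls == SCS_CLASSES[["lumen"]]
  if (!any(lum)) stop("no lumen voxels")
  lab <- .label3d(lum)
  if (max(lab) != 1L) stop("lumen is not a single connected component")
  if (!any(cls[1, , ] == SCS_CLASSES[["outer_wall"]]))
    stop("outer wall does not abut the shallow volume face")
  # inner wall must have parenchymal background below it somewhere
  inner_any <- apply(cls == SCS_CLASSES[["inner_wall"]], 1, any)
  bg_below <- FALSE
  for (iz in which(inner_any)) {
    if (iz < geometry$shape[1]) {
      below <- cls[iz + 1, , ]
      here <- cls[iz, , ] == SCS_CLASSES[["inner_wall"]]
      if (any(below[here] == SCS_CLASSES[["background"]])) bg_below <- TRUE
    }
  }
  if (!bg_below) stop("inner wall has no adjacent parenchymal background")
  invisible(TRUE)
}

# binary merged sinus mask of the true geometry
geometry_mask <- function(geometry) {
  geometry$class_volume != SCS_CLASSES[["background"]]
}
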