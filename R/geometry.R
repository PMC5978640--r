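# Phantom geometry: dimensioned description of every test object in the
# phantom coordinate frame. No image processing lives here.
#
# Coordinate frame (all mm): x lateral (0 at phantom midline), y depth from
# the chest wall (y = 0 at the wall, increasing into the phantom), z
# through-plane (0 at the bottom of the assembly). Right-handed.

GEOMETRY_SCHEMA_VERSION <- "1.0"

#' Stair-step chest-wall gauge
#'
#' A gauge of \code{n_steps} steps of \code{step_increment} mm each, rising
#' into the phantom from the chest wall (\code{y = 0}). The full gauge extent
#' is \code{n_steps * step_increment} (6.0 mm for the defaults).
#'
#' @param n_steps number of steps (default 12).
#' @param step_increment step depth in mm (default 0.5).
#' @param lateral_position gauge center x in mm.
#' @param width lateral width of the gauge in mm.
#' @param z_center through-plane center of the gauge in mm.
#' @param thickness z extent of the gauge material in mm.
#' @param contrast contrast fraction of the gauge relative to background.
#' @param id gauge identifier.
#' @return An object of class \code{step_gauge}.
#' @export
step_gauge <- function(n_steps = 12L, step_increment = 0.5,
                       lateral_position = 0, width = 4, z_center = 21,
                       thickness = 1, contrast = 1.0, id = "gauge") {
  if (!is_num1(n_steps) || n_steps < 1) stopf("n_steps must be a positive count")
  if (!is_num1(step_increment) || step_increment <= 0)
    stopf("step_increment must be > 0")
  g <- list(n_steps = as.integer(n_steps), step_increment = step_increment,
            lateral_position = lateral_position, width = width,
            z_center = z_center, thickness = thickness, contrast = contrast,
            id = id)
  class(g) <- "step_gauge"
  g
}

#' Full extent of a stair-step gauge in mm
#' @param gauge a \code{step_gauge}.
#' @export
gauge_extent <- function(gauge) gauge$n_steps * gauge$step_increment

#' Folded (reversing) bead ramp set
#'
#' Each folded set consists of two limbs offset laterally at the fold: beads
#' of 0.18 mm diameter spaced vertically at 0.25 mm, together rising 10 mm in
#' z. The top bead of the lower limb sits one vertical spacing below the
#' bottom bead of the upper limb, so the z ladder is uniform through the fold
#' and the folded pair spans exactly \code{total_rise}.
#'
#' @param bead_diameter bead diameter in mm (default 0.18).
#' @param vertical_spacing z spacing between consecutive beads in mm
#'   (default 0.25).
#' @param total_rise total z rise of the folded set in mm (default 10).
#' @param x_start x of the first bead in mm.
#' @param x_pitch in-plane spacing between consecutive beads in mm; the
#'   ramp runs along x.
#' @param y_lower,y_upper y (depth) of the lower and upper limb rows; their
#'   difference is the lateral offset at the fold.
#' @param z_base z of the first bead in mm.
#' @param direction +1 for a ramp ascending in z with increasing bead index
#'   (left side), -1 for the opposite run (right side).
#' @param side \code{"left"} or \code{"right"}.
#' @param contrast contrast fraction of the beads relative to background.
#' @return An object of class \code{bead_ramp}.
#' @export
bead_ramp <- function(bead_diameter = 0.18, vertical_spacing = 0.25,
                      total_rise = 10, x_start = -45, x_pitch = 1.0,
                      y_lower = 24.5, y_upper = 25.5, z_base = 16,
                      direction = 1L, side = "left", contrast = 10) {
  if (!is_num1(vertical_spacing) || vertical_spacing <= 0)
    stopf("vertical_spacing must be > 0")
  if (!is_num1(total_rise) || total_rise < 0) stopf("total_rise must be >= 0")
  if (!side %in% c("left", "right")) stopf("side must be 'left' or 'right'")
  r <- list(bead_diameter = bead_diameter,
            vertical_spacing = vertical_spacing, total_rise = total_rise,
            x_start = x_start, x_pitch = x_pitch, y_lower = y_lower,
            y_upper = y_upper, z_base = z_base,
            direction = as.integer(sign(direction)), side = side,
            contrast = contrast)
  class(r) <- "bead_ramp"
  r
}

#' Bead positions of a folded ramp set
#'
#' The lower limb carries \code{floor(total_rise / (2 * vertical_spacing)) + 1}
#' beads; the upper limb continues one vertical spacing above the fold and
#' stops at exactly \code{total_rise}, so consecutive beads differ by
#' \code{vertical_spacing} in z throughout and \code{max(z) - min(z)} equals
#' \code{total_rise} (41 beads for the defaults).
#'
#' @param ramp a \code{bead_ramp}.
#' @return A data.frame with columns \code{x}, \code{y}, \code{z} (mm),
#'   \code{limb} (\code{"lower"}/\code{"upper"}) and \code{bead} (index).
#' @export
bead_positions <- function(ramp) {
  stopifnot(inherits(ramp, "bead_ramp"))
  vs <- ramp$vertical_spacing
  if (vs <= 0) stopf("vertical_spacing must be > 0")
  if (ramp$total_rise == 0) {
    n <- 1L
  } else {
    n_lower <- floor(ramp$total_rise / (2 * vs)) + 1L
    n <- as.integer(round(ramp$total_rise / vs)) + 1L
    if (n < n_lower) n <- n_lower
  }
  k <- seq_len(n) - 1L
  n_lower <- if (ramp$total_rise == 0) 1L else floor(ramp$total_rise / (2 * vs)) + 1L
  dz <- k * vs
  dz[dz > ramp$total_rise] <- ramp$total_rise  # guard against fp spill
  z <- if (ramp$direction >= 0) ramp$z_base + dz else ramp$z_base - dz
  data.frame(
    x = ramp$x_start + k * ramp$x_pitch,
    y = ifelse(k < n_lower, ramp$y_lower, ramp$y_upper),
    z = z,
    limb = ifelse(k < n_lower, "lower", "upper"),
    bead = k + 1L
  )
}

#' Default phantom geometry
#'
#' Returns the dimensioned default geometry: a 42 mm-thick phantom with four
#' 12-step chest-wall gauges at 0.5 mm increments, two folded bead ramps
#' (0.18 mm beads at 0.25 mm vertical spacing rising 10 mm), three 5 mm
#' aluminum beads with z centers 10 mm apart, nine low-contrast spheres with
#' diameters 0.8--10 mm on a circle, an aluminum square just inside that
#' circle, and four alignment markers. Object placements that are not
#' dimensioned by the phantom's printed data (lateral gauge positions, the
#' sphere-circle radius, marker corners) are fixed, documented defaults and
#' can be overridden through the arguments.
#'
#' @param overall_thickness phantom z thickness in mm (default 42).
#' @param half_width,depth lateral half-extent and chest-wall depth in mm.
#' @param test_plane_z z of the central test-object plane in mm.
#' @param sphere_circle_radius radius of the low-contrast sphere circle (mm).
#' @param sphere_contrast contrast fraction of the low-contrast spheres
#'   (default +2\% of background).
#' @param al_square_contrast contrast fraction of the aluminum square
#'   (default +20\%).
#' @param ramp_contrast,marker_contrast,z_bead_contrast,gauge_contrast
#'   contrast fractions of the remaining objects.
#' @return An object of class \code{phantom_geometry}.
#' @export
default_geometry <- function(overall_thickness = 42, half_width = 50,
                             depth = 80, test_plane_z = overall_thickness / 2,
                             sphere_circle_radius = 17,
                             sphere_contrast = 0.02,
                             al_square_contrast = 0.20,
                             ramp_contrast = 10, marker_contrast = 2,
                             z_bead_contrast = 1, gauge_contrast = 1) {
  if (overall_thickness <= 0) stopf("overall_thickness must be > 0")
  zc <- test_plane_z

  gauges <- lapply(seq_along(c(-35, -12, 12, 35)), function(i) {
    x <- c(-35, -12, 12, 35)[i]
    step_gauge(lateral_position = x, z_center = zc, contrast = gauge_contrast,
               id = paste0("gauge", i))
  })

  ramps <- list(
    bead_ramp(x_start = -45, x_pitch = 1.0, y_lower = 24.5, y_upper = 25.5,
              z_base = zc - 5, direction = 1L, side = "left",
              contrast = ramp_contrast),
    bead_ramp(x_start = 5, x_pitch = 1.0, y_lower = 24.5, y_upper = 25.5,
              z_base = zc + 5, direction = -1L, side = "right",
              contrast = ramp_contrast)
  )

  z_beads <- data.frame(
    x = c(-12, 0, 12), y = c(14, 14, 14),
    z = zc + c(-10, 0, 10), diameter = 5, contrast = z_bead_contrast
  )

  # nine spheres on a circle; large diameters kept in the lower half so the
  # anterior ROIs and the contrast-detail sampling region stay clear
  ang <- (20 + 40 * (0:8)) * pi / 180
  sph_d <- c(1, 1.5, 0.8, 2, 4, 8, 10, 6, 3)
  cy <- 50
  spheres <- data.frame(
    x = round(sphere_circle_radius * cos(ang), 3),
    y = round(cy + sphere_circle_radius * sin(ang), 3),
    z = zc, diameter = sph_d, contrast = sphere_contrast
  )
  spheres <- spheres[order(spheres$diameter), ]
  rownames(spheres) <- NULL

  al_square <- list(center = c(x = 0, y = cy, z = zc), side = 10,
                    thickness = 1, contrast = al_square_contrast)

  markers <- data.frame(
    x = c(-44, 44, -44, 44), y = c(8, 8, 72, 72), z = zc,
    diameter = 3, contrast = marker_contrast
  )

  geom <- list(
    schema_version = GEOMETRY_SCHEMA_VERSION,
    overall_thickness = overall_thickness,
    half_width = half_width, depth = depth, test_plane_z = zc,
    chest_wall_plane = 0,
    gauges = gauges, ramps = ramps, z_beads = z_beads,
    low_contrast_spheres = spheres, al_square = al_square,
    alignment_markers = markers,
    background_value = 1  # objects are contrast fractions of background
  )
  class(geom) <- "phantom_geometry"
  validate_geometry(geom)
  geom
}

#' Phantom bounding box
#' @param geometry a \code{phantom_geometry}.
#' @return list with \code{min} and \code{max}, each named xyz vectors (mm).
#' @export
geometry_bbox <- function(geometry) {
  list(min = c(x = -geometry$half_width, y = 0, z = 0),
       max = c(x = geometry$half_width, y = geometry$depth,
               z = geometry$overall_thickness))
}

geometry_center <- function(geometry) {
  bb <- geometry_bbox(geometry)
  (bb$min + bb$max) / 2
}

validate_geometry <- function(geom) {
  stopifnot(inherits(geom, "phantom_geometry"))
  if (geom$overall_thickness <= 0) stopf("overall_thickness must be > 0")
  bb <- geometry_bbox(geom)
  inside <- function(p) all(p >= bb$min - 1e-9) && all(p <= bb$max + 1e-9)
  for (g in geom$gauges) {
    if (!inside(c(g$lateral_position, gauge_extent(g), g$z_center)))
      stopf("gauge '%s' lies outside the phantom bounding box", g$id)
  }
  for (r in geom$ramps) {
    bp <- bead_positions(r)
    if (!all(bp$x >= bb$min["x"] & bp$x <= bb$max["x"] &
             bp$y >= bb$min["y"] & bp$y <= bb$max["y"] &
             bp$z >= bb$min["z"] & bp$z <= bb$max["z"]))
      stopf("bead ramp (%s) lies outside the phantom bounding box", r$side)
  }
  for (df in list(geom$z_beads, geom$low_contrast_spheres,
                  geom$alignment_markers)) {
    if (!all(df$x >= bb$min["x"] & df$x <= bb$max["x"] &
             df$y >= bb$min["y"] & df$y <= bb$max["y"] &
             df$z >= bb$min["z"] & df$z <= bb$max["z"]))
      stopf("object centers lie outside the phantom bounding box")
  }
  invisible(geom)
}

#' @export
print.phantom_geometry <- function(x, ...) {
  bb <- geometry_bbox(x)
  cat("DBT QA phantom geometry (schema ", x$schema_version, ")\n", sep = "")
  cat(sprintf("  extent: x [%g, %g], y [0, %g], z [0, %g] mm\n",
              bb$min["x"], bb$max["x"], x$depth, x$overall_thickness))
  cat(sprintf("  %d step gauges (%d x %.2g mm), 2 folded bead ramps (%.2f mm beads)\n",
              length(x$gauges), x$gauges[[1]]$n_steps,
              x$gauges[[1]]$step_increment, x$ramps[[1]]$bead_diameter))
  cat(sprintf("  %d z-geometry beads (d = %g mm), %d low-contrast spheres (%g-%g mm)\n",
              nrow(x$z_beads), x$z_beads$diameter[1],
              nrow(x$low_contrast_spheres),
              min(x$low_contrast_spheres$diameter),
              max(x$low_contrast_spheres$diameter)))
  cat(sprintf("  Al square %g mm at (%g, %g), %d alignment markers\n",
              x$al_square$side, x$al_square$center["x"],
              x$al_square$center["y"], nrow(x$alignment_markers)))
  invisible(x)
}

## ---- JSON serialization (versioned schema) ---------------------------------

#' Write a phantom geometry to JSON
#' @param geometry a \code{phantom_geometry}.
#' @param path file path.
#' @export
write_geometry <- function(geometry, path) {
  validate_geometry(geometry)
  x <- unclass(geometry)
  x$gauges <- lapply(x$gauges, unclass)
  x$ramps <- lapply(x$ramps, unclass)
  x$al_square <- list(center = as.numeric(x$al_square$center),
                      side = x$al_square$side,
                      thickness = x$al_square$thickness,
                      contrast = x$al_square$contrast)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a phantom geometry from JSON
#' @param path file path written by \code{\link{write_geometry}} (or the
#'   bundled default at
#'   \code{system.file("extdata", "default_geometry.json", package = "tomoqa")}).
#' @export
read_geometry <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$schema_version))
    stopf("not a phantom geometry file (missing schema_version): %s", path)
  x$gauges <- lapply(seq_len(nrow(x$gauges)), function(i) {
    g <- as.list(x$gauges[i, ])
    do.call(step_gauge, g)
  })
  x$ramps <- lapply(seq_len(nrow(x$ramps)), function(i) {
    do.call(bead_ramp, as.list(x$ramps[i, ]))
  })
  x$al_square <- list(
    center = c(x = x$al_square$center[1], y = x$al_square$center[2],
               z = x$al_square$center[3]),
    side = x$al_square$side, thickness = x$al_square$thickness,
    contrast = x$al_square$contrast)
  class(x) <- "phantom_geometry"
  validate_geometry(x)
  x
}

## ---- object footprints (for ROI clearance checks) --------------------------

# Returns a data.frame of in-plane footprints: type ("disc"/"rect"),
# x, y, rx, ry (half extents / radius), label. Used to verify that uniformity
# and contrast-detail ROIs avoid every test object.
object_footprints <- function(geometry) {
  out <- list()
  for (g in geometry$gauges) {
    out[[length(out) + 1L]] <- data.frame(
      type = "rect", x = g$lateral_position, y = gauge_extent(g) / 2,
      rx = g$width / 2, ry = gauge_extent(g) / 2, label = g$id)
  }
  for (r in geometry$ramps) {
    bp <- bead_positions(r)
    out[[length(out) + 1L]] <- data.frame(
      type = "rect", x = mean(range(bp$x)), y = mean(range(bp$y)),
      rx = diff(range(bp$x)) / 2 + r$bead_diameter,
      ry = diff(range(bp$y)) / 2 + r$bead_diameter,
      label = paste0("ramp_", r$side))
  }
  zb <- geometry$z_beads
  out[[length(out) + 1L]] <- data.frame(
    type = "disc", x = zb$x, y = zb$y, rx = zb$diameter / 2,
    ry = zb$diameter / 2, label = paste0("z_bead", seq_len(nrow(zb))))
  sp <- geometry$low_contrast_spheres
  out[[length(out) + 1L]] <- data.frame(
    type = "disc", x = sp$x, y = sp$y, rx = sp$diameter / 2,
    ry = sp$diameter / 2, label = paste0("sphere_", sp$diameter, "mm"))
  sq <- geometry$al_square
  out[[length(out) + 1L]] <- data.frame(
    type = "rect", x = sq$center[["x"]], y = sq$center[["y"]],
    rx = sq$side / 2, ry = sq$side / 2, label = "al_square")
  mk <- geometry$alignment_markers
  out[[length(out) + 1L]] <- data.frame(
    type = "disc", x = mk$x, y = mk$y, rx = mk$diameter / 2,
    ry = mk$diameter / 2, label = paste0("marker", seq_len(nrow(mk))))
  do.call(rbind, out)
}

# distance from a point to a footprint (0 if inside)
footprint_distance <- function(px, py, fp) {
  if (fp$type == "disc") {
    max(0, sqrt((px - fp$x)^2 + (py - fp$y)^2) - fp$rx)
  } else {
    dx <- max(0, abs(px - fp$x) - fp$rx)
    dy <- max(0, abs(py - fp$y) - fp$ry)
    sqrt(dx^2 + dy^2)
  }
}

#' Check that a circular ROI is clear of all phantom objects
#'
#' Verifies that a disc ROI does not intersect any test-object footprint
#' dilated by a safety margin.
#'
#' @param x,y ROI center in phantom coordinates (mm).
#' @param radius ROI radius (mm).
#' @param geometry a \code{phantom_geometry}.
#' @param dilation_mm safety margin added around every object (default 2).
#' @return \code{TRUE} if clear, otherwise \code{FALSE} with attribute
#'   \code{"blocking"} naming the offending object(s).
#' @export
roi_is_clear <- function(x, y, radius, geometry, dilation_mm = 2) {
  fps <- object_footprints(geometry)
  bad <- character(0)
  for (i in seq_len(nrow(fps))) {
    if (footprint_distance(x, y, fps[i, ]) < radius + dilation_mm)
      bad <- c(bad, fps$label[i])
  }
  ok <- length(bad) == 0L
  if (!ok) attr(ok, "blocking") <- bad
  ok
}
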