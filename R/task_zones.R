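#' Task geometry for a reading condition
#'
#' Describes where the reading target sits relative to the observer and its
#' angular extent, plus the cohort-average pupil diameter used as a tolerance
#' when deriving theoretical zones.
#'
#' `target_distance_m` is the horizontal distance from the plane of the eye
#' rotation centers to the target. The vertical placement is given either as
#' an elevation angle or as a height above (+) / below (-) primary gaze, the
#' other being derived via `height = distance * tan(elevation)`.
#' `azimuth_offset_deg` is the head-relative horizontal angle of the target
#' center, positive toward the wearer's right — so a subject rotated
#' counterclockwise under a fixed screen sees the target at positive
#' azimuth.
#'
#' @param name condition label.
#' @param target_distance_m horizontal distance to the target, metres (> 0).
#' @param azimuth_offset_deg head-relative azimuth of the target center,
#'   degrees, wearer's-right positive.
#' @param elevation_offset_deg,target_height_m exactly one must be supplied.
#' @param angular_width_deg,angular_height_deg angular extent of the target
#'   rectangle, degrees (> 0; a 0 extent is allowed for degenerate
#'   single-point targets).
#' @param mean_pupil_diameter_mm cohort-average pupil diameter, mm, applied
#'   as a half-diameter margin on every zone edge.
#' @return object of class `task_geometry`.
#' @export
task_geometry <- function(name, target_distance_m,
                          azimuth_offset_deg = 0,
                          elevation_offset_deg = NULL,
                          target_height_m = NULL,
                          angular_width_deg, angular_height_deg,
                          mean_pupil_diameter_mm = 0) {
  stopifnot(target_distance_m > 0,
            angular_width_deg >= 0, angular_height_deg >= 0,
            mean_pupil_diameter_mm >= 0)
  if (is.null(elevation_offset_deg) == is.null(target_height_m))
    stop("supply exactly one of elevation_offset_deg / target_height_m")
  if (is.null(elevation_offset_deg)) {
    elevation_offset_deg <- rad2deg(atan(target_height_m / target_distance_m))
  } else {
    target_height_m <- target_distance_m * tan(deg2rad(elevation_offset_deg))
  }
  structure(list(name = name, target_distance_m = target_distance_m,
                 azimuth_offset_deg = azimuth_offset_deg,
                 elevation_offset_deg = elevation_offset_deg,
                 target_height_m = target_height_m,
                 angular_width_deg = angular_width_deg,
                 angular_height_deg = angular_height_deg,
                 mean_pupil_diameter_mm = mean_pupil_diameter_mm),
            class = "task_geometry")
}

#' @export
print.task_geometry <- function(x, ...) {
  cat(sprintf(paste0("<task_geometry> %s: %.2f m, az %+.1f deg, ",
                     "el %+.2f deg, %.1f x %.1f deg, pupil %.2f mm\n"),
              x$name, x$target_distance_m, x$azimuth_offset_deg,
              x$elevation_offset_deg, x$angular_width_deg,
              x$angular_height_deg, x$mean_pupil_diameter_mm))
  invisible(x)
}

#' Built-in reading-task conditions
#'
#' The six conditions of the distance/near reading protocol: a distance
#' screen 5.25 m away and 31.7 cm above primary gaze subtending
#' 4.2 x 2.3 degrees, viewed on-axis and at 10 and 15 degrees off-axis
#' (counterclockwise subject rotation, so positive azimuth); and a near
#' display at 0.37 m with three 3-degree-wide, 3.6-degree-tall text columns
#' at azimuths -12.5, 0 and +12.5 degrees. Cohort-average pupil diameters
#' are 3.73 mm (distance) and 2.88 mm (near).
#'
#' The near display's height relative to primary gaze is not part of the
#' protocol description; the default elevation of -20 degrees (typical
#' reading posture) is an assumption, exposed via `near_elevation_deg` and
#' always reported with zone output.
#'
#' @param near_elevation_deg elevation of the near text center, degrees.
#' @return named list of [task_geometry()] objects.
#' @export
task_presets <- function(near_elevation_deg = -20) {
  dist <- function(name, az) task_geometry(
    name, target_distance_m = 5.25, azimuth_offset_deg = az,
    target_height_m = 0.317, angular_width_deg = 4.2,
    angular_height_deg = 2.3, mean_pupil_diameter_mm = 3.73)
  near <- function(name, az) task_geometry(
    name, target_distance_m = 0.37, azimuth_offset_deg = az,
    elevation_offset_deg = near_elevation_deg, angular_width_deg = 3,
    angular_height_deg = 3.6, mean_pupil_diameter_mm = 2.88)
  list(distance_on = dist("distance_on", 0),
       distance_off10 = dist("distance_off10", 10),
       distance_off15 = dist("distance_off15", 15),
       near_left = near("near_left", -12.5),
       near_on = near("near_on", 0),
       near_right = near("near_right", 12.5))
}

#' Read a task file
#'
#' JSON with the unit-suffixed keys of [task_geometry()].
#'
#' @param path JSON file.
#' @return a [task_geometry()].
#' @export
read_task_file <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  args <- cfg[intersect(names(cfg), names(formals(task_geometry)))]
  do.call(task_geometry, args)
}

# target-center position in headset frame, mm
target_center_position <- function(task, z_cre) {
  d <- task$target_distance_m * 1000
  az <- deg2rad(task$azimuth_offset_deg)
  c(-d * sin(az), task$target_height_m * 1000, z_cre + d * cos(az))
}

# unit direction for (azimuth wearer's-right-positive, elevation), degrees
direction_from_angles <- function(azimuth_deg, elevation_deg) {
  az <- deg2rad(azimuth_deg); el <- deg2rad(elevation_deg)
  c(-sin(az) * cos(el), sin(el), cos(az) * cos(el))
}

#' Per-eye angles to the target center
#'
#' Angles of the line from one eye's center of rotation to the target
#' center, accounting for the eye's lateral `ipd/2` offset — this is what
#' makes near targets demand convergence and shifts each eye's zone nasally.
#'
#' @param task a [task_geometry()].
#' @param frame a [frame_geometry()].
#' @param eye `"left"` or `"right"`.
#' @param surface surface model locating the CRE plane; default
#'   [lens_plane()] at the frame's CRE-to-lens distance.
#' @param convergent if `FALSE`, ignore the eye's lateral offset and treat
#'   the target as at optical infinity in azimuth (both eyes get the
#'   head-relative angles). Default `TRUE`.
#' @return list with `azimuth_deg` (wearer's-right positive),
#'   `elevation_deg`, and `azimuth_nasal_deg` (nasal positive for the given
#'   eye).
#' @export
per_eye_target_angles <- function(task, frame, eye = c("right", "left"),
                                  surface = lens_plane(frame$cre_to_lens_mm),
                                  convergent = TRUE) {
  eye <- match.arg(eye)
  cre <- cre_position(frame, surface, eye)
  if (!convergent) cre[1] <- 0
  tc <- target_center_position(task, z_cre = cre[3])
  d <- tc - cre
  az <- rad2deg(atan2(-d[1], d[3]))
  el <- rad2deg(atan2(d[2], sqrt(d[1]^2 + d[3]^2)))
  nasal <- if (eye == "right") -az else +az
  list(azimuth_deg = az, elevation_deg = el, azimuth_nasal_deg = nasal)
}

#' Theoretical zone of use on the lens
#'
#' The expected on-lens footprint of a task: sight lines are cast from the
#' eye's center of rotation toward the four corners of the target rectangle
#' (per-eye center angles plus/minus half the angular extents), intersected
#' with the lens surface, expressed relative to the fitting cross, and the
#' bounding rectangle is expanded on every edge by half the cohort-average
#' pupil diameter — the finite pupil aperture widens the bundle of
#' viewing-through points symmetrically.
#'
#' @inheritParams per_eye_target_angles
#' @param surface a [lens_plane()] or [lens_sphere()].
#' @return object of class `theoretical_zone`: `condition`, `eye`,
#'   `x_min`/`x_max`/`y_min`/`y_max` (mm, signed headset convention,
#'   relative to fitting cross), `x_nasal_min`/`x_nasal_max`
#'   (nasal-positive), `margin_mm`.
#' @export
theoretical_zone <- function(task, frame, eye = c("right", "left"),
                             surface = lens_plane(frame$cre_to_lens_mm),
                             convergent = TRUE) {
  eye <- match.arg(eye)
  ang <- per_eye_target_angles(task, frame, eye, surface, convergent)
  cre <- cre_position(frame, surface, eye)
  hw <- task$angular_width_deg / 2
  hh <- task$angular_height_deg / 2
  corners <- expand.grid(daz = c(-hw, hw), del = c(-hh, hh))
  pts <- lapply(seq_len(nrow(corners)), function(i) {
    v <- direction_from_angles(ang$azimuth_deg + corners$daz[i],
                               ang$elevation_deg + corners$del[i])
    hit <- tryCatch(intersect_gaze_with_surface(cre, v, surface),
                    lensuse_no_intersection = function(e)
                      stop("zone undefined: corner sight line (",
                           task$name, ", ", eye, ") misses the surface"))
    to_fitting_cross_frame(hit, frame, eye)
  })
  pts <- do.call(rbind, pts)
  m <- task$mean_pupil_diameter_mm / 2
  x_min <- min(pts$x_mm) - m; x_max <- max(pts$x_mm) + m
  y_min <- min(pts$y_mm) - m; y_max <- max(pts$y_mm) + m
  xn <- if (eye == "right") c(x_min, x_max) else c(-x_max, -x_min)
  structure(list(condition = task$name, eye = eye,
                 x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max,
                 x_nasal_min = xn[1], x_nasal_max = xn[2],
                 margin_mm = m),
            class = "theoretical_zone")
}

#' @export
print.theoretical_zone <- function(x, ...) {
  cat(sprintf(paste0("<theoretical_zone> %s / %s eye: x [%.2f, %.2f] mm, ",
                     "y [%.2f, %.2f] mm (margin %.2f mm)\n"),
              x$condition, x$eye, x$x_min, x$x_max, x$y_min, x$y_max,
              x$margin_mm))
  invisible(x)
}

#' Center of a theoretical zone
#'
#' @param zone a [theoretical_zone()].
#' @return named numeric `c(x, y)`, mm relative to the fitting cross.
#' @export
zone_center <- function(zone) {
  c(x = (zone$x_min + zone$x_max) / 2, y = (zone$y_min + zone$y_max) / 2)
}

#' Tabulate zones as a data.frame
#'
#' @param zones list of [theoretical_zone()] objects.
#' @return data.frame, one row per zone, signed and nasal-positive bounds.
#' @export
zones_table <- function(zones) {
  do.call(rbind, lapply(zones, function(z)
    data.frame(condition = z$condition, eye = z$eye,
               x_min = z$x_min, x_max = z$x_max,
               y_min = z$y_min, y_max = z$y_max,
               x_nasal_min = z$x_nasal_min, x_nasal_max = z$x_nasal_max,
               margin_mm = z$margin_mm, stringsAsFactors = FALSE)))
}
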