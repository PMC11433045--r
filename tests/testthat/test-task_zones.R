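# closed-form oracle for on-plane coordinates of a sight line from the CRE
# at (azimuth az wearer's-right-positive, elevation el), lever arm L:
#   x = -L * tan(az), y = L * tan(el) / cos(az), relative to the CRE axis
oracle_xy <- function(az_deg, el_deg, L) {
  az <- az_deg * pi / 180; el <- el_deg * pi / 180
  c(x = -L * tan(az), y = L * tan(el) / cos(az))
}

test_that("per-eye target angles: convergence and the cyclops limit", {
  fr <- test_frame(ipd = 62)
  dist_on <- task_presets()$distance_on
  near_on <- task_presets()$near_on
  a <- per_eye_target_angles(dist_on, fr, "right")
  expect_equal(a$azimuth_nasal_deg, atan(0.031 / 5.25) * 180 / pi,
               tolerance = 1e-9)
  b <- per_eye_target_angles(near_on, fr, "left")
  expect_equal(b$azimuth_nasal_deg, atan(31 / 370) * 180 / pi,
               tolerance = 1e-9)
  # both eyes converge nasally for an on-axis target
  expect_gt(per_eye_target_angles(near_on, fr, "right")$azimuth_nasal_deg, 0)
  expect_gt(b$azimuth_nasal_deg, 0)
  # ipd = 0: per-eye azimuth equals the head-relative offset exactly
  fr0 <- test_frame(ipd = 0)
  off <- task_presets()$distance_off15
  a0 <- per_eye_target_angles(off, fr0, "right")
  expect_equal(a0$azimuth_deg, 15, tolerance = 1e-9)
  # non-convergent mode ignores the lateral offset
  anc <- per_eye_target_angles(near_on, fr, "right", convergent = FALSE)
  expect_equal(anc$azimuth_deg, 0, tolerance = 1e-9)
})

test_that("degenerate task collapses the zone onto the primary-gaze pierce point", {
  fr <- test_frame()
  task <- task_geometry("pt", 5.25, azimuth_offset_deg = 0,
                        elevation_offset_deg = 0,
                        angular_width_deg = 0, angular_height_deg = 0,
                        mean_pupil_diameter_mm = 0)
  z <- theoretical_zone(task, test_frame(ipd = 0), "right",
                        lens_plane(fr$cre_to_lens_mm))
  expect_equal(unname(zone_center(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(z$x_min, z$x_max, tolerance = 1e-12)
})

test_that("distance on-axis zone bounds match the trigonometric oracle", {
  fr <- test_frame(ipd = 62)
  task <- task_presets()$distance_on
  z <- theoretical_zone(task, fr, "right")
  ang <- per_eye_target_angles(task, fr, "right")
  L <- fr$cre_to_lens_mm
  m <- task$mean_pupil_diameter_mm / 2
  expect_equal(m, 3.73 / 2)
  corners <- expand.grid(az = ang$azimuth_deg + c(-2.1, 2.1),
                         el = ang$elevation_deg + c(-1.15, 1.15))
  xy <- t(mapply(oracle_xy, corners$az, corners$el, MoreArgs = list(L = L)))
  # oracle x is relative to the CRE axis = fitting-cross position
  expect_equal(z$x_min, min(xy[, 1]) - m, tolerance = 1e-9)
  expect_equal(z$x_max, max(xy[, 1]) + m, tolerance = 1e-9)
  expect_equal(z$y_min, min(xy[, 2]) - m, tolerance = 1e-9)
  expect_equal(z$y_max, max(xy[, 2]) + m, tolerance = 1e-9)
  # and for a zero-width cyclops target the y-bounds reduce to
  # L * tan(el +/- h/2) exactly (no off-azimuth sec factor)
  fr0 <- test_frame(ipd = 0)
  task0 <- task_geometry("narrow", 5.25, target_height_m = 0.317,
                         angular_width_deg = 0, angular_height_deg = 2.3,
                         mean_pupil_diameter_mm = 3.73)
  z0 <- theoretical_zone(task0, fr0, "right")
  el <- atan(0.317 / 5.25) * 180 / pi
  expect_equal(z0$y_min, L * tan((el - 1.15) * pi / 180) - m,
               tolerance = 1e-9)
  expect_equal(z0$y_max, L * tan((el + 1.15) * pi / 180) + m,
               tolerance = 1e-9)
})

test_that("pupil margin is linear: doubling the diameter widens each side by d/2", {
  fr <- test_frame()
  t1 <- task_presets()$near_on
  t2 <- t1; t2$mean_pupil_diameter_mm <- 2 * t1$mean_pupil_diameter_mm
  z1 <- theoretical_zone(t1, fr, "right")
  z2 <- theoretical_zone(t2, fr, "right")
  d <- t1$mean_pupil_diameter_mm
  expect_equal((z2$x_max - z2$x_min) - (z1$x_max - z1$x_min), d,
               tolerance = 1e-12)
  expect_equal((z2$y_max - z2$y_min) - (z1$y_max - z1$y_min), d,
               tolerance = 1e-12)
})

test_that("on-axis zones are mirror images in nasal-positive coordinates", {
  fr <- test_frame()
  for (task in task_presets()[c("distance_on", "near_on")]) {
    zr <- theoretical_zone(task, fr, "right")
    zl <- theoretical_zone(task, fr, "left")
    expect_equal(zr$x_nasal_min, zl$x_nasal_min, tolerance = 1e-9)
    expect_equal(zr$x_nasal_max, zl$x_nasal_max, tolerance = 1e-9)
    expect_equal(zr$y_min, zl$y_min, tolerance = 1e-9)
  }
})

test_that("near on-axis zones sit nasal of distance on-axis zones (convergence)", {
  fr <- test_frame()
  tp <- task_presets()
  for (eye in c("right", "left")) {
    zd <- theoretical_zone(tp$distance_on, fr, eye)
    zn <- theoretical_zone(tp$near_on, fr, eye)
    cd <- (zd$x_nasal_min + zd$x_nasal_max) / 2
    cn <- (zn$x_nasal_min + zn$x_nasal_max) / 2
    expect_gt(cn, cd)
  }
})

test_that("off-axis distance zones shift temporal-right / nasal-left, more at 15 than 10", {
  fr <- test_frame()
  tp <- task_presets()
  nasal_center <- function(task, eye) {
    z <- theoretical_zone(task, fr, eye)
    (z$x_nasal_min + z$x_nasal_max) / 2
  }
  for (eye in c("right", "left")) {
    c0 <- nasal_center(tp$distance_on, eye)
    c10 <- nasal_center(tp$distance_off10, eye)
    c15 <- nasal_center(tp$distance_off15, eye)
    if (eye == "right") expect_true(c15 < c10 && c10 < c0)  # temporal shift
    else expect_true(c15 > c10 && c10 > c0)                  # nasal shift
  }
})

test_that("vertical bounds barely move across distance azimuth conditions", {
  # exact 3D geometry gives a small sec(azimuth) vertical inflation off-axis;
  # it must stay far below the pupil-diameter tolerance of the zones
  fr <- test_frame()
  tp <- task_presets()
  z0 <- theoretical_zone(tp$distance_on, fr, "right")
  z15 <- theoretical_zone(tp$distance_off15, fr, "right")
  expect_lt(abs(z15$y_min - z0$y_min), 0.2)
  expect_lt(abs(z15$y_max - z0$y_max), 0.2)
  expect_gt(z0$margin_mm, 1)
})

test_that("task files round trip and validate", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "custom", target_distance_m = 2,
                            azimuth_offset_deg = 5, target_height_m = 0.1,
                            angular_width_deg = 10, angular_height_deg = 4,
                            mean_pupil_diameter_mm = 3),
                       path, auto_unbox = TRUE)
  task <- read_task_file(path)
  expect_s3_class(task, "task_geometry")
  expect_equal(task$elevation_offset_deg, atan(0.05) * 180 / pi)
  expect_error(task_geometry("bad", 1, elevation_offset_deg = 0,
                             target_height_m = 0, angular_width_deg = 1,
                             angular_height_deg = 1), "exactly one")
  expect_error(task_geometry("bad", 0, elevation_offset_deg = 0,
                             angular_width_deg = 1, angular_height_deg = 1))
})
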