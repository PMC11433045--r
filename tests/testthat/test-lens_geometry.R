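test_that("plane intersection matches the closed-form parametric oracle", {
  # axial ray
  p1 <- intersect_gaze_with_surface(c(0, 0, 0), c(0, 0, 1), lens_plane(25))
  expect_equal(as.numeric(p1), c(0, 0, 25), tolerance = 1e-12)
  # oblique ray: t = (z0 - pz)/vz by substitution
  v <- c(0.1, -0.2, 1) / sqrt(sum(c(0.1, -0.2, 1)^2))
  p <- c(1, 2, 0)
  hit <- intersect_gaze_with_surface(p, v, lens_plane(30))
  t_oracle <- 30 / v[3]
  expect_equal(as.numeric(hit), p + t_oracle * v, tolerance = 1e-9)
  expect_equal(hit[3], 30, tolerance = 1e-9)
})

test_that("sphere intersection matches a bisection oracle", {
  center <- c(0, 0, 92); radius <- 80
  v <- c(sin(5 * pi / 180), 0, cos(5 * pi / 180))
  hit <- intersect_gaze_with_surface(c(0, 0, 0), v, lens_sphere(center, radius))
  t_or <- bisect_sphere_t(c(0, 0, 0), v, center, radius, t_hi = 100)
  expect_equal(attr(hit, "t"), t_or, tolerance = 1e-6)
  expect_equal(abs(sqrt(sum((as.numeric(hit) - center)^2)) - radius), 0,
               tolerance = 1e-6)
})

test_that("degenerate rays raise no-intersection errors", {
  expect_error(intersect_gaze_with_surface(c(0, 0, 0), c(0, 1, 0),
                                           lens_plane(25)),
               class = "lensuse_no_intersection")
  expect_error(intersect_gaze_with_surface(c(0, 0, 30), c(0, 0, 1),
                                           lens_plane(25)),
               class = "lensuse_no_intersection")
  expect_error(intersect_gaze_with_surface(c(200, 0, 0), c(0, 0, 1),
                                           lens_sphere(c(0, 0, 92), 80)),
               class = "lensuse_no_intersection")
  expect_error(intersect_gaze_with_surface(c(0, 0, 0), c(0, 0, 2),
                                           lens_plane(25)), "unit")
})

test_that("fitting-cross frame re-expression and nasal sign bookkeeping", {
  fr <- test_frame()
  fc_r <- fr$fitting_cross_right_mm
  # point exactly at the right fitting cross -> (0, 0)
  p <- to_fitting_cross_frame(c(fc_r[1], fc_r[2], 25.5), fr, "right")
  expect_equal(c(p$x_mm, p$y_mm, p$x_nasal_mm), c(0, 0, 0))
  # 3 mm above -> (0, +3)
  p <- to_fitting_cross_frame(c(fc_r[1], fc_r[2] + 3, 25.5), fr, "right")
  expect_equal(c(p$x_mm, p$y_mm), c(0, 3))
  # left eye, 2 mm toward the nose (nose at x ~ 0, left eye at +ipd/2,
  # so nasal displacement is -x): x = -2, x_nasal = +2
  fc_l <- fr$fitting_cross_left_mm
  p <- to_fitting_cross_frame(c(fc_l[1] - 2, fc_l[2], 25.5), fr, "left")
  expect_equal(p$x_mm, -2)
  expect_equal(p$x_nasal_mm, 2)
})

test_that("project_fixations: axial hit, determinism, trig oracle, failures kept", {
  fr <- test_frame(); su <- test_surface(fr)
  cre <- cre_position(fr, su, "right")
  axial <- data.frame(eye = "right", t_start = 0, t_end = 1, duration = 1,
                      n_samples = 50, gx = 0, gy = 0, gz = 1,
                      px = cre[1], py = cre[2], pz = cre[3],
                      stringsAsFactors = FALSE)
  pts <- project_fixations(axial, fr, su)
  expect_equal(c(pts$x_mm, pts$y_mm), c(0, 0), tolerance = 1e-12)
  # 10 identical fixations -> 10 identical points
  pts10 <- project_fixations(axial[rep(1, 10), ], fr, su)
  expect_equal(nrow(pts10), 10)
  expect_equal(var(pts10$x_mm), 0)
  # pure-elevation sight line at atan(0.317/5.25): y = cre_to_lens * tan(el)
  el <- atan(0.317 / 5.25)
  fx <- axial
  fx$gy <- sin(el); fx$gz <- cos(el)
  pts <- project_fixations(fx, fr, su)
  expect_equal(pts$y_mm, fr$cre_to_lens_mm * tan(el), tolerance = 1e-6)
  expect_equal(pts$x_mm, 0, tolerance = 1e-9)
  # a fixation aimed away from the lens is flagged, not dropped
  bad <- axial; bad$gz <- -1
  expect_warning(ptsb <- project_fixations(rbind(axial, bad), fr, su),
                 "no surface intersection")
  expect_equal(nrow(ptsb), 2)
  expect_equal(ptsb$ok, c(TRUE, FALSE))
})

test_that("plane and sphere agree in the large-radius limit", {
  fr <- test_frame()
  plane <- lens_plane(25.5)
  R <- 1e6
  sph <- lens_sphere(c(0, 0, 25.5 + R), R)
  set.seed(3)
  for (i in 1:50) {
    v <- unlist(dir_at(runif(1, -15, 15), runif(1, -15, 15)))
    p <- c(runif(1, -35, 35), runif(1, -5, 5), 0)
    h1 <- as.numeric(intersect_gaze_with_surface(p, v, plane))
    h2 <- as.numeric(intersect_gaze_with_surface(p, v, sph))
    expect_lt(sqrt(sum((h1 - h2)^2)), 1e-3)
  }
})

test_that("mirror symmetry across the midline", {
  fr <- test_frame(); su <- test_surface(fr)
  set.seed(4)
  for (i in 1:20) {
    v <- dir_at(runif(1, -10, 10), runif(1, -10, 10))
    p <- c(runif(1, -35, -27), runif(1, -3, 3), 0)
    a <- to_fitting_cross_frame(
      as.numeric(intersect_gaze_with_surface(p, v, su)), fr, "right")
    vm <- v * c(-1, 1, 1); pm <- p * c(-1, 1, 1)
    b <- to_fitting_cross_frame(
      as.numeric(intersect_gaze_with_surface(pm, vm, su)), fr, "left")
    expect_equal(b$x_mm, -a$x_mm, tolerance = 1e-9)
    expect_equal(b$y_mm, a$y_mm, tolerance = 1e-9)
    expect_equal(b$x_nasal_mm, a$x_nasal_mm, tolerance = 1e-9)
  }
})

test_that("rotation toward the wearer's right is temporal on the right lens, nasal on the left", {
  fr <- test_frame(); su <- test_surface(fr)
  v <- dir_at(8, 0)   # 8 deg toward the wearer's right
  for (eye in c("right", "left")) {
    cre <- cre_position(fr, su, eye)
    p <- to_fitting_cross_frame(
      as.numeric(intersect_gaze_with_surface(cre, v, su)), fr, eye)
    if (eye == "right") expect_lt(p$x_nasal_mm, 0)  # temporal
    else expect_gt(p$x_nasal_mm, 0)                 # nasal
  }
})

test_that("angular_to_lens_mm is lever * tan(angle) with a guarded domain", {
  expect_equal(angular_to_lens_mm(0, 32.5), 0)
  expect_equal(angular_to_lens_mm(1, 30), 30 * tan(pi / 180),
               tolerance = 1e-12)
  # note: 30 * tan(1 deg) = 0.52365, i.e. 0.5237 at 4 decimals; the
  # small-angle value 0.5236 is only the radian approximation
  expect_error(angular_to_lens_mm(90, 30), "< 90")
  expect_error(angular_to_lens_mm(0.5, -1))
})
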