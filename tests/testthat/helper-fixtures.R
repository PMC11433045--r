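# Shared fixture builders. Everything is generated in code; no stored data.

# sample grid for one eye looking along `dir` (recycled row-wise if a matrix)
make_samples <- function(n, eye = "right", dir = c(0, 0, 1),
                         t0 = 0, rate = 50, pupil = 3.5, valid = TRUE,
                         pupil_pos = c(-31, 0, -11)) {
  dirm <- if (is.matrix(dir)) dir else matrix(dir, n, 3, byrow = TRUE)
  data.frame(t = t0 + (seq_len(n) - 1) / rate, eye = eye,
             px = pupil_pos[1], py = pupil_pos[2], pz = pupil_pos[3],
             gx = dirm[, 1], gy = dirm[, 2], gz = dirm[, 3],
             pupil_mm = pupil, valid = valid, stringsAsFactors = FALSE)
}

# unit direction at (azimuth wearer's-right-positive, elevation) degrees
dir_at <- function(az_deg, el_deg) {
  az <- az_deg * pi / 180; el <- el_deg * pi / 180
  c(-sin(az) * cos(el), sin(el), cos(az) * cos(el))
}

# a recording with a controlled number of valid samples on a full grid
make_loss_recording <- function(n_expected, n_valid, rate = 50,
                                eye = "right") {
  s <- make_samples(n_expected, eye = eye, rate = rate)
  if (n_valid < n_expected)
    s$valid[seq(n_valid + 1, n_expected)] <- FALSE
  gaze_recording(s, sample_rate_hz = rate, duration_s = n_expected / rate)
}

# hand-built rectangular zone for containment tests
make_zone <- function(x_min, x_max, y_min, y_max, eye = "right",
                      condition = "test") {
  xn <- if (eye == "right") c(x_min, x_max) else c(-x_max, -x_min)
  structure(list(condition = condition, eye = eye,
                 x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 x_nasal_min = xn[1], x_nasal_max = xn[2], margin_mm = 0),
            class = "theoretical_zone")
}

# default geometry used across tests
test_frame <- function(ipd = 62) frame_geometry(ipd_mm = ipd)
test_surface <- function(frame = test_frame()) lens_plane(frame$cre_to_lens_mm)

# bisection oracle for ray-sphere intersection: smallest positive root of
# ||p + t v - c|| - R, bracketing from t = 0 outward
bisect_sphere_t <- function(p, v, center, radius, t_hi = 1e5, tol = 1e-10) {
  f <- function(t) sqrt(sum((p + t * v - center)^2)) - radius
  ts <- seq(0, t_hi, length.out = 20000)
  fs <- vapply(ts, f, numeric(1))
  i <- which(fs[-1] * fs[-length(fs)] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  lo <- ts[i]; hi <- ts[i + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
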