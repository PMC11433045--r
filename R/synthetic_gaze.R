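#' Simulation scenario for synthetic gaze recordings
#'
#' Describes a reading-like recording session to synthesize: the task and
#' frame geometry, duration and sample rate, the tracker noise model, and
#' the data-loss rate.
#'
#' The noise model has two parts, both in degrees at the eye:
#' `accuracy_bias_deg` is a systematic rotation of every gaze direction by a
#' fixed magnitude in a fixed (per-scenario, by default randomly drawn)
#' direction — the tracker's accuracy; `precision_sd_deg` is independent
#' per-sample angular jitter with that root-mean-square magnitude — the
#' tracker's precision. Defaults 0.6 and 0.03 degrees match the device-class
#' figures the pipeline's error budget uses. Samples are flagged invalid
#' independently with probability `data_loss_p`.
#'
#' The scanpath model is deliberately simple: `"sweep"` walks fixation
#' targets left-to-right along `n_lines` text lines covering the task
#' rectangle (geometric coverage, not oculomotor realism), `"central"` holds
#' every fixation on the task center (the noiseless-recovery scenario).
#' Fixation durations are exponential with mean `mean_fixation_s`, clipped
#' to `[0.08, 1]` s.
#'
#' @param task a [task_geometry()].
#' @param frame a [frame_geometry()].
#' @param duration_s,sample_rate_hz recording length and rate; 50 Hz default.
#' @param accuracy_bias_deg,precision_sd_deg noise magnitudes, degrees.
#' @param bias_direction_deg direction of the accuracy bias in the plane
#'   normal to the gaze (degrees); `NULL` (default) draws it from the seeded
#'   RNG, one value per simulated recording.
#' @param data_loss_p per-sample invalid probability in `[0, 1)`.
#' @param mean_fixation_s mean fixation duration, seconds.
#' @param scanpath `"sweep"` or `"central"`.
#' @param n_lines text lines for the sweep scanpath.
#' @param pupil_offset_mm distance from the CRE to the simulated pupil
#'   along the gaze direction (approximate CRE-to-entrance-pupil distance).
#' @param surface lens surface the truth table is computed against.
#' @param subject_id,condition_id labels for the emitted recording.
#' @param seed integer seed; simulation refuses to run without one
#'   (reproducibility contract).
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(task, frame,
                                duration_s = 20, sample_rate_hz = 50,
                                accuracy_bias_deg = 0.6,
                                bias_direction_deg = NULL,
                                precision_sd_deg = 0.03,
                                data_loss_p = 0,
                                mean_fixation_s = 0.25,
                                scanpath = c("sweep", "central"),
                                n_lines = 5,
                                pupil_offset_mm = 11,
                                surface = lens_plane(frame$cre_to_lens_mm),
                                subject_id = "SIM", condition_id = task$name,
                                seed = NULL) {
  scanpath <- match.arg(scanpath)
  stopifnot(inherits(task, "task_geometry"), inherits(frame, "frame_geometry"),
            duration_s > 0, sample_rate_hz > 0,
            accuracy_bias_deg >= 0, precision_sd_deg >= 0,
            data_loss_p >= 0, data_loss_p < 1,
            mean_fixation_s > 0, n_lines >= 1, pupil_offset_mm >= 0)
  structure(list(task = task, frame = frame, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz,
                 accuracy_bias_deg = accuracy_bias_deg,
                 bias_direction_deg = bias_direction_deg,
                 precision_sd_deg = precision_sd_deg,
                 data_loss_p = data_loss_p,
                 mean_fixation_s = mean_fixation_s,
                 scanpath = scanpath, n_lines = n_lines,
                 pupil_offset_mm = pupil_offset_mm, surface = surface,
                 subject_id = subject_id, condition_id = condition_id,
                 seed = seed),
            class = "simulation_scenario")
}

# rotate unit vector v by theta_deg toward direction phi_deg in its normal plane
rotate_direction <- function(v, theta_deg, phi_deg) {
  if (theta_deg == 0) return(v)
  up <- if (abs(v[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
  e1 <- unitize(c(v[2] * up[3] - v[3] * up[2],
                  v[3] * up[1] - v[1] * up[3],
                  v[1] * up[2] - v[2] * up[1]))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  cos(th) * v + sin(th) * (cos(ph) * e1 + sin(ph) * e2)
}

# exponential fixation schedule filling [0, duration]; data.frame with spans
fixation_schedule <- function(duration_s, mean_fixation_s) {
  t <- 0; starts <- numeric(); ends <- numeric()
  while (t < duration_s) {
    d <- min(max(stats::rexp(1, rate = 1 / mean_fixation_s), 0.08), 1)
    starts <- c(starts, t)
    ends <- c(ends, min(t + d, duration_s))
    t <- t + d
  }
  data.frame(fixation = seq_along(starts), t_start = starts, t_end = ends)
}

# head-relative target angles for each scheduled fixation
scanpath_angles <- function(sc, n_fix) {
  task <- sc$task
  if (sc$scanpath == "central" || n_fix == 1) {
    return(data.frame(az = rep(task$azimuth_offset_deg, n_fix),
                      el = rep(task$elevation_offset_deg, n_fix)))
  }
  pos <- (seq_len(n_fix) - 0.5) / n_fix
  line <- pmin(floor(pos * sc$n_lines), sc$n_lines - 1)
  within <- pos * sc$n_lines - line
  data.frame(
    az = task$azimuth_offset_deg + (within - 0.5) * task$angular_width_deg,
    el = task$elevation_offset_deg +
      (0.5 - (line + 0.5) / sc$n_lines) * task$angular_height_deg)
}

#' Simulate a binocular gaze recording
#'
#' Generates true per-eye gaze directions from each eye's center of rotation
#' to the scanpath targets (convergent — each eye gets its own angle),
#' applies the accuracy bias and per-sample precision jitter, places the
#' simulated pupil `pupil_offset_mm` along the current gaze direction, and
#' flags samples invalid with probability `data_loss_p`. Identical scenario
#' and seed give a bit-identical recording.
#'
#' The ground truth (scheduled fixation spans, head-relative target angles,
#' and the noise-free on-lens intersection per fixation and eye) is attached
#' as attribute `"truth"`.
#'
#' @param sc a [simulation_scenario()] with a non-`NULL` seed.
#' @return a [gaze_recording()] with a `"truth"` attribute.
#' @export
simulate_recording <- function(sc) {
  if (is.null(sc$seed)) stop("simulation requires an explicit seed")
  with_local_seed(sc$seed, simulate_recording_impl(sc))
}

simulate_recording_impl <- function(sc, fixed_dir = NULL) {
  frame <- sc$frame; surface <- sc$surface
  bias_phi <- sc$bias_direction_deg %||% stats::runif(1, 0, 360)
  sched <- fixation_schedule(sc$duration_s, sc$mean_fixation_s)
  ang <- scanpath_angles(sc, nrow(sched))
  d_mm <- sc$task$target_distance_m * 1000
  n_samp <- round(sc$duration_s * sc$sample_rate_hz)
  t_grid <- (seq_len(n_samp) - 1) / sc$sample_rate_hz
  fix_of <- findInterval(t_grid, sched$t_start)
  eyes <- c("right", "left")
  truth <- list(); rows <- list()
  for (eye in eyes) {
    cre <- cre_position(frame, surface, eye)
    # per-fixation true directions
    dirs <- lapply(seq_len(nrow(sched)), function(k) {
      if (!is.null(fixed_dir)) return(fixed_dir[[eye]])
      az <- deg2rad(ang$az[k])
      tgt <- c(-d_mm * sin(az), d_mm * tan(deg2rad(ang$el[k])),
               cre[3] + d_mm * cos(az))
      unitize(tgt - cre)
    })
    hits <- vapply(dirs, function(v) {
      p <- to_fitting_cross_frame(intersect_gaze_with_surface(cre, v, surface),
                                  frame, eye)
      c(p$x_mm, p$y_mm)
    }, numeric(2))
    truth[[eye]] <- data.frame(sched, eye = eye, az_deg = ang$az,
                               el_deg = ang$el, lens_x_mm = hits[1, ],
                               lens_y_mm = hits[2, ],
                               stringsAsFactors = FALSE)
    biased <- lapply(dirs, rotate_direction, theta_deg = sc$accuracy_bias_deg,
                     phi_deg = bias_phi)
    jit <- matrix(stats::rnorm(2 * n_samp, 0, sc$precision_sd_deg / sqrt(2)),
                  ncol = 2)
    lost <- stats::runif(n_samp) < sc$data_loss_p
    g <- matrix(NA_real_, n_samp, 3); p <- matrix(NA_real_, n_samp, 3)
    for (i in seq_len(n_samp)) {
      v <- biased[[fix_of[i]]]
      theta <- sqrt(jit[i, 1]^2 + jit[i, 2]^2)
      phi <- rad2deg(atan2(jit[i, 2], jit[i, 1]))
      v <- unitize(rotate_direction(v, theta, phi))
      g[i, ] <- v
      p[i, ] <- cre + sc$pupil_offset_mm * v
    }
    g[lost, ] <- NA_real_; p[lost, ] <- NA_real_
    rows[[eye]] <- data.frame(
      t = t_grid, eye = eye,
      px = p[, 1], py = p[, 2], pz = p[, 3],
      gx = g[, 1], gy = g[, 2], gz = g[, 3],
      pupil_mm = ifelse(lost, NA_real_, sc$task$mean_pupil_diameter_mm),
      valid = !lost, stringsAsFactors = FALSE)
  }
  rec <- gaze_recording(do.call(rbind, rows), subject_id = sc$subject_id,
                        condition_id = sc$condition_id,
                        sample_rate_hz = sc$sample_rate_hz,
                        duration_s = sc$duration_s)
  attr(rec, "truth") <- do.call(rbind, truth)
  attr(rec, "bias_direction_deg") <- bias_phi
  rec
}

#' Simulate the pinhole validity-check experiment
#'
#' Reproduces the pilot validation setup: a pinhole attached to the right
#' lens forces every sight line through one known on-lens point, the left
#' eye being occluded. All true right-eye gaze directions pass through the
#' pinhole; the tracker noise model of the scenario is applied on top. The
#' recording's known truth (the pinhole position in fitting-cross
#' coordinates) enables the horizontal/vertical measurement-error metric.
#'
#' @param pinhole_pos length-2 `(x, y)` position of the pinhole relative to
#'   the right-eye fitting cross, mm.
#' @param sc a [simulation_scenario()]; only the right eye of the output is
#'   meaningful (the left eye is emitted all-invalid, mirroring occlusion).
#' @return list with `recording` (a [gaze_recording()]), `truth`
#'   (the pinhole lens coordinates), and `fixation_points` — the per-fixation
#'   projected points obtained by averaging each scheduled fixation's
#'   samples and projecting, i.e. the estimator the error metric uses.
#' @export
simulate_pinhole_check <- function(pinhole_pos, sc) {
  if (is.null(sc$seed)) stop("simulation requires an explicit seed")
  stopifnot(length(pinhole_pos) == 2)
  with_local_seed(sc$seed, {
    frame <- sc$frame; surface <- sc$surface
    fc <- frame$fitting_cross_right_mm
    pin3 <- c(fc[1] + pinhole_pos[1], fc[2] + pinhole_pos[2],
              surface_vertex_z(surface))
    cre <- cre_position(frame, surface, "right")
    dir <- unitize(pin3 - cre)
    rec <- simulate_recording_impl(sc, fixed_dir = list(right = dir,
                                                        left = dir))
    # occlude the left eye
    rec$samples$valid[rec$samples$eye == "left"] <- FALSE
    truth <- attr(rec, "truth")
    truth <- truth[truth$eye == "right", , drop = FALSE]
    # fixation-level estimates from the scheduled spans
    s <- rec$samples[rec$samples$eye == "right" & rec$samples$valid, ,
                     drop = FALSE]
    pts <- lapply(seq_len(nrow(truth)), function(k) {
      g <- s[s$t >= truth$t_start[k] & s$t < truth$t_end[k], , drop = FALSE]
      if (nrow(g) == 0) return(NULL)
      v <- unitize(c(mean(g$gx), mean(g$gy), mean(g$gz)))
      p <- c(mean(g$px), mean(g$py), mean(g$pz))
      hit <- tryCatch(intersect_gaze_with_surface(p, v, surface),
                      lensuse_no_intersection = function(e) NULL)
      if (is.null(hit)) return(NULL)
      to_fitting_cross_frame(hit, frame, "right")
    })
    pts <- do.call(rbind, pts)
    list(recording = rec,
         truth = c(x = pinhole_pos[1], y = pinhole_pos[2]),
         fixation_points = pts)
  })
}
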