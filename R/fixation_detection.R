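#' Velocity-threshold (I-VT) fixation classification
#'
#' Classifies one eye's samples into fixations with the standard I-VT
#' scheme: the angular velocity between consecutive valid samples — the
#' angle between their gaze directions divided by the time step — is
#' compared against a threshold; sub-threshold stretches form fixation
#' runs. Invalid samples terminate the current run (a gap is never bridged),
#' and runs shorter than `min_duration_s` are discarded.
#'
#' Each sample is taken to cover one frame period `[t, t + 1/rate)`, so a
#' fixation's `t_end` is the last sample's time plus one period and a steady
#' 2 s recording yields a single fixation of duration 2 s.
#'
#' The representative direction of a fixation is the renormalized arithmetic
#' mean of its sample directions; the representative pupil position is the
#' plain arithmetic mean.
#'
#' @param rec a [gaze_recording()].
#' @param eye `"left"` or `"right"`.
#' @param velocity_threshold_deg_s I-VT threshold, degrees/second.
#'   Default 30, standard practice for wearable trackers.
#' @param min_duration_s minimum fixation duration, seconds. Default 0.06.
#' @return data.frame with one row per fixation: `eye`, `t_start`, `t_end`,
#'   `duration`, `n_samples`, `gx`, `gy`, `gz` (mean direction, unit), `px`,
#'   `py`, `pz` (mean pupil position, mm).
#' @export
classify_fixations <- function(rec, eye = c("right", "left"),
                               velocity_threshold_deg_s = 30,
                               min_duration_s = 0.06) {
  eye <- match.arg(eye)
  stopifnot(velocity_threshold_deg_s > 0, min_duration_s >= 0)
  period <- 1 / rec$sample_rate_hz
  s <- rec$samples[rec$samples$eye == eye, , drop = FALSE]
  empty <- data.frame(eye = character(), t_start = numeric(),
                      t_end = numeric(), duration = numeric(),
                      n_samples = integer(), gx = numeric(), gy = numeric(),
                      gz = numeric(), px = numeric(), py = numeric(),
                      pz = numeric(), stringsAsFactors = FALSE)
  if (sum(s$valid) < 2) {
    warning("fewer than 2 valid samples for the ", eye, " eye; no fixations")
    return(empty)
  }
  n <- nrow(s)
  # run ids: start a new run at each invalid sample, after each invalid
  # sample, and at each super-threshold velocity step between valid samples
  run <- integer(n)
  cur <- 0L
  prev_valid <- FALSE
  for (i in seq_len(n)) {
    if (!s$valid[i]) {
      run[i] <- NA_integer_
      prev_valid <- FALSE
      next
    }
    new_run <- TRUE
    if (prev_valid) {
      j <- i - 1L
      dt <- s$t[i] - s$t[j]
      if (dt > 0) {
        dot <- s$gx[i] * s$gx[j] + s$gy[i] * s$gy[j] + s$gz[i] * s$gz[j]
        ang <- rad2deg(acos(min(max(dot, -1), 1)))
        new_run <- (ang / dt) >= velocity_threshold_deg_s
      }
    }
    if (new_run) cur <- cur + 1L
    run[i] <- cur
    prev_valid <- TRUE
  }
  keep <- !is.na(run)
  sv <- s[keep, , drop = FALSE]
  rv <- run[keep]
  out <- lapply(split(seq_len(nrow(sv)), rv), function(idx) {
    g <- sv[idx, , drop = FALSE]
    t_start <- g$t[1]
    t_end <- g$t[nrow(g)] + period
    dir <- unitize(c(mean(g$gx), mean(g$gy), mean(g$gz)))
    data.frame(eye = eye, t_start = t_start, t_end = t_end,
               duration = t_end - t_start, n_samples = nrow(g),
               gx = dir[1], gy = dir[2], gz = dir[3],
               px = mean(g$px), py = mean(g$py), pz = mean(g$pz),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$duration >= min_duration_s, , drop = FALSE]
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$t_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a fixation table as CSV
#'
#' @param fixations output of [classify_fixations()].
#' @param path output file.
#' @param subject,condition identifiers prepended as columns.
#' @return `path`, invisibly.
#' @export
write_fixations <- function(fixations, path, subject = "S00",
                            condition = "cond") {
  df <- cbind(subject = subject, condition = condition, fixations)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
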