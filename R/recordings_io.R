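#' Construct a gaze recording
#'
#' A recording holds per-sample binocular eye-tracker output in a single
#' data.frame plus the metadata needed for quality control (nominal sample
#' rate and duration). Columns: `t` (s from recording start), `eye`
#' (`"left"`/`"right"`), `px`, `py`, `pz` (pupil position, mm, headset
#' frame), `gx`, `gy`, `gz` (gaze direction, renormalized to unit length for
#' valid samples), `pupil_mm`, `valid`.
#'
#' @param samples data.frame with the columns above.
#' @param subject_id,condition_id identifiers.
#' @param sample_rate_hz nominal sample rate (the device family targeted
#'   records at 50 Hz).
#' @param duration_s recording duration; defaults to the span implied by the
#'   sample grid (`max(t) + 1/rate`).
#' @return object of class `gaze_recording`.
#' @export
gaze_recording <- function(samples, subject_id = "S00", condition_id = "cond",
                           sample_rate_hz = 50, duration_s = NULL) {
  needed <- c("t", "eye", "px", "py", "pz", "gx", "gy", "gz",
              "pupil_mm", "valid")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols))
    stop("samples missing columns: ", paste(missing_cols, collapse = ", "))
  stopifnot(sample_rate_hz > 0)
  samples <- samples[order(samples$eye, samples$t), , drop = FALSE]
  rownames(samples) <- NULL
  # renormalize gaze directions of valid samples; degenerate ones -> invalid
  nv <- sqrt(samples$gx^2 + samples$gy^2 + samples$gz^2)
  bad <- samples$valid & (!is.finite(nv) | nv == 0)
  if (any(bad)) samples$valid[bad] <- FALSE
  ok <- samples$valid
  samples$gx[ok] <- samples$gx[ok] / nv[ok]
  samples$gy[ok] <- samples$gy[ok] / nv[ok]
  samples$gz[ok] <- samples$gz[ok] / nv[ok]
  if (any(ok & !(samples$pupil_mm > 0), na.rm = TRUE)) {
    samples$valid[ok & !(samples$pupil_mm > 0)] <- FALSE
  }
  if (is.null(duration_s)) {
    duration_s <- if (nrow(samples)) max(samples$t) + 1 / sample_rate_hz else 0
  }
  structure(list(subject_id = subject_id, condition_id = condition_id,
                 sample_rate_hz = sample_rate_hz, duration_s = duration_s,
                 samples = samples),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %s / %s: %.1f s at %g Hz, %d samples (%d valid)\n",
              x$subject_id, x$condition_id, x$duration_s, x$sample_rate_hz,
              nrow(x$samples), sum(x$samples$valid)))
  invisible(x)
}

NATIVE_COLS <- c("t", "eye", "px", "py", "pz", "gx", "gy", "gz",
                 "pupil_mm", "valid")

#' Read a gaze recording from disk
#'
#' Two dialects are supported. `native_tsv` is the package's tab-separated
#' schema: a mandatory header row with columns `t eye px py pz gx gy gz
#' pupil_mm valid`, one sample per row. `tobii_jsonl` is a JSON-lines
#' dialect mimicking wearable-tracker exports: one object per line with keys
#' `timestamp` and per-eye records `eyeleft` / `eyeright`, each holding
#' `gazedirection` (3-array), `pupilposition` (3-array) and `pupildiameter`.
#'
#' Malformed rows/lines (non-numeric fields, missing keys, zero-length
#' directions) are flagged invalid, never dropped, so data-loss accounting
#' sees them. Gaze directions of valid samples are renormalized on read.
#'
#' @param path file to read.
#' @param dialect `"native_tsv"` or `"tobii_jsonl"`.
#' @param subject_id,condition_id,sample_rate_hz,duration_s metadata passed
#'   to [gaze_recording()].
#' @return a `gaze_recording`.
#' @export
read_recording <- function(path, dialect = c("native_tsv", "tobii_jsonl"),
                           subject_id = "S00", condition_id = "cond",
                           sample_rate_hz = 50, duration_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect: ",
                                               paste(dialect, collapse = "/")))
  samples <- switch(dialect,
                    native_tsv = read_native_tsv(path),
                    tobii_jsonl = read_tobii_jsonl(path))
  if (nrow(samples) == 0 || !any(samples$valid))
    stop("empty recording: no valid samples in ", path)
  gaze_recording(samples, subject_id = subject_id,
                 condition_id = condition_id,
                 sample_rate_hz = sample_rate_hz, duration_s = duration_s)
}

read_native_tsv <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(NATIVE_COLS, names(raw))
  if (length(missing_cols))
    stop("native_tsv file lacks columns: ", paste(missing_cols, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(t = num(raw$t), eye = trimws(raw$eye),
                    px = num(raw$px), py = num(raw$py), pz = num(raw$pz),
                    gx = num(raw$gx), gy = num(raw$gy), gz = num(raw$gz),
                    pupil_mm = num(raw$pupil_mm),
                    valid = tolower(trimws(raw$valid)) %in%
                      c("true", "t", "1", "yes"),
                    stringsAsFactors = FALSE)
  malformed <- !is.finite(out$t) | !(out$eye %in% c("left", "right")) |
    !is.finite(out$gx) | !is.finite(out$gy) | !is.finite(out$gz) |
    !is.finite(out$px) | !is.finite(out$py) | !is.finite(out$pz)
  out$valid[malformed] <- FALSE
  out$t[!is.finite(out$t)] <- NA_real_
  out[!is.na(out$t), , drop = FALSE]
}

read_tobii_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", 2L * length(lines))
  k <- 0L
  for (ln in lines) {
    obj <- tryCatch(jsonlite::fromJSON(ln), error = function(e) NULL)
    ts <- if (is.list(obj) && !is.null(obj$timestamp))
      suppressWarnings(as.numeric(obj$timestamp)) else NA_real_
    for (eye in c("left", "right")) {
      rec <- if (is.list(obj)) obj[[paste0("eye", eye)]] else NULL
      gd <- rec$gazedirection; pp <- rec$pupilposition
      pd <- suppressWarnings(as.numeric(rec$pupildiameter))
      ok <- is.finite(ts) && length(gd) == 3 && length(pp) == 3 &&
        all(is.finite(as.numeric(gd))) && all(is.finite(as.numeric(pp))) &&
        length(pd) == 1 && is.finite(pd)
      k <- k + 1L
      rows[[k]] <- data.frame(
        t = ts,
        eye = eye,
        px = if (ok) as.numeric(pp[1]) else NA_real_,
        py = if (ok) as.numeric(pp[2]) else NA_real_,
        pz = if (ok) as.numeric(pp[3]) else NA_real_,
        gx = if (ok) as.numeric(gd[1]) else NA_real_,
        gy = if (ok) as.numeric(gd[2]) else NA_real_,
        gz = if (ok) as.numeric(gd[3]) else NA_real_,
        pupil_mm = if (ok) pd else NA_real_,
        valid = ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out)) out <- data.frame()
  out[!is.na(out$t), , drop = FALSE]
}

#' Write a recording in the native TSV dialect
#'
#' Values are written with enough digits that a read/write round trip
#' preserves positions and direction components to 1e-6.
#'
#' @param rec a `gaze_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  s <- rec$samples
  fmt <- function(x) formatC(x, format = "g", digits = 15)
  df <- data.frame(t = fmt(s$t), eye = s$eye,
                   px = fmt(s$px), py = fmt(s$py), pz = fmt(s$pz),
                   gx = fmt(s$gx), gy = fmt(s$gy), gz = fmt(s$gz),
                   pupil_mm = fmt(s$pupil_mm),
                   valid = ifelse(s$valid, "true", "false"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Data-loss fraction of one eye's stream
#'
#' Data loss counts both invalid-flagged samples and samples missing from
#' the nominal grid: `(expected - valid) / expected`, clipped to `[0, 1]`,
#' with `expected = round(duration * sample_rate)`. This is the statistic
#' the 10 % exclusion threshold is applied to.
#'
#' @param rec a `gaze_recording`.
#' @param eye `"left"` or `"right"`.
#' @return fraction in `[0, 1]`.
#' @export
data_loss_fraction <- function(rec, eye = c("right", "left")) {
  eye <- match.arg(eye)
  if (rec$duration_s <= 0) stop("data loss undefined: recording has zero duration")
  expected <- round(rec$duration_s * rec$sample_rate_hz)
  if (expected <= 0) stop("data loss undefined: zero expected samples")
  s <- rec$samples[rec$samples$eye == eye, , drop = FALSE]
  n_valid <- sum(s$valid)
  if (n_valid > expected)
    warning("more valid samples than the nominal grid expects (duplicates?); ",
            "loss clipped to 0")
  min(max((expected - n_valid) / expected, 0), 1)
}

#' Quality-control filter on data loss
#'
#' Keeps a recording iff its data loss is *strictly below* `max_loss` for
#' every analyzed eye (a loss of exactly the threshold is excluded, matching
#' the strict "lower than" exclusion rule). Whether loss is assessed per eye
#' or only for one analyzed eye is configurable via `eyes`.
#'
#' @param recs list of `gaze_recording` objects.
#' @param max_loss exclusion threshold in `(0, 1]`; default 0.10.
#' @param eyes eyes whose loss must each pass; default both.
#' @return list with elements `kept` and `excluded` (each a list of
#'   recordings); `excluded` carries attribute `"loss"` with the offending
#'   per-eye loss values.
#' @export
qc_filter <- function(recs, max_loss = 0.10, eyes = c("right", "left")) {
  stopifnot(max_loss > 0, max_loss <= 1)
  kept <- list(); excluded <- list(); loss_log <- list()
  for (rec in recs) {
    losses <- vapply(eyes, function(e) data_loss_fraction(rec, e), numeric(1))
    if (all(losses < max_loss)) kept[[length(kept) + 1L]] <- rec
    else {
      excluded[[length(excluded) + 1L]] <- rec
      loss_log[[length(loss_log) + 1L]] <- losses
    }
  }
  attr(excluded, "loss") <- loss_log
  list(kept = kept, excluded = excluded)
}

#' Read a frame (fitting-parameter) file
#'
#' JSON with unit-suffixed keys: `ipd_mm`, `pupil_height_mm`, `bvd_mm`,
#' optional `cre_to_lens_mm`, `fitting_cross_right_mm`,
#' `fitting_cross_left_mm`, `pantoscopic_deg`, `wrap_deg`.
#'
#' @param path JSON file.
#' @return a [frame_geometry()].
#' @export
read_frame_file <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  args <- cfg[intersect(names(cfg),
                        names(formals(frame_geometry)))]
  do.call(frame_geometry, args)
}
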