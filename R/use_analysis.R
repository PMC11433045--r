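#' Region of use: center of mass of projected fixations
#'
#' Summarizes a set of on-lens fixation points by the horizontal and
#' vertical components `(Cx, Cy)` of their center of mass relative to the
#' fitting cross, with standard deviations. Unweighted by default (each
#' fixation counts once); supplying durations as `weights` gives the
#' dwell-time-weighted center instead.
#'
#' @param points data.frame with columns `x_mm`, `y_mm` (and optionally
#'   `eye`, `ok`); rows with `ok == FALSE` or `NA` coordinates are excluded.
#' @param weights optional non-negative weights (e.g. fixation durations).
#' @param subject,condition,eye labels carried into the result.
#' @return object of class `region_of_use` with fields `Cx`, `Cy`, `sd_x`,
#'   `sd_y`, `n_fixations`, `points`, plus the labels.
#' @export
region_of_use <- function(points, weights = NULL, subject = "S00",
                          condition = "cond", eye = NULL) {
  if (!is.null(points$ok)) points <- points[points$ok, , drop = FALSE]
  points <- points[is.finite(points$x_mm) & is.finite(points$y_mm), ,
                   drop = FALSE]
  if (nrow(points) == 0) stop("no points: region of use undefined")
  if (is.null(eye) && !is.null(points$eye)) eye <- unique(points$eye)[1]
  if (is.null(weights)) {
    cx <- mean(points$x_mm); cy <- mean(points$y_mm)
  } else {
    stopifnot(length(weights) == nrow(points), all(weights >= 0),
              sum(weights) > 0)
    cx <- sum(points$x_mm * weights) / sum(weights)
    cy <- sum(points$y_mm * weights) / sum(weights)
  }
  structure(list(subject = subject, condition = condition, eye = eye,
                 Cx = cx, Cy = cy,
                 sd_x = stats::sd(points$x_mm),
                 sd_y = stats::sd(points$y_mm),
                 n_fixations = nrow(points), points = points),
            class = "region_of_use")
}

#' @export
print.region_of_use <- function(x, ...) {
  cat(sprintf("<region_of_use> %s / %s / %s: C = (%.2f, %.2f) mm, n = %d\n",
              x$subject, x$condition, x$eye %||% "?", x$Cx, x$Cy,
              x$n_fixations))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Point-in-zone containment
#'
#' Closed-boundary test: a point exactly on a zone edge counts as inside
#' (documented tie-break). Vectorized over the rows of `points`.
#'
#' @param points data.frame with `x_mm`, `y_mm` and an `eye` column.
#' @param zone a [theoretical_zone()] for the same eye.
#' @return logical vector.
#' @export
point_in_zone <- function(points, zone) {
  if (!is.null(points$eye) &&
      !all(points$eye[!is.na(points$eye)] == zone$eye))
    stop("eye mismatch between points and zone")
  points$x_mm >= zone$x_min & points$x_mm <= zone$x_max &
    points$y_mm >= zone$y_min & points$y_mm <= zone$y_max
}

#' Concordance of one subject's fixations with a theoretical zone
#'
#' @param points projected fixations ([project_fixations()] output); rows
#'   with `ok == FALSE` are counted in `n_total` but never inside.
#' @param zone a [theoretical_zone()].
#' @param subject subject label.
#' @return one-row data.frame: `subject`, `eye`, `condition`, `n_inside`,
#'   `n_total`, `fraction_inside`, `all_inside`.
#' @export
concordance_result <- function(points, zone, subject = "S00") {
  n_total <- nrow(points)
  if (n_total == 0) stop("no fixations: concordance undefined")
  usable <- if (is.null(points$ok)) rep(TRUE, n_total) else points$ok
  inside <- rep(FALSE, n_total)
  inside[usable] <- point_in_zone(points[usable, , drop = FALSE], zone)
  data.frame(subject = subject, eye = zone$eye, condition = zone$condition,
             n_inside = sum(inside), n_total = n_total,
             fraction_inside = sum(inside) / n_total,
             all_inside = sum(inside) == n_total,
             stringsAsFactors = FALSE)
}

#' Pooled concordance percentage
#'
#' Fixation-pooled estimator: total fixations inside the zones divided by
#' total fixations, across all subjects, times 100. The companion
#' subject-averaged estimator ([subject_mean_concordance()]) averages the
#' per-subject fractions instead; both are reported by the pipeline because
#' a printed "percentage of fixations for all subjects" can mean either.
#'
#' @param results data.frame of [concordance_result()] rows.
#' @return percentage in `[0, 100]`.
#' @export
pooled_concordance <- function(results) {
  if (nrow(results) == 0 || sum(results$n_total) == 0)
    stop("zero fixations: pooled concordance undefined")
  100 * sum(results$n_inside) / sum(results$n_total)
}

#' @rdname pooled_concordance
#' @export
subject_mean_concordance <- function(results) {
  if (nrow(results) == 0) stop("no results")
  100 * mean(results$fraction_inside)
}

#' Percentage of subjects with every fixation inside the zone
#'
#' A subject passes only if *all* of their fixations (across the rows
#' belonging to them) fell inside the theoretical zone; the statistic is
#' the percentage of passing subjects.
#'
#' @param results data.frame of [concordance_result()] rows.
#' @return percentage in `[0, 100]`.
#' @export
strict_subject_percentage <- function(results) {
  if (nrow(results) == 0) stop("no results")
  per_subject <- tapply(results$all_inside, results$subject, all)
  100 * mean(as.logical(per_subject))
}

#' Per-condition summary of regions of use
#'
#' Mean and sample standard deviation of `Cx` and `Cy` per condition and
#' eye — the numeric content of the usual region-of-use bar plots. Groups
#' with a single region report `sd = 0` and are flagged.
#'
#' @param regions list of [region_of_use()] objects.
#' @return data.frame: `condition`, `eye`, `n`, `mean_Cx`, `sd_Cx`,
#'   `mean_Cy`, `sd_Cy`, `single_subject` flag.
#' @export
condition_summary <- function(regions) {
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(condition = r$condition, eye = r$eye, Cx = r$Cx, Cy = r$Cy,
               stringsAsFactors = FALSE)))
  groups <- split(df, list(df$condition, df$eye), drop = TRUE)
  out <- lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(condition = g$condition[1], eye = g$eye[1], n = n,
               mean_Cx = mean(g$Cx),
               sd_Cx = if (n > 1) stats::sd(g$Cx) else 0,
               mean_Cy = mean(g$Cy),
               sd_Cy = if (n > 1) stats::sd(g$Cy) else 0,
               single_subject = n == 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$condition, out$eye), , drop = FALSE]
  rownames(out) <- NULL
  out
}
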