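#' A single examination (CT or RSA)
#'
#' One imaging examination of the phantom/patient: the pelvis and cup
#' marker sets measured in that examination's own scanner frame, tagged
#' with the study position (1-6), the series within the double examination
#' (1-2) and the modality.
#'
#' @param position Position index (1-6).
#' @param series Series index (1-2).
#' @param pelvis,cup [marker_set()]s with >= 3 markers each.
#' @param modality `"CT"` or `"RSA"`.
#' @return An `examination`.
#' @export
examination <- function(position, series, pelvis, cup,
                        modality = c("CT", "RSA")) {
  modality <- match.arg(modality)
  stopifnot(inherits(pelvis, "marker_set"), inherits(cup, "marker_set"))
  if (nrow(pelvis) < 3L || nrow(cup) < 3L)
    stop("an examination needs >= 3 usable markers per rigid body",
         call. = FALSE)
  structure(list(position = as.integer(position),
                 series = as.integer(series),
                 pelvis = pelvis, cup = cup, modality = modality),
            class = "examination")
}

#' @export
print.examination <- function(x, ...) {
  cat(sprintf("<examination> %s position %d series %d: %d pelvis + %d cup markers\n",
              x$modality, x$position, x$series, nrow(x$pelvis), nrow(x$cup)))
  invisible(x)
}

# restrict an examination to given visible marker ids (used when comparing
# modalities on the common rigid body)
restrict_examination <- function(exam, pelvis_ids = NULL, cup_ids = NULL) {
  pelvis <- if (is.null(pelvis_ids)) exam$pelvis
            else subset_markers(exam$pelvis,
                                intersect(pelvis_ids, exam$pelvis$marker_id))
  cup <- if (is.null(cup_ids)) exam$cup
         else subset_markers(exam$cup,
                             intersect(cup_ids, exam$cup$marker_id))
  examination(exam$position, exam$series, pelvis, cup, exam$modality)
}

#' Register one examination to another on the pelvic markers
#'
#' Fits the rigid transform aligning the moving examination's pelvic
#' markers to the reference examination's, using the intersection of
#' pelvic marker ids. After applying the transform the two pelves coincide
#' up to residual noise; the cup can then be compared in the common frame.
#' A registration whose mean error exceeds `qc_mean_error` (the RSA
#' stability bound, default 0.35 mm) is flagged - not rejected - via
#' `qc_pass`, mirroring the convention of reporting QC values alongside
#' results.
#'
#' @param moving,reference [examination()]s sharing pelvic marker ids.
#' @param qc_mean_error QC bound on the registration mean error (mm).
#' @return A list of class `registration`: `transform`, `quality`
#'   (from [fit_rigid()]), `n_pelvis_used`, `qc_pass`.
#' @export
register_exams <- function(moving, reference, qc_mean_error = 0.35) {
  stopifnot(inherits(moving, "examination"),
            inherits(reference, "examination"))
  fit <- fit_rigid(moving$pelvis, reference$pelvis)
  structure(list(transform = fit$transform, quality = fit$quality,
                 n_pelvis_used = fit$quality$n,
                 qc_pass = fit$quality$mean_error <= qc_mean_error),
            class = "registration")
}

#' Cup migration between two examinations
#'
#' The central measurement: the rigid motion of the cup relative to the
#' pelvis between examinations `exam_a` and `exam_b`. The second
#' examination is first registered to the first on the pelvic markers;
#' `exam_b`'s cup markers are mapped through that registration, and the cup
#' motion is the rigid fit from `exam_a`'s cup markers to the mapped set.
#' Translations are reported at the cup-marker centroid (the standard RSA
#' rigid-body translation convention); rotations as Cardan x-y-z angles in
#' degrees. The sign convention is motion *from a to b*.
#'
#' Reporting axes: by default the components are expressed in the reference
#' examination's own scanner axes. Because the subject may be posed
#' arbitrarily in the scanner, pass `frame` - the pelvis marker template in
#' anatomical coordinates (the marker table) - to express the motion in
#' anatomical axes instead: the reference pelvis is registered to the
#' template and the cup motion conjugated into that frame. This makes the
#' result invariant to how the subject was positioned in the scanner.
#'
#' @param exam_a,exam_b [examination()]s with registrable pelves and
#'   shared cup marker ids (>= 3).
#' @param frame Optional pelvis [marker_set()] defining the anatomical
#'   reporting axes.
#' @param qc_mean_error Passed to [register_exams()].
#' @return A `migration_result`: components `dx, dy, dz` (mm),
#'   `rx, ry, rz` (degrees), marker counts, registration quality and the
#'   cup-fit mean error.
#' @export
cup_migration <- function(exam_a, exam_b, frame = NULL,
                          qc_mean_error = 0.35) {
  reg <- register_exams(exam_b, exam_a, qc_mean_error = qc_mean_error)
  ids <- intersect(exam_a$cup$marker_id, exam_b$cup$marker_id)
  if (length(ids) < 3L)
    stop(sprintf("cup migration needs >= 3 shared cup markers (found %d)",
                 length(ids)), call. = FALSE)
  cup_a <- subset_markers(exam_a$cup, ids)
  cup_b <- apply_transform(reg$transform, subset_markers(exam_b$cup, ids))
  fit <- tryCatch(fit_rigid(cup_a, cup_b), error = function(e)
    stop(sprintf("degenerate cup marker configuration: %s",
                 conditionMessage(e)), call. = FALSE))
  M <- fit$transform
  centroid <- colMeans(marker_coords(cup_a))
  if (!is.null(frame)) {
    # conjugate into the anatomical axes carried by the pelvis template
    A <- fit_rigid(exam_a$pelvis, frame)$transform
    tr <- as.vector(A$rotation %*%
                      (apply_transform(M, centroid) - centroid))
    ang <- decompose_cardan(A$rotation %*% M$rotation %*% t(A$rotation))
  } else {
    tr <- apply_transform(M, centroid) - centroid
    ang <- decompose_cardan(M)
  }
  structure(list(
    dx = tr[[1]], dy = tr[[2]], dz = tr[[3]],
    rx = ang[["rx"]], ry = ang[["ry"]], rz = ang[["rz"]],
    n_pelvis_used = reg$n_pelvis_used, n_cup_used = length(ids),
    registration_quality = reg$quality,
    cup_fit_error = fit$quality$mean_error,
    qc_pass = reg$qc_pass,
    position_a = exam_a$position, position_b = exam_b$position,
    series_a = exam_a$series, series_b = exam_b$series,
    modality = exam_a$modality
  ), class = "migration_result")
}

#' @export
print.migration_result <- function(x, ...) {
  cat(sprintf("<migration_result> %s position %d->%d (series %d/%d)\n",
              x$modality, x$position_a, x$position_b, x$series_a, x$series_b))
  cat(sprintf("  translation (mm):  dx % .4f  dy % .4f  dz % .4f\n",
              x$dx, x$dy, x$dz))
  cat(sprintf("  rotation (deg):    rx % .4f  ry % .4f  rz % .4f\n",
              x$rx, x$ry, x$rz))
  cat(sprintf("  markers used: %d pelvis, %d cup; registration mean error %.4f mm%s\n",
              x$n_pelvis_used, x$n_cup_used,
              x$registration_quality$mean_error,
              if (x$qc_pass) "" else " [QC FLAG]"))
  invisible(x)
}

#' @export
as.data.frame.migration_result <- function(x, ...) {
  data.frame(position_a = x$position_a, position_b = x$position_b,
             series_a = x$series_a, series_b = x$series_b,
             modality = x$modality,
             dx = x$dx, dy = x$dy, dz = x$dz,
             rx = x$rx, ry = x$ry, rz = x$rz,
             n_pelvis_used = x$n_pelvis_used, n_cup_used = x$n_cup_used,
             reg_mean_error = x$registration_quality$mean_error,
             cup_fit_error = x$cup_fit_error,
             condition_number = x$registration_quality$condition_number,
             qc_pass = x$qc_pass,
             stringsAsFactors = FALSE)
}

migrations_frame <- function(migrations) {
  do.call(rbind, lapply(migrations, as.data.frame))
}

find_exam <- function(exams, position, series) {
  for (e in exams)
    if (e$position == position && e$series == series) return(e)
  stop(sprintf("study is missing position %d series %d", position, series),
       call. = FALSE)
}

#' Pairwise migrations across the study positions
#'
#' Computes migrations for the independent position pairs (1-2, 3-4, 5-6),
#' pairing series 1 with series 1 and series 2 with series 2 - up to six
#' independent measurements per study. These pairings feed the accuracy
#' comparison against a gold-standard modality.
#'
#' @param exams List of [examination()]s covering positions 1-6.
#' @param frame Optional pelvis template defining anatomical reporting
#'   axes (see [cup_migration()]).
#' @param pairs List of position index pairs; default
#'   `list(c(1,2), c(3,4), c(5,6))`.
#' @param series Series pairing convention; default `1:2` (matched series).
#' @return Data frame with one row per pair x series, components and QC
#'   columns, plus a `pair` label column.
#' @export
pairwise_migrations <- function(exams, frame = NULL,
                                pairs = list(c(1, 2), c(3, 4), c(5, 6)),
                                series = 1:2) {
  rows <- list()
  for (pr in pairs) for (s in series) {
    m <- cup_migration(find_exam(exams, pr[1], s), find_exam(exams, pr[2], s),
                       frame = frame)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(pair = paste(pr, collapse = "-")), as.data.frame(m))
  }
  do.call(rbind, rows)
}

#' Double-examination migrations (precision data)
#'
#' For each position, measures the apparent cup migration between the two
#' series of the double examination. The cup did not move between series,
#' so every component estimates zero; the spread of these differences is
#' the precision of the method.
#'
#' @param exams List of [examination()]s (6 positions x 2 series).
#' @param frame Optional pelvis template defining anatomical reporting
#'   axes (see [cup_migration()]).
#' @return Data frame with one row per position.
#' @export
double_exam_migrations <- function(exams, frame = NULL) {
  positions <- sort(unique(vapply(exams, `[[`, integer(1), "position")))
  rows <- lapply(positions, function(p)
    as.data.frame(cup_migration(find_exam(exams, p, 1),
                                find_exam(exams, p, 2), frame = frame)))
  do.call(rbind, rows)
}
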