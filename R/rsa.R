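#' Stereoradiographic (RSA) acquisition geometry
#'
#' Simplified uniplanar RSA setup: two X-ray tube foci above a single
#' detector plane (the plane of the calibration cage), their central rays
#' crossing at the examination volume. The detector plane is z = 0 with
#' normal +z; foci sit at height `focus_height`, laterally separated so the
#' central rays - each aimed at the crossing point above the cage - subtend
#' `tube_angle`. Calibration is assumed exact: the cage fiducials are
#' carried along only to emulate the workflow, and detector coordinates are
#' continuous (no pixel quantisation).
#'
#' @param tube_angle Angle between the central rays (degrees). Angles of
#'   10 degrees or less are accepted with a warning: they make the stereo
#'   reconstruction ill-conditioned.
#' @param focus_height Focus height above the detector (mm).
#' @param phantom_height Height of the examination volume (central-ray
#'   crossing point) above the detector (mm).
#' @return A `stereo_geometry` with foci, detector plane and cage
#'   fiducials.
#' @export
stereo_geometry <- function(tube_angle = 40, focus_height = 1000,
                            phantom_height = 200) {
  if (tube_angle <= 0 || tube_angle >= 90)
    stop("tube_angle must be in (0, 90) degrees", call. = FALSE)
  if (tube_angle <= 10)
    warning("tube_angle <= 10 degrees gives an ill-conditioned stereo geometry")
  if (focus_height <= phantom_height || phantom_height < 0)
    stop("need 0 <= phantom_height < focus_height", call. = FALSE)
  half <- tube_angle / 2 * pi / 180
  d <- (focus_height - phantom_height) * tan(half)
  cage <- marker_set(cbind(c(-150, 150, 150, -150, -75, 75, 75, -75),
                           c(-150, -150, 150, 150, -75, -75, 75, 75),
                           rep(0, 8)),
                     body = "pelvis", ids = paste0("f", 1:8))
  attr(cage, "body") <- "pelvis" # cage plate fiducials, workflow only
  structure(list(
    focus_1 = c(-d, 0, focus_height),
    focus_2 = c(d, 0, focus_height),
    detector_point = c(0, 0, 0),
    detector_normal = c(0, 0, 1),
    tube_angle = tube_angle,
    phantom_center = c(0, 0, phantom_height),
    cage_fiducials = cage
  ), class = "stereo_geometry")
}

#' @export
print.stereo_geometry <- function(x, ...) {
  cat(sprintf("<stereo_geometry> tube angle %.1f deg, foci at z = %.0f mm, examination volume at z = %.0f mm\n",
              x$tube_angle, x$focus_1[3], x$phantom_center[3]))
  invisible(x)
}

#' Marker occlusion mask
#'
#' Stereo radiographs routinely lose markers to occlusion by the metal
#' implant; the mask lists, per body, the marker ids hidden in the
#' projections. `default_occlusion()` reproduces the visible counts of the
#' validation conditions: 7 pelvic markers for both cups, 6 cup markers for
#' the cemented cup and 4 for the uncemented cup.
#'
#' @param pelvis_hidden,cup_hidden Character vectors of hidden marker ids.
#' @return An `occlusion_mask`.
#' @export
occlusion_mask <- function(pelvis_hidden = character(),
                           cup_hidden = character()) {
  structure(list(pelvis = as.character(pelvis_hidden),
                 cup = as.character(cup_hidden)),
            class = "occlusion_mask")
}

#' @rdname occlusion_mask
#' @param cup_type `"cemented"` or `"uncemented"`.
#' @export
default_occlusion <- function(cup_type = c("cemented", "uncemented")) {
  cup_type <- match.arg(cup_type)
  if (cup_type == "cemented")
    occlusion_mask(pelvis_hidden = c("p8", "p9"),
                   cup_hidden = c("c2", "c5", "c8"))
  else
    occlusion_mask(pelvis_hidden = c("p8", "p9"),
                   cup_hidden = paste0("c", setdiff(1:12, c(1, 4, 7, 10))))
}

visible_ids <- function(ms, hidden) setdiff(ms$marker_id, hidden)

#' Project markers through the stereo geometry
#'
#' Central projection of each visible marker from each focus onto the
#' detector plane, with optional seeded Gaussian measurement noise per
#' detector coordinate (default SD 0.02 mm, modelling film/detector
#' digitisation error). Markers must lie between the foci and the detector.
#'
#' @param geometry A [stereo_geometry()].
#' @param markers A [marker_set()] in world coordinates.
#' @param mask Optional [occlusion_mask()].
#' @param noise_sd Detector measurement noise SD (mm).
#' @param seed Optional seed for the noise.
#' @return List of class `stereo_projection` with data frames `view1` and
#'   `view2` (`marker_id`, `u`, `v`) and the body name.
#' @export
project_markers <- function(geometry, markers, mask = NULL, noise_sd = 0.02,
                            seed = NULL) {
  stopifnot(inherits(geometry, "stereo_geometry"),
            inherits(markers, "marker_set"))
  body <- attr(markers, "body")
  hidden <- if (is.null(mask)) character() else mask[[body]]
  vis <- visible_ids(markers, hidden)
  if (length(vis) < 3L && length(vis) < nrow(markers))
    stop(sprintf("occlusion mask leaves fewer than 3 visible %s markers",
                 body), call. = FALSE)
  if (length(vis) == 0L)
    stop(sprintf("no visible %s markers to project", body), call. = FALSE)
  ms <- subset_markers(markers, vis)
  pts <- marker_coords(ms)
  project_one <- function(focus) {
    dz <- focus[3] - pts[, 3]
    if (any(pts[, 3] <= 0) || any(dz <= 0))
      stop("marker behind focus or below the detector plane", call. = FALSE)
    s <- focus[3] / dz # ray parameter reaching z = 0
    u <- focus[1] + s * (pts[, 1] - focus[1])
    v <- focus[2] + s * (pts[, 2] - focus[2])
    data.frame(marker_id = ms$marker_id, u = u, v = v,
               stringsAsFactors = FALSE)
  }
  views <- list(view1 = project_one(geometry$focus_1),
                view2 = project_one(geometry$focus_2))
  if (noise_sd > 0) {
    add_noise <- function(view) {
      view$u <- view$u + rnorm(nrow(view), sd = noise_sd)
      view$v <- view$v + rnorm(nrow(view), sd = noise_sd)
      view
    }
    views <- if (is.null(seed)) lapply(views, add_noise)
             else with_seed(seed, lapply(views, add_noise))
  }
  structure(c(views, list(body = body)), class = "stereo_projection")
}

#' Reconstruct 3D marker positions from a stereo projection pair
#'
#' Back-projects each marker's two detector points toward their foci and
#' returns the midpoint of the common perpendicular of the two rays; the
#' ray skew distance (how far the rays miss each other, ~0 at zero noise)
#' is recorded per marker as a quality value. Rays subtending less than 5
#' degrees are rejected as ill-conditioned.
#'
#' @param projections A `stereo_projection` from [project_markers()].
#' @param geometry The [stereo_geometry()] used for the projection.
#' @return A [marker_set()] (source `"reconstructed"`) with attribute
#'   `skew_distance`.
#' @export
reconstruct_3d <- function(projections, geometry) {
  stopifnot(inherits(projections, "stereo_projection"),
            inherits(geometry, "stereo_geometry"))
  v1 <- projections$view1; v2 <- projections$view2
  if (!identical(v1$marker_id, v2$marker_id))
    stop("projection views carry different marker ids", call. = FALSE)
  n <- nrow(v1)
  out <- matrix(NA_real_, n, 3)
  skew <- numeric(n)
  for (i in seq_len(n)) {
    p1 <- geometry$focus_1; d1 <- c(v1$u[i], v1$v[i], 0) - p1
    p2 <- geometry$focus_2; d2 <- c(v2$u[i], v2$v[i], 0) - p2
    d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
    cosang <- abs(sum(d1 * d2))
    if (cosang > cos(5 * pi / 180))
      stop(sprintf("stereo reconstruction is ill-conditioned: rays for marker '%s' subtend %.2f degrees (< 5)",
                   v1$marker_id[i], acos(min(1, cosang)) * 180 / pi),
           call. = FALSE)
    # closest points on the two skew lines
    b <- sum(d1 * d2)
    w0 <- p1 - p2
    t1 <- (b * sum(d2 * w0) - sum(d1 * w0)) / (1 - b^2)
    t2 <- (sum(d2 * w0) - b * sum(d1 * w0)) / (1 - b^2)
    q1 <- p1 + t1 * d1
    q2 <- p2 + t2 * d2
    out[i, ] <- (q1 + q2) / 2
    skew[i] <- sqrt(sum((q1 - q2)^2))
  }
  ms <- marker_set(out, body = projections$body, ids = v1$marker_id,
                   source = "reconstructed")
  attr(ms, "skew_distance") <- skew
  ms
}

#' Simulate RSA examinations of a phantom study
#'
#' The gold-standard arm of the validation: for every position and series
#' of the study the posed phantom is placed at the examination volume of
#' the stereo geometry, pelvis and cup markers are projected through both
#' foci (with occlusion applied and detector noise added), and 3D marker
#' positions are reconstructed. The resulting examinations feed the same
#' migration pipeline as the CT examinations.
#'
#' @param manifest A [build_study()] manifest.
#' @param geometry A [stereo_geometry()].
#' @param mask An [occlusion_mask()]; default from the manifest's cup type.
#' @param noise_sd Detector noise SD (mm); 0.02 mm by default.
#' @param seed Base seed for the detector noise; defaults to the manifest
#'   configuration seed.
#' @return List of 12 [examination()]s with modality `"RSA"`.
#' @export
rsa_measure_study <- function(manifest, geometry = stereo_geometry(),
                              mask = default_occlusion(manifest$config$cup_type),
                              noise_sd = 0.02,
                              seed = manifest$config$seed) {
  stopifnot(inherits(manifest, "study_manifest"))
  exams <- list()
  for (p in 1:6) for (s in 1:2) {
    pose <- manifest$poses[[p]][[s]]
    shift <- geometry$phantom_center
    place <- function(ms) {
      coords <- sweep(apply_transform(pose, marker_coords(ms)), 2L, shift,
                      "+")
      set_marker_coords(ms, coords)
    }
    exam_seed <- seed + 1000L + 20L * p + s
    pelvis <- reconstruct_3d(
      project_markers(geometry, place(manifest$pelvis), mask,
                      noise_sd = noise_sd, seed = exam_seed),
      geometry)
    cup <- reconstruct_3d(
      project_markers(geometry, place(manifest$positions[[p]]$cup), mask,
                      noise_sd = noise_sd, seed = exam_seed + 10000L),
      geometry)
    exams[[length(exams) + 1L]] <-
      examination(p, s, pelvis, cup, modality = "RSA")
  }
  exams
}
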