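#' Synthetic pelvic phantom configuration
#'
#' Describes the simulated phantom and CT acquisition: a pelvic model
#' carrying periacetabular beads and an acetabular cup carrying beads in a
#' circle at the periphery of the liner opening, scanned on a grid of
#' 0.6 x 0.6 mm in-plane voxels at 0.3 mm increments. Defaults reproduce
#' the validation study conditions: 9 pelvic beads; 9 (cemented) or 12
#' (uncemented) cup beads; 1.0 mm bead diameter.
#'
#' Intensity model: beads are rendered as spheres of *pre-blur* contrast
#' `bead_intensity` above a uniform `background_intensity`, convolved with
#' an isotropic Gaussian point-spread function of `blur_sigma`. Because a
#' 1.0 mm bead is comparable in size to the PSF, the rendered peak voxel is
#' far below the pre-blur contrast: with the defaults (10000 HU pre-blur,
#' 0.4 mm blur) the observed peak is ~3000 HU, the familiar saturated
#' tantalum value on clinical scanners, and sits well above the 1500 HU
#' detection threshold.
#'
#' @param cup_type `"cemented"` (9 cup beads) or `"uncemented"` (12).
#' @param n_pelvis_markers,n_cup_markers Bead counts (>= 3 each);
#'   `n_cup_markers` defaults from `cup_type`.
#' @param cup_radius Radius (mm) of the bead circle at the liner periphery.
#' @param bead_diameter Bead diameter (mm).
#' @param pelvis_spread Length-3 extents (mm) of the periacetabular region
#'   in which pelvic beads scatter.
#' @param noise_sd Gaussian image noise SD (HU).
#' @param blur_sigma Gaussian PSF sigma (mm).
#' @param bead_intensity Pre-blur bead contrast above background (HU).
#' @param background_intensity Background attenuation (HU).
#' @param spacing Voxel spacing (mm).
#' @param fov Field of view (mm), cropped around the acetabulum.
#' @param supersample Subvoxel sampling factor per axis (>= 1) for
#'   partial-volume rendering.
#' @param seed Integer seed controlling marker placement, repositioning
#'   poses and image noise.
#' @return A `phantom_config`.
#' @examples
#' cfg <- phantom_config(cup_type = "uncemented")
#' cfg$n_cup_markers # 12
#' @export
phantom_config <- function(cup_type = c("cemented", "uncemented"),
                           n_pelvis_markers = 9,
                           n_cup_markers = NULL,
                           cup_radius = 25,
                           bead_diameter = 1.0,
                           pelvis_spread = c(60, 60, 40),
                           noise_sd = 20,
                           blur_sigma = 0.4,
                           bead_intensity = 10000,
                           background_intensity = 100,
                           spacing = c(0.6, 0.6, 0.3),
                           fov = c(120, 120, 90),
                           supersample = 3,
                           seed = 1) {
  cup_type <- match.arg(cup_type)
  if (is.null(n_cup_markers))
    n_cup_markers <- if (cup_type == "cemented") 9L else 12L
  if (n_pelvis_markers < 3 || n_cup_markers < 3)
    stop("at least 3 markers per rigid body are required", call. = FALSE)
  if (bead_diameter <= 0) stop("bead_diameter must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values", call. = FALSE)
  if (supersample < 1) stop("supersample must be >= 1", call. = FALSE)
  structure(list(
    cup_type = cup_type,
    n_pelvis_markers = as.integer(n_pelvis_markers),
    n_cup_markers = as.integer(n_cup_markers),
    cup_radius = cup_radius,
    bead_diameter = bead_diameter,
    pelvis_spread = as.numeric(pelvis_spread),
    noise_sd = noise_sd,
    blur_sigma = blur_sigma,
    bead_intensity = bead_intensity,
    background_intensity = background_intensity,
    spacing = as.numeric(spacing),
    fov = as.numeric(fov),
    supersample = as.integer(supersample),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Generate phantom marker geometries
#'
#' Pelvic beads scatter uniformly (seeded) in a box of extents
#' `pelvis_spread` centered on the acetabulum, subject to realistic
#' separation constraints (>= 12 mm between pelvic beads, >= 10 mm from any
#' cup bead) so beads never merge in the rendered image. Cup beads are
#' equally spaced on a circle of `cup_radius` in the liner-opening plane
#' (normal along z, 12 mm above the acetabular center), with a small seeded
#' axial stagger (+/- 0.5 mm) emulating bead seating depth - this keeps the
#' cup body from being exactly coplanar.
#'
#' @param config A [phantom_config()].
#' @return List with [marker_set()]s `pelvis` and `cup` (ids `p1`, ...,
#'   `c1`, ...).
#' @export
make_phantom_markers <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    nc <- config$n_cup_markers
    theta <- 2 * pi * (seq_len(nc) - 1) / nc
    cup <- cbind(config$cup_radius * cos(theta),
                 config$cup_radius * sin(theta),
                 12 + runif(nc, -0.5, 0.5))
    np <- config$n_pelvis_markers
    half <- config$pelvis_spread / 2
    pelvis <- matrix(NA_real_, np, 3)
    accepted <- 0L
    for (attempt in seq_len(20000L)) {
      cand <- runif(3, -half, half)
      d_cup <- sqrt(colSums((t(cup) - cand)^2))
      ok <- all(d_cup >= 10)
      if (ok && accepted > 0L) {
        d_pel <- sqrt(colSums((t(pelvis[seq_len(accepted), , drop = FALSE]) -
                                 cand)^2))
        ok <- all(d_pel >= 12)
      }
      if (ok) {
        accepted <- accepted + 1L
        pelvis[accepted, ] <- cand
        if (accepted == np) break
      }
    }
    if (accepted < np)
      stop("could not place pelvic markers with the required separation; increase pelvis_spread",
           call. = FALSE)
    list(pelvis = marker_set(pelvis, body = "pelvis",
                             ids = paste0("p", seq_len(np))),
         cup = marker_set(cup, body = "cup", ids = paste0("c", seq_len(nc))))
  })
}

#' Jig-controlled cup motion
#'
#' `jig_setting()` describes one motion of the calibration jig holding the
#' cup: translations along x, y, z (1.0 mm increments on the physical jig)
#' and a rotation about the x-axis (1.0 degree increments). `apply_jig()`
#' applies the motion to the cup markers: rotation about the x-axis through
#' the cup-marker centroid (the jig pivot), then translation. The motion is
#' exactly rigid, so all pairwise marker distances are preserved.
#'
#' @param dx,dy,dz Translations (mm).
#' @param rx Rotation about x (degrees).
#' @export
jig_setting <- function(dx = 0, dy = 0, dz = 0, rx = 0) {
  vals <- c(dx = dx, dy = dy, dz = dz, rx = rx)
  if (any(!is.finite(vals))) stop("jig settings must be finite", call. = FALSE)
  structure(as.list(vals), class = "jig_setting")
}

# rigid transform realising a jig setting on a given cup (pivot = centroid)
jig_transform <- function(cup, setting) {
  pivot <- colMeans(marker_coords(cup))
  rot <- cardan_transform(setting$rx, 0, 0)$rotation
  t <- pivot - as.vector(rot %*% pivot) +
    c(setting$dx, setting$dy, setting$dz)
  rigid_transform(rot, t)
}

#' @rdname jig_setting
#' @param cup Cup [marker_set()].
#' @param setting A `jig_setting`.
#' @export
apply_jig <- function(cup, setting) {
  stopifnot(inherits(cup, "marker_set"), inherits(setting, "jig_setting"))
  apply_transform(jig_transform(cup, setting), cup)
}

#' Default six-position migration schedule
#'
#' Incremental jig settings applied before positions 2..6: the cup moves
#' 1.0 mm along the x- or y-axis (alternating) and rotates 1.0 degree about
#' the x-axis at every step, so each independent position pair (1-2, 3-4,
#' 5-6) carries a true migration of 1.0 mm plus 1.0 degree.
#'
#' @return List of 6 [jig_setting()]s (the first is the identity).
#' @export
default_jig_schedule <- function() {
  list(jig_setting(),
       jig_setting(dx = 1, rx = 1),
       jig_setting(dy = 1, rx = 1),
       jig_setting(dx = 1, rx = 1),
       jig_setting(dy = 1, rx = 1),
       jig_setting(dx = 1, rx = 1))
}

#' Build the six-position, two-series phantom study
#'
#' Assembles the double-examination study design: 6 cup positions, each
#' generated from the previous by an incremental jig setting, and 2 series
#' per position in which the whole phantom (pelvis + cup together) is
#' repositioned by a random seeded rigid pose (rotations up to +/- 10
#' degrees per axis, translations up to +/- 20 mm) while the cup-to-pelvis
#' pose is untouched - emulating patient repositioning between scans. That
#' gives 12 examinations per cup. Ground-truth migrations are recorded for
#' the independent pairs 1-2, 3-4 and 5-6 (and are identically zero within
#' any position's series pair).
#'
#' @param config A [phantom_config()].
#' @param schedule List of 6 incremental [jig_setting()]s; default
#'   [default_jig_schedule()].
#' @return A `study_manifest`: list with `config`, `pelvis` (marker set),
#'   `positions` (per-position cup marker sets + incremental settings),
#'   `poses` (6 x 2 list of repositioning [rigid_transform()]s),
#'   `pairs` (the pairwise design) and `ground_truth` (data frame of true
#'   migration components per pair).
#' @export
build_study <- function(config, schedule = default_jig_schedule()) {
  stopifnot(inherits(config, "phantom_config"))
  if (length(schedule) != 6L)
    stop("schedule must list 6 incremental jig settings", call. = FALSE)
  markers <- make_phantom_markers(config)
  positions <- vector("list", 6L)
  cup <- markers$cup
  for (p in 1:6) {
    cup <- apply_jig(cup, schedule[[p]])
    positions[[p]] <- list(index = p, setting = schedule[[p]], cup = cup)
  }
  poses <- with_seed(config$seed + 1L, {
    lapply(1:6, function(p) lapply(1:2, function(s) random_rigid_pose()))
  })
  pairs <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  gt <- do.call(rbind, lapply(pairs, function(pr) {
    mig <- true_migration(positions[[pr[1]]]$cup, positions[[pr[2]]]$cup)
    cbind(data.frame(pair = paste(pr, collapse = "-")), mig)
  }))
  structure(list(config = config, pelvis = markers$pelvis,
                 positions = positions, poses = poses, pairs = pairs,
                 ground_truth = gt),
            class = "study_manifest")
}

# exact migration components between two ground-truth cup marker sets:
# translation of the (first) cup centroid, Cardan rotations
true_migration <- function(cup_a, cup_b) {
  fit <- fit_rigid(cup_a, cup_b)
  ca <- colMeans(marker_coords(cup_a))
  tr <- apply_transform(fit$transform, ca) - ca
  ang <- decompose_cardan(fit$transform)
  data.frame(dx = tr[1], dy = tr[2], dz = tr[3],
             rx = ang[["rx"]], ry = ang[["ry"]], rz = ang[["rz"]],
             row.names = NULL)
}

#' @export
print.study_manifest <- function(x, ...) {
  cat(sprintf("<study_manifest> %s cup: %d pelvis + %d cup markers, 6 positions x 2 series (12 examinations)\n",
              x$config$cup_type, nrow(x$pelvis),
              nrow(x$positions[[1]]$cup)))
  cat("ground-truth pairwise migrations:\n")
  print(x$ground_truth, digits = 4)
  invisible(x)
}

#' Ground-truth migration between two study positions
#'
#' @param manifest A [build_study()] manifest.
#' @param a,b Position indices (1-6).
#' @return One-row data frame with components `dx, dy, dz` (mm) and
#'   `rx, ry, rz` (degrees).
#' @export
ground_truth_migration <- function(manifest, a, b) {
  stopifnot(inherits(manifest, "study_manifest"))
  true_migration(manifest$positions[[a]]$cup, manifest$positions[[b]]$cup)
}

#' Save / load a study manifest as JSON
#'
#' Serialises the full study design (configuration, marker coordinates,
#' repositioning poses, ground truth) to a plain-text JSON file, for use by
#' the command-line interface and for archiving simulated studies.
#'
#' @param manifest A `study_manifest`.
#' @param path JSON file path.
#' @export
save_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "study_manifest"))
  obj <- list(
    config = unclass(manifest$config),
    pelvis = list(ids = manifest$pelvis$marker_id,
                  coords = marker_coords(manifest$pelvis)),
    positions = lapply(manifest$positions, function(p)
      list(index = p$index, setting = unclass(p$setting),
           cup_ids = p$cup$marker_id, cup_coords = marker_coords(p$cup))),
    poses = lapply(manifest$poses, function(ps) lapply(ps, function(tr)
      list(rotation = tr$rotation, translation = tr$translation))),
    pairs = manifest$pairs,
    ground_truth = manifest$ground_truth
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  # write_json stores matrices row-wise as arrays of arrays
  as_mat <- function(x) do.call(rbind, lapply(x, function(r)
    as.numeric(unlist(r))))
  cfg <- do.call(phantom_config, obj$config[setdiff(names(obj$config),
                                                    "n_cup_markers")])
  cfg$n_cup_markers <- as.integer(obj$config$n_cup_markers)
  pelvis <- marker_set(as_mat(obj$pelvis$coords), body = "pelvis",
                       ids = unlist(obj$pelvis$ids))
  positions <- lapply(obj$positions, function(p)
    list(index = as.integer(p$index),
         setting = do.call(jig_setting, p$setting),
         cup = marker_set(as_mat(p$cup_coords), body = "cup",
                          ids = unlist(p$cup_ids))))
  poses <- lapply(obj$poses, function(ps) lapply(ps, function(tr)
    rigid_transform(as_mat(tr$rotation), unlist(tr$translation))))
  gt <- do.call(rbind, lapply(obj$ground_truth, function(r)
    data.frame(pair = r$pair, dx = r$dx, dy = r$dy, dz = r$dz,
               rx = r$rx, ry = r$ry, rz = r$rz,
               stringsAsFactors = FALSE)))
  structure(list(config = cfg, pelvis = pelvis, positions = positions,
                 poses = poses,
                 pairs = lapply(obj$pairs, function(p) as.integer(unlist(p))),
                 ground_truth = gt),
            class = "study_manifest")
}
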