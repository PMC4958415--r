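#' Rigid-body transforms
#'
#' A `rigid_transform` is a proper rotation plus a translation,
#' `y = R x + t`, in world mm. The constructor validates that `R` is
#' orthonormal with determinant +1.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return A `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("`translation` must be 3 finite values", call. = FALSE)
  check_direction(rotation) # same orthonormal/det +1 requirements
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- tryCatch(decompose_cardan(x), error = function(e) rep(NA_real_, 3))
  cat(sprintf("<rigid_transform> t = (%.4f, %.4f, %.4f) mm, cardan xyz = (%.4f, %.4f, %.4f) deg\n",
              x$translation[1], x$translation[2], x$translation[3],
              ang[1], ang[2], ang[3]))
  invisible(x)
}

#' Apply, compose and invert rigid transforms
#'
#' `apply_transform()` maps points (or a [marker_set()]) through a
#' transform; `compose_transforms(a, b)` returns the transform equivalent to
#' applying `b` first, then `a`; `invert_transform()` returns the inverse.
#'
#' @param transform,a,b [rigid_transform()] objects.
#' @param points Length-3 vector, n x 3 matrix, or [marker_set()].
#' @export
apply_transform <- function(transform, points) {
  if (inherits(points, "marker_set"))
    return(set_marker_coords(points,
                             apply_transform(transform,
                                             marker_coords(points))))
  p <- as_point_matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (is.null(dim(points))) drop(out) else out
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.vector(rt %*% transform$translation))
}

#' Cardan-angle rotation conventions
#'
#' Rotations are reported as Cardan angles in the *intrinsic x, then y,
#' then z* sequence, the order conventional in RSA migration reporting:
#' `R = Rx(rx) %*% Ry(ry) %*% Rz(rz)`. Because sequential angles do not
#' commute, migration rotations from different conventions are not
#' comparable; this package uses x-y-z throughout.
#'
#' `cardan_transform()` builds a rotation from angles (degrees);
#' `decompose_cardan()` recovers them. Decomposition fails within 1 degree
#' of gimbal lock (`|ry| >= 89` degrees), where the x and z angles become
#' unidentifiable; a quaternion representation should be used instead for
#' such large rotations (far beyond any plausible implant migration).
#'
#' @param rx,ry,rz Rotation angles in degrees.
#' @param translation Translation (mm) attached to the built transform.
#' @return `cardan_transform()`: a [rigid_transform()];
#'   `decompose_cardan()`: named numeric `c(rx, ry, rz)` in degrees.
#' @examples
#' decompose_cardan(cardan_transform(1, 0, 0)) # c(rx = 1, ry = 0, rz = 0)
#' @export
cardan_transform <- function(rx = 0, ry = 0, rz = 0,
                             translation = c(0, 0, 0)) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  rigid_transform(Rx %*% Ry %*% Rz, translation)
}

#' @rdname cardan_transform
#' @param transform A [rigid_transform()] or a 3x3 rotation matrix.
#' @export
decompose_cardan <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation
       else as.matrix(transform)
  check_direction(R)
  # R = Rx Ry Rz  =>  R[1,3] = sin(ry), R[2,3] = -sin(rx)cos(ry),
  # R[3,3] = cos(rx)cos(ry), R[1,2] = -cos(ry)sin(rz), R[1,1] = cos(ry)cos(rz)
  s <- min(1, max(-1, R[1, 3]))
  if (abs(s) > sin(89 * pi / 180))
    stop("rotation is within 1 degree of gimbal lock (|ry| >= 89 deg); Cardan x-y-z angles are unidentifiable here - use a quaternion representation",
         call. = FALSE)
  ry <- asin(s)
  rx <- atan2(-R[2, 3], R[3, 3])
  rz <- atan2(-R[1, 2], R[1, 1])
  c(rx = rx, ry = ry, rz = rz) * 180 / pi
}

#' Least-squares rigid-body fit between corresponding marker sets
#'
#' Finds the rigid transform `T` minimising `sum(|T(source_i) - target_i|^2)`
#' over corresponding markers, solved in closed form by SVD of the
#' cross-covariance of the mean-centered coordinates (Kabsch), with
#' reflection correction so the result is always a proper rotation.
#' When both inputs are [marker_set()]s, correspondence is by `marker_id`
#' and the fit uses the intersection of ids.
#'
#' The attached quality mirrors the RSA diagnostics: `mean_error` is the
#' root-mean-square post-fit marker residual (mm) - the classical RSA
#' "mean error" flagging marker instability (QC bound 0.35 mm) - and
#' `condition_number` describes the scatter of the source configuration.
#'
#' @param source,target [marker_set()]s sharing ids, or n x 3 matrices in
#'   row correspondence; n >= 3 and not collinear.
#' @return A list of class `rigid_fit`: `transform` ([rigid_transform()]),
#'   `quality` (list with `mean_error`, `condition_number`, `n`), and
#'   `ids` used.
#' @examples
#' src <- matrix(rnorm(27, sd = 20), 9, 3)
#' tgt <- apply_transform(cardan_transform(2, -1, 3, c(1, 2, 3)), src)
#' fit_rigid(src, tgt)$quality$mean_error # ~0
#' @export
fit_rigid <- function(source, target) {
  ids <- NULL
  if (inherits(source, "marker_set") && inherits(target, "marker_set")) {
    ids <- intersect(source$marker_id, target$marker_id)
    if (length(ids) < 3L)
      stop(sprintf("rigid fit needs >= 3 shared markers (found %d)",
                   length(ids)), call. = FALSE)
    X <- marker_coords(subset_markers(source, ids))
    Y <- marker_coords(subset_markers(target, ids))
  } else {
    X <- as_point_matrix(source)
    Y <- as_point_matrix(target)
  }
  n <- nrow(X)
  if (n != nrow(Y)) stop("source and target sizes differ", call. = FALSE)
  if (n < 3L)
    stop(sprintf("rigid fit needs >= 3 markers (found %d)", n),
         call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  sv_x <- svd(Xc)$d
  if (sv_x[2] <= 1e-9 * max(sv_x[1], 1e-300))
    stop("degenerate marker configuration: markers are collinear",
         call. = FALSE)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cy - as.vector(R %*% cx)
  transform <- rigid_transform(R, t)
  res <- Y - apply_transform(transform, X)
  quality <- list(
    mean_error = sqrt(mean(rowSums(res^2))),
    condition_number = as.numeric(condition_number(X)),
    n = n
  )
  structure(list(transform = transform, quality = quality, ids = ids),
            class = "rigid_fit")
}

#' @export
print.rigid_fit <- function(x, ...) {
  cat(sprintf("<rigid_fit> n = %d markers, mean error = %.5f mm, condition number = %.2f\n",
              x$quality$n, x$quality$mean_error, x$quality$condition_number))
  print(x$transform)
  invisible(x)
}

#' Marker-scatter condition number
#'
#' The RSA condition number diagnostic of a rigid body's marker
#' distribution: the ratio of largest to smallest singular value of the
#' mean-centered n x 3 coordinate matrix. Well-spread 3D scatters give
#' values near 1; near-planar or near-collinear configurations give large
#' values that destabilise the rotation estimate. Conventionally values
#' below 100-110 are considered reliable; the attribute `qc_ok` flags
#' `value <= qc_limit`. Rank-deficient configurations return `Inf`.
#' The measure is invariant under rigid motion and uniform scaling.
#'
#' @param markers A [marker_set()] or n x 3 coordinate matrix, n >= 3.
#' @param qc_limit QC threshold (default 100).
#' @return Numeric condition number with attribute `qc_ok`.
#' @export
condition_number <- function(markers, qc_limit = 100) {
  X <- if (inherits(markers, "marker_set")) marker_coords(markers)
       else as_point_matrix(markers)
  if (nrow(X) < 3L)
    stop("condition number needs >= 3 markers", call. = FALSE)
  sv <- svd(sweep(X, 2L, colMeans(X)))$d
  value <- if (sv[3] <= 1e-12 * max(sv[1], 1e-300)) Inf else sv[1] / sv[3]
  structure(value, qc_ok = is.finite(value) && value <= qc_limit)
}

#' Rigid-body mean error between two examinations of the same body
#'
#' Fits the same rigid body between two examinations and returns the RMS
#' post-fit residual (mm). In RSA practice this "mean error" flags unstable
#' (migrating or loosened) markers; values above ~0.35 mm are considered
#' unacceptable.
#'
#' @param body_exam1,body_exam2 [marker_set()]s of the same body in two
#'   examinations, sharing marker ids.
#' @return Mean error in mm.
#' @export
mean_error_between_exams <- function(body_exam1, body_exam2) {
  fit_rigid(body_exam1, body_exam2)$quality$mean_error
}

# Random bounded rigid pose (whole-phantom repositioning): Cardan angles
# uniform within +/- max_rotation deg per axis, translation uniform within
# +/- max_translation mm per axis. Uses the current RNG stream.
random_rigid_pose <- function(max_rotation = 10, max_translation = 20) {
  ang <- runif(3, -max_rotation, max_rotation)
  cardan_transform(ang[1], ang[2], ang[3],
                   runif(3, -max_translation, max_translation))
}
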