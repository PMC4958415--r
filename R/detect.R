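#' Bead detection parameters
#'
#' Controls thresholding, connected-component size gating and centroid
#' refinement for tantalum bead detection. `detection_params_for()` derives
#' sensible values from a phantom configuration: the threshold sits midway
#' between background and the rendered bead peak, and the component-size
#' bounds are 0.25x-4x the voxel count predicted for the *blurred*
#' above-threshold blob (solved from the closed-form [bead_profile()]),
#' since blurring makes the detectable blob substantially larger than the
#' bare 1.0 mm sphere.
#'
#' @param threshold Detection threshold (HU); must exceed background.
#' @param min_voxels,max_voxels Accepted connected-component sizes.
#' @param window_radius Radius (mm) of the spherical window used by
#'   [refine_centroid()].
#' @return A `detection_params`.
#' @export
detection_params <- function(threshold = 1500, min_voxels = 2,
                             max_voxels = 40, window_radius = 1.7) {
  if (min_voxels <= 0 || min_voxels >= max_voxels)
    stop("need 0 < min_voxels < max_voxels", call. = FALSE)
  if (window_radius <= 0) stop("window_radius must be > 0", call. = FALSE)
  structure(list(threshold = threshold, min_voxels = as.integer(min_voxels),
                 max_voxels = as.integer(max_voxels),
                 window_radius = window_radius),
            class = "detection_params")
}

#' @rdname detection_params
#' @param config A [phantom_config()].
#' @export
detection_params_for <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  radius <- config$bead_diameter / 2
  threshold <- config$background_intensity +
    config$bead_intensity *
      bead_profile(0, radius, config$blur_sigma) / 2
  rel <- (threshold - config$background_intensity) / config$bead_intensity
  upper <- radius + 6 * config$blur_sigma + max(config$spacing)
  r_star <- if (bead_profile(upper, radius, config$blur_sigma) >= rel) upper
  else uniroot(function(r) bead_profile(r, radius, config$blur_sigma) - rel,
               c(0, upper), tol = 1e-10)$root
  nominal <- (4 / 3) * pi * r_star^3 / prod(config$spacing)
  detection_params(threshold = threshold,
                   min_voxels = max(1, floor(0.25 * nominal)),
                   max_voxels = max(2, ceiling(4 * nominal)),
                   window_radius = radius + 3 * config$blur_sigma +
                     max(config$spacing) / 2)
}

#' Detect bead candidates in a CT volume
#'
#' Thresholds the volume, extracts 26-connected components, discards
#' components outside `[min_voxels, max_voxels]`, and returns one candidate
#' center per surviving component: the intensity-weighted centroid (weights
#' are the above-threshold excess), in world mm. Candidates are coarse
#' (roughly half-voxel accurate); pass them through [refine_centroid()] for
#' subvoxel landmarks.
#'
#' @param volume A [voxel_volume()].
#' @param params A [detection_params()].
#' @return n x 3 matrix of world coordinates with attribute
#'   `component_size`.
#' @export
detect_beads <- function(volume, params = detection_params()) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(params, "detection_params"))
  dims <- dim(volume$data)
  lin <- which(volume$data > params$threshold)
  if (length(lin) == 0L)
    stop(sprintf("no voxels above detection threshold %.1f HU (volume max %.1f HU)",
                 params$threshold, max(volume$data)), call. = FALSE)
  coord <- arrayInd(lin, dims) # 1-based
  vals <- volume$data[lin]
  n <- length(lin)

  # union-find over the above-threshold voxels; 26-connectivity via the 13
  # strictly "positive" neighbour offsets (each unordered pair seen once)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  key <- (coord[, 1] - 1) + dims[1] * ((coord[, 2] - 1) +
                                         dims[2] * (coord[, 3] - 1))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2L, offs[o, ], "+")
    valid <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_key <- (nb[, 1] - 1) + dims[1] * ((nb[, 2] - 1) +
                                           dims[2] * (nb[, 3] - 1))
    hit <- match(nb_key, key)
    pairs <- which(valid & !is.na(hit))
    for (i in pairs) {
      ri <- find(i); rj <- find(hit[i])
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), root)
  sizes <- lengths(comps)
  comps <- comps[sizes >= params$min_voxels & sizes <= params$max_voxels]
  if (length(comps) == 0L)
    stop(sprintf("no connected component within size bounds [%d, %d] at threshold %.1f HU (component sizes seen: %s)",
                 params$min_voxels, params$max_voxels, params$threshold,
                 paste(sort(unique(sizes)), collapse = ", ")), call. = FALSE)
  # deterministic order: by first voxel in array order
  comps <- comps[order(vapply(comps, function(ix) min(key[ix]), double(1)))]
  centers <- t(vapply(comps, function(ix) {
    w <- vals[ix] - params$threshold
    colSums((coord[ix, , drop = FALSE] - 1) * w) / sum(w)
  }, double(3)))
  out <- voxel_to_world(volume, centers)
  dimnames(out) <- NULL
  attr(out, "component_size") <- unname(lengths(comps))
  out
}

#' Refine a bead centroid to subvoxel precision
#'
#' Computes the background-subtracted intensity-weighted centroid of the
#' voxels within `window_radius` of the seed point, iterating (recentering
#' the window on the running estimate) until the estimate moves less than
#' `tol`. The background level is estimated from the below-threshold voxels
#' inside the window; weights are clipped at zero. For the bead sizes at
#' hand (2-4 voxels per axis) the weighted centroid of the blurred profile
#' is a stable subvoxel estimator of the bead center.
#'
#' @param volume A [voxel_volume()].
#' @param seed_point World mm point within `window_radius` of a bead.
#' @param params A [detection_params()].
#' @param max_iter,tol Iteration controls.
#' @return Length-3 world coordinate (mm).
#' @export
refine_centroid <- function(volume, seed_point, params = detection_params(),
                            max_iter = 10, tol = 1e-5) {
  stopifnot(inherits(volume, "voxel_volume"))
  est <- as.numeric(seed_point)
  dims <- dim(volume$data)
  rad <- params$window_radius
  for (it in seq_len(max_iter)) {
    ctr <- world_to_voxel(volume, est)
    lo <- pmax(0, floor(ctr - rad / volume$spacing))
    hi <- pmin(dims - 1, ceiling(ctr + rad / volume$spacing))
    if (any(lo > hi))
      stop("refinement window lies outside the volume", call. = FALSE)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    grid <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    world <- voxel_to_world(volume, grid)
    keep <- rowSums(sweep(world, 2L, est)^2) <= rad^2
    grid <- grid[keep, , drop = FALSE]
    world <- world[keep, , drop = FALSE]
    vals <- volume$data[grid + 1]
    if (!any(vals > params$threshold))
      stop(sprintf("no above-threshold voxel within %.2f mm of the seed point",
                   rad), call. = FALSE)
    below <- vals[vals <= params$threshold]
    bg <- if (length(below)) median(below) else min(vals)
    w <- pmax(vals - bg, 0)
    new_est <- colSums(world * w) / sum(w)
    moved <- sqrt(sum((new_est - est)^2))
    est <- new_est
    if (moved < tol) break
  }
  est
}

#' Label detected bead candidates against a marker template
#'
#' Establishes correspondence between unlabelled candidate bead positions
#' and a labelled template [marker_set()], tolerating an unknown rigid
#' displacement between the two. Matching proceeds in two stages: a
#' deterministic alignment search - three well-separated template anchors
#' are matched against candidate triplets with compatible pairwise
#' distances (distances are rigid invariants), each compatible triplet
#' proposes a rigid transform, and the proposal matching the most template
#' markers wins - followed by a rigid refit on the matched pairs and a
#' final nearest-neighbour assignment under the refined transform.
#' Labelling is therefore invariant to the ordering of the candidate list.
#'
#' Template markers whose matched candidate lies farther than `match_tol`
#' are reported as missing (attribute `missing`); if two template markers
#' claim the same candidate, a labelling error lists the conflict.
#'
#' @param candidates n x 3 matrix of world points (e.g. from
#'   [detect_beads()]).
#' @param template A [marker_set()] with the expected marker labels.
#' @param max_missing Maximum template markers allowed to go unmatched.
#' @param match_tol Acceptance radius (mm) for the final assignment.
#' @return A [marker_set()] (source `"detected"`) with the matched
#'   candidate coordinates under the template's labels, and attribute
#'   `missing` listing unmatched template ids.
#' @export
label_markers <- function(candidates, template, max_missing = 3,
                          match_tol = 6) {
  stopifnot(inherits(template, "marker_set"))
  cand <- as_point_matrix(candidates)
  tmpl <- marker_coords(template)
  nt <- nrow(tmpl); ncand <- nrow(cand)
  if (ncand < nt - max_missing)
    stop(sprintf("too few candidates (%d) for template of %d markers (allowing %d missing)",
                 ncand, nt, max_missing), call. = FALSE)
  if (nt < 3L) stop("template needs >= 3 markers", call. = FALSE)

  # stage 1: alignment search. Anchor triplets are drawn from peripheral
  # template markers (well separated, hence a well-conditioned fit);
  # candidate triplets must reproduce the anchors' pairwise distances -
  # rigid invariants, preserved to detection noise - and each surviving
  # triplet proposes a transform scored by how many template markers it
  # matches within match_tol.
  Dc <- as.matrix(stats::dist(cand))
  ctr <- colMeans(tmpl)
  periph <- order(-sqrt(rowSums(sweep(tmpl, 2L, ctr)^2)))
  anchor_pool <- periph[seq_len(min(nt, 6L))]
  triplets <- utils::combn(anchor_pool, 3L)
  pair_tol <- 0.7 # mm; intra-body distances survive detection noise
  best <- NULL
  for (tcol in seq_len(ncol(triplets))) {
    a <- triplets[, tcol]
    dt <- c(sqrt(sum((tmpl[a[1], ] - tmpl[a[2], ])^2)),
            sqrt(sum((tmpl[a[1], ] - tmpl[a[3], ])^2)),
            sqrt(sum((tmpl[a[2], ] - tmpl[a[3], ])^2)))
    if (min(dt) < 2) next # near-coincident anchors fit poorly
    p12 <- which(abs(Dc - dt[1]) < pair_tol, arr.ind = TRUE)
    p12 <- p12[p12[, 1] != p12[, 2], , drop = FALSE]
    for (r in seq_len(nrow(p12))) {
      j1 <- p12[r, 1]; j2 <- p12[r, 2]
      j3s <- which(abs(Dc[j1, ] - dt[2]) < pair_tol &
                     abs(Dc[j2, ] - dt[3]) < pair_tol)
      for (j3 in setdiff(j3s, c(j1, j2))) {
        fit3 <- tryCatch(fit_rigid(tmpl[a, , drop = FALSE],
                                   cand[c(j1, j2, j3), , drop = FALSE]),
                         error = function(e) NULL)
        if (is.null(fit3) || fit3$quality$mean_error > pair_tol) next
        proj3 <- apply_transform(fit3$transform, tmpl)
        dm <- sqrt(pmax(outer(rowSums(proj3^2), rowSums(cand^2), "+") -
                          2 * proj3 %*% t(cand), 0))
        hits <- sum(!is.na(greedy_assign(dm, max_dist = match_tol)))
        if (is.null(best) || hits > best$hits)
          best <- list(hits = hits, fit = fit3)
        if (!is.null(best) && best$hits == nt) break
      }
      if (!is.null(best) && best$hits == nt) break
    }
    if (!is.null(best) && best$hits >= nt - max_missing) break
  }
  if (is.null(best) || best$hits < 3L)
    stop("could not form a labelling hypothesis (no candidate triplet reproduces the template geometry)",
         call. = FALSE)
  # refit on all matched pairs for a noise-averaged transform
  proj <- apply_transform(best$fit$transform, tmpl)
  dmat0 <- sqrt(pmax(outer(rowSums(proj^2), rowSums(cand^2), "+") -
                       2 * proj %*% t(cand), 0))
  hyp <- greedy_assign(dmat0, max_dist = match_tol)
  use <- which(!is.na(hyp))
  fit <- fit_rigid(tmpl[use, , drop = FALSE], cand[hyp[use], , drop = FALSE])

  # stage 2: final assignment under the fitted transform
  proj <- apply_transform(fit$transform, tmpl)
  d2 <- outer(rowSums(proj^2), rowSums(cand^2), "+") -
    2 * proj %*% t(cand)
  dmat <- sqrt(pmax(d2, 0))
  assign <- greedy_assign(dmat, max_dist = match_tol)
  unmatched <- which(is.na(assign))
  if (length(unmatched)) {
    for (i in unmatched) {
      j <- which.min(dmat[i, ])
      if (dmat[i, j] <= match_tol && j %in% assign) {
        other <- template$marker_id[which(assign == j)]
        stop(sprintf("ambiguous labelling: template markers '%s' and '%s' both claim the candidate at (%.2f, %.2f, %.2f)",
                     template$marker_id[i], other[1],
                     cand[j, 1], cand[j, 2], cand[j, 3]), call. = FALSE)
      }
    }
  }
  matched <- which(!is.na(assign))
  if (length(matched) < nt - max_missing)
    stop(sprintf("labelling failed: only %d of %d template markers matched within %.1f mm",
                 length(matched), nt, match_tol), call. = FALSE)
  out <- marker_set(cand[assign[matched], , drop = FALSE],
                    body = attr(template, "body"),
                    ids = template$marker_id[matched], source = "detected")
  attr(out, "missing") <- template$marker_id[is.na(assign)]
  out
}

# greedy unique row->column assignment by ascending score
greedy_assign <- function(score, max_dist = Inf) {
  nt <- nrow(score); ncand <- ncol(score)
  assign <- rep(NA_integer_, nt)
  taken <- rep(FALSE, ncand)
  ord <- order(score)
  for (k in ord) {
    j <- (k - 1) %/% nt + 1
    i <- (k - 1) %% nt + 1
    if (score[i, j] > max_dist) break
    if (is.na(assign[i]) && !taken[j]) {
      assign[i] <- j
      taken[j] <- TRUE
    }
  }
  assign
}
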