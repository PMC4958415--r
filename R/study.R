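#' Measure a simulated study with the 3D CT pipeline
#'
#' The full CT measurement chain for every examination of a study: pose the
#' phantom, render the CT volume ([render_ct()]), detect bead candidates
#' ([detect_beads()]), refine each to a subvoxel centroid
#' ([refine_centroid()]), and label the candidates against the study's
#' reference marker template ([label_markers()]) - the pelvis template plus
#' the position-1 cup template, exactly the marker table a reading
#' physician would carry between examinations. Measured coordinates come
#' solely from the rendered image; the template contributes labels only.
#'
#' @param manifest A [build_study()] manifest.
#' @param params Detection parameters; default derived from the
#'   configuration via [detection_params_for()].
#' @param seed Base seed for the per-examination image noise; defaults to
#'   the configuration seed.
#' @return List of 12 [examination()]s with modality `"CT"`.
#' @export
measure_ct_study <- function(manifest,
                             params = detection_params_for(manifest$config),
                             seed = manifest$config$seed) {
  stopifnot(inherits(manifest, "study_manifest"))
  config <- manifest$config
  template <- rbind(cbind(body = "pelvis",
                          as.data.frame(manifest$pelvis)),
                    cbind(body = "cup",
                          as.data.frame(manifest$positions[[1]]$cup)))
  combined <- marker_set(as.matrix(template[, c("x", "y", "z")]),
                         body = "pelvis", ids = template$marker_id)
  exams <- list()
  for (p in 1:6) for (s in 1:2) {
    pose <- manifest$poses[[p]][[s]]
    vol <- render_ct(manifest$pelvis, manifest$positions[[p]]$cup,
                     phantom_pose = pose, config = config,
                     seed = seed + 10L * p + s)
    cand <- detect_beads(vol, params)
    refined <- t(apply(cand, 1L, function(pt)
      refine_centroid(vol, pt, params)))
    labelled <- label_markers(refined, combined, max_missing = 0)
    pel <- labelled$marker_id %in% manifest$pelvis$marker_id
    exams[[length(exams) + 1L]] <- examination(
      p, s,
      pelvis = marker_set(marker_coords(labelled)[pel, , drop = FALSE],
                          body = "pelvis",
                          ids = labelled$marker_id[pel],
                          source = "detected"),
      cup = marker_set(marker_coords(labelled)[!pel, , drop = FALSE],
                       body = "cup", ids = labelled$marker_id[!pel],
                       source = "detected"),
      modality = "CT")
  }
  exams
}

#' Run one complete precision/accuracy phantom study
#'
#' End-to-end driver for the validation experiment: builds the 6-position x
#' 2-series study, measures every examination with the CT pipeline and with
#' the simulated stereo gold standard, and computes
#' * CT and RSA precision from the double examinations
#'   ([precision_summary()]),
#' * CT accuracy against RSA from the independent pairwise migrations
#'   1-2 / 3-4 / 5-6 ([accuracy_summary()]), with both modalities
#'   restricted to the markers visible in both - the common rigid body -
#'   as occlusion dictates,
#' * all registration and rigid-body-fit mean errors and condition numbers
#'   encountered, for QC.
#'
#' @param config A [phantom_config()]; its seed determines markers, poses
#'   and noise.
#' @param geometry Stereo geometry for the RSA arm.
#' @param mask Occlusion mask for the RSA arm.
#' @param rsa_noise_sd Detector noise SD (mm).
#' @return List of class `phantom_study`: `manifest`, `ct_exams`,
#'   `rsa_exams`, `precision_ct`, `precision_rsa`, `accuracy`,
#'   `ct_doubles`, `rsa_doubles` (the raw double-examination differences),
#'   `ct_pairwise`, `rsa_pairwise`, `ground_truth`, `mean_errors`,
#'   `condition_numbers`.
#' @examples
#' \donttest{
#' study <- run_phantom_study(phantom_config(seed = 7))
#' study$precision_ct
#' study$accuracy
#' }
#' @export
run_phantom_study <- function(config = phantom_config(),
                              geometry = stereo_geometry(),
                              mask = default_occlusion(config$cup_type),
                              rsa_noise_sd = 0.02) {
  manifest <- build_study(config)
  ct_exams <- measure_ct_study(manifest)
  rsa_exams <- rsa_measure_study(manifest, geometry, mask,
                                 noise_sd = rsa_noise_sd)

  frame <- manifest$pelvis # marker table = anatomical reporting axes
  prec_ct_data <- double_exam_migrations(ct_exams, frame = frame)
  prec_rsa_data <- double_exam_migrations(rsa_exams, frame = frame)

  # accuracy on the common rigid body: markers visible in both modalities
  vis_pelvis <- visible_ids(manifest$pelvis, mask$pelvis)
  vis_cup <- visible_ids(manifest$positions[[1]]$cup, mask$cup)
  ct_masked <- lapply(ct_exams, restrict_examination,
                      pelvis_ids = vis_pelvis, cup_ids = vis_cup)
  ct_pairs <- pairwise_migrations(ct_masked, frame = frame)
  rsa_pairs <- pairwise_migrations(rsa_exams, frame = frame)

  all_rows <- rbind(prec_ct_data, prec_rsa_data,
                    ct_pairs[names(prec_ct_data)],
                    rsa_pairs[names(prec_ct_data)])
  structure(list(
    manifest = manifest,
    ct_exams = ct_exams, rsa_exams = rsa_exams,
    precision_ct = precision_summary(prec_ct_data),
    precision_rsa = precision_summary(prec_rsa_data),
    accuracy = accuracy_summary(ct_pairs, rsa_pairs),
    ct_doubles = prec_ct_data, rsa_doubles = prec_rsa_data,
    ct_pairwise = ct_pairs, rsa_pairwise = rsa_pairs,
    ground_truth = manifest$ground_truth,
    mean_errors = c(registration = all_rows$reg_mean_error,
                    cup_fit = all_rows$cup_fit_error),
    condition_numbers = all_rows$condition_number
  ), class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> %s cup, seed %d\n",
              x$manifest$config$cup_type, x$manifest$config$seed))
  cat("\n3D CT ")
  print(x$precision_ct)
  cat("\nRSA ")
  print(x$precision_rsa)
  cat("\n3D CT vs RSA ")
  print(x$accuracy)
  cat(sprintf("\nQC: max mean error %.4f mm, max condition number %.1f\n",
              max(x$mean_errors), max(x$condition_numbers)))
  invisible(x)
}

#' Replicate the phantom study over several seeds
#'
#' Repeats [run_phantom_study()] under independent seeds and collects the
#' per-replicate worst-case precision and accuracy entries plus the QC
#' extremes - the quantities summarised by the validation bounds.
#'
#' @param n_seeds Number of replicate studies.
#' @param base_seed Seed for the first replicate; replicate i uses
#'   `base_seed + i - 1`.
#' @param config Template [phantom_config()]; its seed field is replaced
#'   per replicate.
#' @param ... Passed on to [run_phantom_study()].
#' @return Data frame with one row per seed: `max_trans_precision`,
#'   `max_rot_precision` (CT), `max_trans_accuracy`, `max_rot_accuracy`,
#'   `max_mean_error`, `max_condition_number`.
#' @export
replicate_study_metrics <- function(n_seeds = 20, base_seed = 1,
                                    config = phantom_config(), ...) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1)
    st <- run_phantom_study(cfg, ...)
    trans <- st$precision_ct$component %in% c("dx", "dy", "dz")
    acc_trans <- st$accuracy$component %in% c("dx", "dy", "dz")
    data.frame(
      seed = cfg$seed,
      max_trans_precision = max(st$precision_ct$precision[trans]),
      max_rot_precision = max(st$precision_ct$precision[!trans]),
      max_trans_accuracy = max(st$accuracy$accuracy[acc_trans]),
      max_rot_accuracy = max(st$accuracy$accuracy[!acc_trans]),
      max_mean_error = max(st$mean_errors),
      max_condition_number = max(st$condition_numbers)
    )
  })
  do.call(rbind, rows)
}
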