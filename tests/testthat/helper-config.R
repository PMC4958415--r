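# Compact phantom configurations for unit tests: same physics as the
# defaults, smaller field of view / marker spread so renders stay cheap.
quick_config <- function(..., seed = 1) {
  phantom_config(pelvis_spread = c(50, 50, 36), cup_radius = 20,
                 fov = c(96, 96, 72), seed = seed, ...)
}

# single-bead volume: one pelvis bead at `offset` from the FOV center plus a
# far-away cup bead (render_ct needs both bodies); tiny FOV
render_single_bead <- function(offset = c(0, 0, 0), noise_sd = 0,
                               blur_sigma = 0.4, seed = 1,
                               supersample = 3) {
  # FOV chosen to give odd grid dimensions, so the FOV center (world origin
  # here) falls exactly on a voxel center
  cfg <- phantom_config(noise_sd = noise_sd, blur_sigma = blur_sigma,
                        fov = c(30.6, 30.6, 24.3), seed = seed,
                        supersample = supersample)
  pelvis <- marker_set(matrix(offset, 1, 3), body = "pelvis", ids = "p1")
  cup <- marker_set(matrix(c(10, 0, 0), 1, 3), body = "cup", ids = "c1")
  list(volume = render_ct(pelvis, cup, config = cfg, center = c(0, 0, 0),
                          seed = seed),
       config = cfg, truth = offset)
}

migration_cols <- c("dx", "dy", "dz", "rx", "ry", "rz")

# examination built directly from ground-truth markers (no rendering)
truth_examination <- function(manifest, position, series,
                              modality = "CT") {
  pose <- manifest$poses[[position]][[series]]
  examination(position, series,
              pelvis = apply_transform(pose, manifest$pelvis),
              cup = apply_transform(pose, manifest$positions[[position]]$cup),
              modality = modality)
}
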