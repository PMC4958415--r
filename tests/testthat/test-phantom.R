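test_that("phantom marker counts follow the cup type", {
  cem <- make_phantom_markers(phantom_config(cup_type = "cemented"))
  expect_equal(nrow(cem$pelvis), 9)
  expect_equal(nrow(cem$cup), 9)
  unc <- make_phantom_markers(phantom_config(cup_type = "uncemented"))
  expect_equal(nrow(unc$pelvis), 9)
  expect_equal(nrow(unc$cup), 12)
  expect_error(phantom_config(n_pelvis_markers = 2), "at least 3")
})

test_that("marker placement is seeded and respects separation constraints", {
  a <- make_phantom_markers(phantom_config(seed = 42))
  b <- make_phantom_markers(phantom_config(seed = 42))
  expect_identical(marker_coords(a$pelvis), marker_coords(b$pelvis))
  expect_identical(marker_coords(a$cup), marker_coords(b$cup))
  c2 <- make_phantom_markers(phantom_config(seed = 43))
  expect_false(identical(marker_coords(a$pelvis), marker_coords(c2$pelvis)))
  # beads never sit close enough to merge in the image
  pel <- marker_coords(a$pelvis); cup <- marker_coords(a$cup)
  expect_gt(min(dist(pel)), 12 - 1e-9)
  cross <- sqrt(outer(rowSums(pel^2), rowSums(cup^2), "+") -
                  2 * pel %*% t(cup))
  expect_gt(min(cross), 10 - 1e-9)
  # cup beads lie on the liner-periphery circle (in-plane radius)
  ctr <- colMeans(cup)
  expect_equal(sqrt((cup[, 1] - ctr[1])^2 + (cup[, 2] - ctr[2])^2),
               rep(25, 9), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("default pelvic scatter stays well inside the condition-number QC bound", {
  cn <- vapply(1:50, function(s) {
    as.numeric(condition_number(make_phantom_markers(
      phantom_config(seed = s))$pelvis))
  }, double(1))
  expect_true(all(cn < 100))
  expect_true(all(cn >= 1))
})

test_that("jig motions are exactly rigid", {
  cup <- make_phantom_markers(phantom_config(seed = 3))$cup
  shifted <- apply_jig(cup, jig_setting(dx = 1))
  expect_equal(marker_coords(shifted),
               marker_coords(cup) + rep(c(1, 0, 0), each = 9),
               tolerance = 1e-12)
  same <- apply_jig(cup, jig_setting())
  expect_equal(marker_coords(same), marker_coords(cup), tolerance = 1e-15)
  # rotation composition: two 90-degree turns equal one 180-degree turn
  twice <- apply_jig(apply_jig(cup, jig_setting(rx = 90)),
                     jig_setting(rx = 90))
  once <- apply_jig(cup, jig_setting(rx = 180))
  expect_lt(max(abs(marker_coords(twice) - marker_coords(once))), 1e-9)
  # pairwise distances preserved through an arbitrary setting
  moved <- apply_jig(cup, jig_setting(dx = 2, dy = -1, dz = 3, rx = 37))
  expect_lt(max(abs(dist(marker_coords(moved)) -
                      dist(marker_coords(cup)))), 1e-12)
})

test_that("the study design has 6 positions x 2 series with zero in-position migration", {
  man <- build_study(phantom_config(seed = 6))
  expect_length(man$positions, 6)
  expect_length(man$poses, 6)
  expect_true(all(lengths(man$poses) == 2)) # 12 examinations per cup
  # repositioning differs between the two series of every position
  for (p in 1:6)
    expect_false(isTRUE(all.equal(man$poses[[p]][[1]]$translation,
                                  man$poses[[p]][[2]]$translation)))
  # the cup is untouched within a position, so in-position migration is zero
  for (p in 1:6) {
    mig <- cupmig:::true_migration(man$positions[[p]]$cup,
                                   man$positions[[p]]$cup)
    expect_equal(unlist(mig[migration_cols]),
                 c(dx = 0, dy = 0, dz = 0, rx = 0, ry = 0, rz = 0),
                 tolerance = 1e-12)
  }
  expect_identical(build_study(phantom_config(seed = 6))$ground_truth,
                   man$ground_truth)
})

test_that("ground-truth pairwise migrations equal the composed jig settings", {
  man <- build_study(phantom_config(seed = 8))
  gt <- man$ground_truth
  # default schedule: every independent pair is 1.0 mm (x or y) + 1.0 deg
  expect_equal(gt$pair, c("1-2", "3-4", "5-6"))
  expect_equal(gt$dx, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(gt$dy + gt$dz, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(gt$rx, c(1, 1, 1), tolerance = 1e-12)
  expect_equal(gt$ry, rep(0, 3), tolerance = 1e-12)
  expect_equal(gt$rz, rep(0, 3), tolerance = 1e-12)
  # and a custom schedule is recovered exactly too
  man2 <- build_study(phantom_config(seed = 8),
                      schedule = full_range_schedule())
  g2 <- ground_truth_migration(man2, 3, 4)
  expect_equal(unlist(g2[migration_cols]),
               c(dx = 0, dy = 3, dz = 3, rx = -3, ry = 0, rz = 0),
               tolerance = 1e-10)
})

test_that("study manifests round-trip through JSON", {
  man <- build_study(phantom_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_manifest(man, path)
  back <- load_manifest(path)
  expect_equal(back$config, man$config)
  expect_equal(marker_coords(back$pelvis), marker_coords(man$pelvis))
  expect_equal(marker_coords(back$positions[[4]]$cup),
               marker_coords(man$positions[[4]]$cup))
  expect_equal(back$poses[[3]][[2]]$rotation, man$poses[[3]][[2]]$rotation)
  expect_equal(back$ground_truth, man$ground_truth)
})
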