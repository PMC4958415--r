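test_that("self-registration is the identity and QC passes", {
  man <- build_study(quick_config(seed = 2))
  ex <- truth_examination(man, 1, 1)
  reg <- register_exams(ex, ex)
  expect_equal(reg$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_true(reg$qc_pass)
  expect_equal(reg$n_pelvis_used, 9)
})

test_that("registration proceeds on the intersection of pelvic marker ids", {
  man <- build_study(quick_config(seed = 2))
  full <- truth_examination(man, 1, 1)
  reduced <- restrict_one <- examination(
    1, 2,
    pelvis = subset_markers(truth_examination(man, 1, 2)$pelvis,
                            paste0("p", 1:8)),
    cup = truth_examination(man, 1, 2)$cup)
  reg <- register_exams(reduced, full)
  expect_equal(reg$n_pelvis_used, 8)
  mig <- cup_migration(full, reduced, frame = man$pelvis)
  expect_lt(max(abs(unlist(mig[migration_cols]))), 1e-9)
  expect_equal(mig$n_pelvis_used, 8)
})

test_that("migration recovers the jig motion exactly from exact markers", {
  man <- build_study(quick_config(seed = 3))
  m <- cup_migration(truth_examination(man, 1, 1),
                     truth_examination(man, 2, 1), frame = man$pelvis)
  expect_equal(unlist(m[migration_cols]),
               c(dx = 1, dy = 0, dz = 0, rx = 1, ry = 0, rz = 0),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("reversing the examination order negates every component", {
  man <- build_study(quick_config(seed = 4))
  ab <- cup_migration(truth_examination(man, 1, 1),
                      truth_examination(man, 2, 1), frame = man$pelvis)
  ba <- cup_migration(truth_examination(man, 2, 1),
                      truth_examination(man, 1, 1), frame = man$pelvis)
  expect_equal(unlist(ab[migration_cols]) + unlist(ba[migration_cols]),
               setNames(rep(0, 6), migration_cols), tolerance = 1e-9)
})

test_that("migration components are invariant to phantom repositioning", {
  # the same physical cup motion measured under different whole-phantom
  # poses must yield identical components in the anatomical frame
  man <- build_study(quick_config(seed = 5))
  m11 <- cup_migration(truth_examination(man, 1, 1),
                       truth_examination(man, 2, 1), frame = man$pelvis)
  m22 <- cup_migration(truth_examination(man, 1, 2),
                       truth_examination(man, 2, 2), frame = man$pelvis)
  expect_equal(unlist(m11[migration_cols]), unlist(m22[migration_cols]),
               tolerance = 1e-9)
  # without the anatomical frame the scanner pose leaks into the axes
  s11 <- cup_migration(truth_examination(man, 1, 1),
                       truth_examination(man, 2, 1))
  s22 <- cup_migration(truth_examination(man, 1, 2),
                       truth_examination(man, 2, 2))
  expect_gt(max(abs(unlist(s11[migration_cols]) -
                      unlist(s22[migration_cols]))), 1e-3)
})

test_that("pairwise migrations cover 1-2, 3-4, 5-6 for both series", {
  man <- build_study(quick_config(seed = 6))
  exams <- unlist(lapply(1:6, function(p) lapply(1:2, function(s)
    truth_examination(man, p, s))), recursive = FALSE)
  pw <- pairwise_migrations(exams, frame = man$pelvis)
  expect_equal(nrow(pw), 6)
  expect_equal(pw$pair, rep(c("1-2", "3-4", "5-6"), each = 2))
  expect_equal(pw$series_a, rep(1:2, 3))
  gt <- man$ground_truth[rep(1:3, each = 2), migration_cols]
  expect_lt(max(abs(as.matrix(pw[migration_cols]) - as.matrix(gt))), 1e-9)
  # double examinations measure exactly zero on exact markers
  dbl <- double_exam_migrations(exams, frame = man$pelvis)
  expect_lt(max(abs(as.matrix(dbl[migration_cols]))), 1e-9)
  expect_error(pairwise_migrations(exams[1:6]), "missing position")
})

test_that("too few shared cup markers is an error", {
  man <- build_study(quick_config(seed = 7))
  a <- truth_examination(man, 1, 1)
  b <- truth_examination(man, 2, 1)
  b$cup <- subset_markers(b$cup, paste0("c", 1:3))
  a$cup <- subset_markers(a$cup, paste0("c", 4:9))
  expect_error(cup_migration(a, b), "shared cup markers")
})
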