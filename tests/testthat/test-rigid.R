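random_points <- function(n = 9, scale = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * 3, -scale, scale), n, 3)
}

test_that("rigid fits recover exact transforms and the identity", {
  X <- random_points(seed = 1)
  fit0 <- fit_rigid(X, X)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit0$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit0$quality$mean_error, 0, tolerance = 1e-12)
  tr <- cardan_transform(12, -7, 33, c(4, -6, 2))
  fit <- fit_rigid(X, apply_transform(tr, X))
  expect_lt(max(abs(fit$transform$rotation - tr$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - tr$translation)), 1e-9)
  expect_lt(fit$quality$mean_error, 1e-9)
})

test_that("the SVD fit matches a brute-force rotation optimizer to 1e-9", {
  for (s in 1:20) {
    set.seed(s)
    X <- random_points()
    tr <- cardan_transform(runif(1, -90, 90), runif(1, -60, 60),
                           runif(1, -90, 90), runif(3, -20, 20))
    Y <- apply_transform(tr, X) + matrix(rnorm(27, sd = 0.05), 9, 3)
    fit <- fit_rigid(X, Y)
    oracle <- oracle_fit_rigid(X, Y)
    expect_lt(max(abs(fit$transform$rotation - oracle$rotation)), 1e-9)
    expect_lt(max(abs(fit$transform$translation - oracle$translation)),
              1e-9)
  }
})

test_that("fitting is left-invariant under a common rigid motion", {
  X <- random_points(seed = 5)
  Y <- apply_transform(cardan_transform(3, 1, -2, c(1, 1, 1)), X) +
    matrix(rnorm(27, sd = 0.1), 9, 3)
  base <- fit_rigid(X, Y)
  pre <- cardan_transform(40, -25, 65, c(30, -12, 8))
  moved <- fit_rigid(apply_transform(pre, X), apply_transform(pre, Y))
  expect_equal(moved$quality$mean_error, base$quality$mean_error,
               tolerance = 1e-9)
  # and rotations are always proper
  for (f in list(base, moved)) {
    R <- f$transform$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("degenerate configurations are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(fit_rigid(line, line + 1), "collinear")
  expect_error(fit_rigid(random_points(2), random_points(2)), ">= 3")
  # marker sets correspond by id, and fits need >= 3 shared ids
  a <- marker_set(random_points(seed = 2), body = "pelvis",
                  ids = paste0("p", 1:9))
  b <- marker_set(random_points(seed = 3), body = "pelvis",
                  ids = paste0("q", 1:9))
  expect_error(fit_rigid(a, b), "shared markers")
})

test_that("Cardan angles decompose and recompose exactly", {
  expect_equal(decompose_cardan(diag(3)), c(rx = 0, ry = 0, rz = 0))
  expect_equal(decompose_cardan(cardan_transform(1, 0, 0)),
               c(rx = 1, ry = 0, rz = 0), tolerance = 1e-12)
  set.seed(9)
  worst <- 0
  for (i in 1:200) {
    ang <- c(runif(1, -179, 179), runif(1, -80, 80), runif(1, -179, 179))
    R <- cardan_transform(ang[1], ang[2], ang[3])$rotation
    back <- decompose_cardan(R)
    R2 <- cardan_transform(back[1], back[2], back[3])$rotation
    worst <- max(worst, max(abs(R2 - R)))
  }
  expect_lt(worst, 1e-9)
  expect_error(decompose_cardan(cardan_transform(10, 89.5, -5)),
               "gimbal")
})

test_that("the condition number flags marker scatter quality", {
  cube <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  expect_equal(as.numeric(condition_number(cube)), 1, tolerance = 1e-12)
  expect_true(attr(condition_number(cube), "qc_ok"))
  line <- cbind(1:6, 1:6, 1:6)
  cn_line <- condition_number(line)
  expect_identical(as.numeric(cn_line), Inf)
  expect_false(attr(cn_line, "qc_ok"))
  # invariance under rigid motion and uniform scaling
  X <- random_points(seed = 11)
  base <- as.numeric(condition_number(X))
  moved <- apply_transform(cardan_transform(31, -22, 47, c(5, 5, 5)), X)
  expect_equal(as.numeric(condition_number(moved)), base,
               tolerance = 1e-9)
  expect_equal(as.numeric(condition_number(X * 7.3)), base,
               tolerance = 1e-9)
})

test_that("the rigid-body mean error measures marker instability", {
  ids <- paste0("p", 1:9)
  X <- random_points(seed = 21)
  a <- marker_set(X, body = "pelvis", ids = ids)
  expect_equal(mean_error_between_exams(a, a), 0, tolerance = 1e-12)
  # jittered markers: equals the directly computed RMS residual
  set.seed(22)
  Y <- X + matrix(rnorm(27, sd = 0.1), 9, 3)
  b <- marker_set(Y, body = "pelvis", ids = ids)
  me <- mean_error_between_exams(a, b)
  fit <- fit_rigid(X, Y)
  res <- Y - apply_transform(fit$transform, X)
  expect_equal(me, sqrt(mean(rowSums(res^2))), tolerance = 1e-12)
  expect_lt(me, 0.35) # stable body: inside the QC bound
  # one marker displaced 1 mm: instability detected
  Z <- X; Z[5, ] <- Z[5, ] + c(1, 0, 0)
  c_ <- marker_set(Z, body = "pelvis", ids = ids)
  expect_gt(mean_error_between_exams(a, c_), 0.25)
  res1 <- Z - apply_transform(fit_rigid(X, Z)$transform, X)
  expect_equal(mean_error_between_exams(a, c_),
               sqrt(mean(rowSums(res1^2))), tolerance = 1e-12)
})

test_that("transform composition and inversion are consistent", {
  a <- cardan_transform(10, 20, 30, c(1, 2, 3))
  b <- cardan_transform(-5, 12, -40, c(-2, 0, 4))
  p <- random_points(4, seed = 30)
  expect_equal(apply_transform(compose_transforms(a, b), p),
               apply_transform(a, apply_transform(b, p)),
               tolerance = 1e-12)
  roundtrip <- compose_transforms(invert_transform(a), a)
  expect_equal(roundtrip$rotation, diag(3), tolerance = 1e-12)
  expect_equal(roundtrip$translation, c(0, 0, 0), tolerance = 1e-12)
})
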