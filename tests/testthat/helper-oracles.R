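# Independent oracles used to validate the closed-form implementations.

# Brute-force rigid fit: minimise the sum of squared residuals over the
# three Cardan rotation parameters (translation eliminated in closed form),
# by quasi-Newton iteration with an analytic gradient. Shares nothing with
# the SVD (Kabsch) solution path.
oracle_fit_rigid <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  H <- crossprod(Xc, Yc) # maximise tr(R %*% H)
  rot_parts <- function(theta) {
    a <- theta[1]; b <- theta[2]; g <- theta[3]
    Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    dRx <- rbind(c(0, 0, 0), c(0, -sin(a), -cos(a)), c(0, cos(a), -sin(a)))
    dRy <- rbind(c(-sin(b), 0, cos(b)), c(0, 0, 0), c(-cos(b), 0, -sin(b)))
    dRz <- rbind(c(-sin(g), -cos(g), 0), c(cos(g), -sin(g), 0), c(0, 0, 0))
    list(R = Rx %*% Ry %*% Rz,
         grad = c(sum(diag((dRx %*% Ry %*% Rz) %*% H)),
                  sum(diag((Rx %*% dRy %*% Rz) %*% H)),
                  sum(diag((Rx %*% Ry %*% dRz) %*% H))))
  }
  fn <- function(theta) -sum(diag(rot_parts(theta)$R %*% H))
  gr <- function(theta) -rot_parts(theta)$grad
  best <- NULL
  starts <- rbind(c(0, 0, 0), c(0.5, -0.3, 0.8), c(-1, 1, -1), c(2, 0.5, 2))
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], fn, gr, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # Newton polish on the analytic gradient (numeric Jacobian) down to
  # machine-precision stationarity
  theta <- best$par
  for (it in 1:25) {
    g <- gr(theta)
    if (max(abs(g)) < 1e-13) break
    h <- 1e-6
    J <- vapply(1:3, function(k) {
      e <- numeric(3); e[k] <- h
      (gr(theta + e) - gr(theta - e)) / (2 * h)
    }, double(3))
    step <- tryCatch(solve(J, g), error = function(e) g * 0)
    if (!all(is.finite(step)) || max(abs(step)) > 0.5) break
    theta <- theta - step
  }
  R <- rot_parts(theta)$R
  list(rotation = R,
       translation = colMeans(Y) - as.vector(R %*% colMeans(X)))
}

# 3D numeric convolution of the unit ball with an isotropic Gaussian,
# evaluated at distance r from the ball center (Riemann sum oracle)
oracle_ball_blur <- function(r, radius, sigma, n = 60) {
  g <- seq(-radius, radius, length.out = n)
  step <- g[2] - g[1]
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  sum(exp(-((pts[, 1] - r)^2 + pts[, 2]^2 + pts[, 3]^2) / (2 * sigma^2))) *
    step^3 / ((2 * pi)^1.5 * sigma^3)
}

# symmetric-coverage t multiplier by numeric integration of the hand-written
# t density (no calls into R's t distribution functions)
oracle_t_multiplier <- function(p, dof) {
  dens <- function(x)
    gamma((dof + 1) / 2) / (sqrt(dof * pi) * gamma(dof / 2)) *
      (1 + x^2 / dof)^(-(dof + 1) / 2)
  cover <- function(m)
    2 * integrate(dens, 0, m, rel.tol = 1e-12)$value - p
  uniroot(cover, c(1e-9, 1e3), tol = 1e-10)$root
}
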