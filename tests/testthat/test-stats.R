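test_that("t multipliers reproduce the conventional RSA factors", {
  expect_equal(round(t_quantile(0.95, 6), 2), 2.45)
  expect_equal(round(t_quantile(0.95, 5), 2), 2.57)
  # numeric-integration oracle of the t density, dof 1..30
  for (dof in c(1, 2, 5, 6, 12, 30))
    expect_equal(t_quantile(0.95, dof), oracle_t_multiplier(0.95, dof),
                 tolerance = 1e-6)
  expect_error(t_quantile(1.2, 5), "probability")
  expect_error(t_quantile(0.95, 0), "dof")
})

fake_doubles <- function(mat) {
  df <- as.data.frame(matrix(0, nrow(mat), 6))
  names(df) <- migration_cols
  df[, seq_len(ncol(mat))] <- mat
  df
}

test_that("precision summarises double-examination differences as m x SD", {
  zeros <- fake_doubles(matrix(0, 6, 6))
  ps <- precision_summary(zeros)
  expect_equal(ps$precision, rep(0, 6))
  expect_equal(ps$mean, rep(0, 6))
  # symmetric differences +/- d: mean 0, min -d, max +d, SD about zero = d
  d <- 0.05
  sym <- fake_doubles(cbind(rep(c(d, -d), 3), matrix(0, 6, 5)))
  ps2 <- precision_summary(sym)
  expect_equal(ps2$mean[1], 0)
  expect_equal(ps2$min[1], -d)
  expect_equal(ps2$max[1], d)
  expect_equal(ps2$precision[1], t_quantile(0.95, 6) * d,
               tolerance = 1e-12)
  expect_equal(ps2$dof[1], 6) # SD about zero keeps all 6 d.o.f.
  # mean-subtracted variant drops one degree of freedom
  ps3 <- precision_summary(sym, about_zero = FALSE)
  expect_equal(ps3$dof[1], 5)
  expect_equal(ps3$precision[1], t_quantile(0.95, 5) * sd(sym$dx))
  expect_error(precision_summary(zeros[1, ]), "at least 2")
})

test_that("swapping the series labels flips signs but not the precision", {
  set.seed(41)
  d <- fake_doubles(matrix(rnorm(36, sd = 0.05), 6, 6))
  flipped <- fake_doubles(-as.matrix(d))
  a <- precision_summary(d); b <- precision_summary(flipped)
  expect_equal(b$precision, a$precision, tolerance = 1e-12)
  expect_equal(b$mean, -a$mean, tolerance = 1e-12)
  expect_equal(b$min, -a$max, tolerance = 1e-12)
  expect_equal(b$max, -a$min, tolerance = 1e-12)
})

fake_pairs <- function(mat) {
  cbind(data.frame(pair = rep(c("1-2", "3-4", "5-6"),
                              length.out = nrow(mat)),
                   series_a = rep(1:2, each = 3, length.out = nrow(mat))),
        fake_doubles(mat))
}

test_that("accuracy summarises gold-minus-method differences as m x RMS", {
  m <- fake_pairs(matrix(rnorm(36), 6, 6))
  perfect <- accuracy_summary(m, m)
  expect_equal(perfect$accuracy, rep(0, 6))
  # hand-computed case: differences {0.1, -0.1, 0.1} on one component
  method <- fake_pairs(matrix(0, 3, 6))
  gold <- fake_pairs(cbind(c(0.1, -0.1, 0.1), matrix(0, 3, 5)))
  as_ <- accuracy_summary(method, gold)
  expect_equal(as_$rms[1], 0.1, tolerance = 1e-12)
  expect_equal(as_$accuracy[1], t_quantile(0.95, 2) * 0.1,
               tolerance = 1e-12)
  expect_equal(as_$n[1], 3)
  expect_equal(as_$mean[1], mean(c(0.1, -0.1, 0.1)))
  # m x RMS always dominates m x |mean|
  set.seed(42)
  g2 <- fake_pairs(matrix(rnorm(36, mean = 0.1, sd = 0.2), 6, 6))
  a2 <- accuracy_summary(m, g2)
  expect_true(all(a2$accuracy >= a2$multiplier * abs(a2$mean) - 1e-12))
  # mismatched pairings are rejected
  bad <- fake_pairs(matrix(0, 3, 6))
  expect_error(accuracy_summary(m, bad), "pair")
})

test_that("effective dose is the DLP times the conversion factor", {
  expect_equal(effective_dose(0, 0.015), 0)
  expect_equal(effective_dose(22, 0.015), 0.33)
  expect_equal(effective_dose(100, 0.015), 1.5)
  expect_error(effective_dose(-1, 0.015), "non-negative")
  expect_error(effective_dose(10, -0.2), "non-negative")
})

test_that("normality diagnostics flag the right samples", {
  set.seed(101)
  ok <- normality_check(rnorm(100))
  expect_false(ok$departure)
  expect_false(ok$degenerate)
  const <- normality_check(rep(0.2, 10))
  expect_true(const$degenerate)
  set.seed(102)
  heavy <- normality_check(rt(100, df = 1))
  expect_true(heavy$departure)
  expect_error(normality_check(c(1, 2)), "n >= 3")
})
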