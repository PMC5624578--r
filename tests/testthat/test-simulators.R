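test_that("pole expansion reproduces hand-expanded polynomials", {
  expect_equal(poles_to_coefficients(0.65, 0), 0.65)
  expect_equal(poles_to_coefficients(c(0.5, 0.3), c(0, 0)), c(0.8, -0.15))
  # negative real pole: (1 - (-rho) z^-1) -> a1 = -rho
  expect_equal(poles_to_coefficients(0.4, 0.5), -0.4)
  a <- poles_to_coefficients(c(0.65, 0.8, 0.92), c(0, 0.1, 0.25))
  expect_equal(round(a, 3), c(1.944, -2.328, 2.062, -1.254, 0.352))
  expect_error(poles_to_coefficients(1.0, 0), "\\[0, 1\\)")
})

test_that("pole round trip through coefficients is exact to 1e-10", {
  set.seed(88)
  for (i in 1:30) {
    n_pairs <- sample(0:2, 1)
    n_real <- sample(if (n_pairs == 0) 1:2 else 0:2, 1)
    mods <- runif(n_pairs + n_real, 0.1, 0.95)
    freqs <- c(runif(n_pairs, 0.02, 0.48),
               sample(c(0, 0.5), n_real, replace = TRUE))
    a <- poles_to_coefficients(mods, freqs)
    r <- polyroot(c(-rev(a), 1))
    got_mod <- sort(Mod(r))
    want_mod <- sort(rep(mods, ifelse(freqs %in% c(0, 0.5), 1, 2)))
    expect_equal(got_mod, want_mod, tolerance = 1e-10)
    got_f <- sort(unique(round(abs(Arg(r)) / (2 * pi), 9)))
    expect_equal(got_f, sort(unique(round(freqs, 9))), tolerance = 1e-9)
  }
})

test_that("the linear simulator has the model's second-order statistics", {
  expect_true(all(simulate_ar(ar_model(0.5, 0), 100, seed = 1)$values == 0))
  x1 <- simulate_ar(ar_model(0.5, 1), n = 1e5, seed = 17)
  expect_equal(var(x1$values), 4 / 3, tolerance = 0.02)
  m <- benchmark_model()
  x5 <- simulate_ar(m, n = 1e5, seed = 18)
  g <- yw_autocov(m$a, m$sw, max_lag = 1)   # direct Yule-Walker oracle
  v <- x5$values - mean(x5$values)
  rho1_sim <- sum(v[-1] * v[-length(v)]) / sum(v^2)
  expect_equal(rho1_sim, g[2] / g[1], tolerance = 0.02)
  # the Yule-Walker gamma_0 cross-checks the covariance-solve variance
  expect_equal(g[1], process_variance(m), tolerance = 1e-10)
})

test_that("simulated series are weakly stationary after burn-in", {
  for (s in 1:5) {
    x <- simulate_ar(benchmark_model(), n = 1e4, seed = s)$values
    ratio <- var(x[1:5000]) / var(x[5001:10000])
    expect_gt(ratio, 0.7)
    expect_lt(ratio, 1.4)
  }
})

test_that("simulators are seed-deterministic", {
  m <- benchmark_model()
  expect_identical(simulate_ar(m, 300, seed = 5)$values,
                   simulate_ar(m, 300, seed = 5)$values)
  expect_false(identical(simulate_ar(m, 300, seed = 5)$values,
                         simulate_ar(m, 300, seed = 6)$values))
  expect_identical(simulate_squared(m, 0.02, 300, seed = 5)$values,
                   simulate_squared(m, 0.02, 300, seed = 5)$values)
  expect_identical(
    simulate_threshold(m$a, gamma_rel = 1, n = 300, seed = 5)$values,
    simulate_threshold(m$a, gamma_rel = 1, n = 300, seed = 5)$values)
})

test_that("the quadratic simulator reduces to the linear one at beta = 0", {
  m <- benchmark_model()
  expect_identical(simulate_squared(m, beta = 0, n = 500, seed = 42)$values,
                   simulate_ar(m, n = 500, seed = 42)$values)
})

test_that("mild quadratic nonlinearity stays finite near the linear variance", {
  m <- benchmark_model()
  x <- simulate_squared(m, beta = 0.02, n = 5000, seed = 7)
  expect_true(all(is.finite(x$values)))
  expect_lt(abs(var(x$values) - process_variance(m)) / process_variance(m),
            0.5)
  for (s in 1:100)
    expect_true(all(is.finite(
      simulate_squared(m, beta = 0.02, n = 300, seed = s)$values)))
})

test_that("strong quadratic nonlinearity triggers the divergence monitor", {
  # beta = 0.06 puts the quadratic term outside its contraction basin at
  # the benchmark amplitude: the guard must fire and name the seed
  m <- benchmark_model()
  errs <- vapply(1:20, function(s)
    inherits(tryCatch(simulate_squared(m, beta = 0.06, n = 300, seed = s),
                      error = function(e) e), "error"), logical(1))
  expect_gt(sum(errs), 0)
  expect_error(simulate_squared(m, beta = 0.06, n = 300, seed = 1),
               "seed 1")
})

test_that("the threshold simulator switches regimes at the scaled threshold", {
  m <- benchmark_model()
  # a threshold far in the tail never triggers regime b
  expect_identical(
    simulate_threshold(m$a, gamma_rel = 1e6, n = 500, seed = 13)$values,
    simulate_ar(m, n = 500, seed = 13)$values)
  x3 <- simulate_threshold(m$a, gamma_rel = 3, n = 1e5, seed = 14)
  expect_lt(attr(x3, "regime_b_fraction"), 0.01)
  x1 <- simulate_threshold(m$a, gamma_rel = 1, n = 1e5, seed = 15)
  occ <- attr(x1, "regime_b_fraction")
  expect_gt(occ, 0.05)
  expect_lt(occ, 0.40)
})

test_that("the sinusoidal trend adds the expected power", {
  m <- benchmark_model()
  x <- simulate_ar(m, 300, seed = 20)
  expect_identical(add_trend(x, 0, 600, seed = 1)$values, x$values)
  flat <- ar_ts(rep(5, 100))
  expect_identical(add_trend(flat, 1, 600, seed = 1)$values, flat$values)
  # whole cycles: amplitude = series SD -> sinusoid power SD^2/2 -> 1.5x
  ratios_full <- vapply(1:100, function(s) {
    xs <- simulate_ar(m, 300, seed = s)
    var(add_trend(xs, 1, 150, seed = s + 1000)$values) / var(xs$values)
  }, numeric(1))
  expect_equal(mean(ratios_full), 1.5, tolerance = 0.1)
  # half a cycle (period 600 s over 300 s of data): mean removal absorbs
  # the sinusoid's DC, leaving 1/2 - 2/pi^2 of phase-averaged power
  ratios_half <- vapply(1:100, function(s) {
    xs <- simulate_ar(m, 300, seed = s)
    var(add_trend(xs, 1, 600, seed = s + 1000)$values) / var(xs$values)
  }, numeric(1))
  expect_equal(mean(ratios_half), 1 + 0.5 - 2 / pi^2, tolerance = 0.1)
})

test_that("the gold standard reduces to a single fit at one realization", {
  m <- benchmark_model()
  g1 <- gold_standard(m, n = 300, n_realizations = 1, seed = 77)
  x <- simulate_ar(m, n = 300,
                   seed = arclim:::.child_seeds(77, 1)[[1]])
  fit <- ar_fit(x, order = 5)
  expect_equal(unlist(g1[1, ]), as.numeric(hrv_indexes(fit$model)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("gold-standard intervals shrink with the series length", {
  m <- benchmark_model()
  g_short <- gold_standard(m, n = 120, n_realizations = 500, seed = 5)
  g_long <- gold_standard(m, n = 600, n_realizations = 500, seed = 5)
  for (k in c("f_lf", "p_lfhf", "s_x"))
    expect_lt(IQR(g_long[[k]], na.rm = TRUE),
              IQR(g_short[[k]], na.rm = TRUE))
})

test_that("gold-standard medians fall inside single-recording MC intervals", {
  m <- benchmark_model()
  g <- gold_standard(m, n = 300, n_realizations = 1000, seed = 50)
  g_med <- median(g$s_x, na.rm = TRUE)
  inside <- vapply(1:100, function(s) {
    fit <- ar_fit(simulate_ar(m, 300, seed = 7000 + s), order = 5)
    rep <- ar_replicates(fit, "mc", m = 500, seed = s)
    q <- quantile(rep$indexes[, "s_x"], c(0.05, 0.95), na.rm = TRUE)
    g_med >= q[1] && g_med <= q[2]
  }, logical(1))
  expect_gte(sum(inside), 85)
})
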