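test_that("the AR spectrum matches closed forms and integrates to the variance", {
  # white noise: flat at sw * dt
  s <- ar_psd(ar_model(0, sw = 1, dt = 1), n_freqs = 16)
  expect_equal(s$density, rep(1, 16))
  # AR(1): P(0) = sw / (1 - a)^2
  s1 <- ar_psd(ar_model(0.5, 1), n_freqs = 64)
  expect_equal(s1$density[1], 4)
  # benchmark: two-sided quadrature equals the stationary variance
  m <- benchmark_model()
  s5 <- ar_psd(m, n_freqs = 8193)
  df <- diff(s5$frequency[1:2])
  int2 <- 2 * (sum(s5$density) - (s5$density[1] + s5$density[8193]) / 2) * df
  expect_equal(int2, process_variance(m), tolerance = 1e-3)
  expect_error(ar_psd(ar_model(1.01, 1)), "unstable")
})

test_that("the model-implied variance matches closed forms and a long simulation", {
  expect_equal(process_variance(ar_model(0.5, 1)), 4 / 3)
  expect_equal(process_variance(ar_model(c(0, 0, 0), 2)), 2)
  m <- benchmark_model()
  x <- simulate_ar(m, n = 1e6, seed = 99)
  expect_equal(process_variance(m), var(x$values), tolerance = 0.01)
  # and the information storage follows from the same simulated ratio
  expect_equal(information_storage(m), 0.5 * log(var(x$values) / m$sw),
               tolerance = 0.01)
})

test_that("spectral decomposition splits the benchmark into VLF/LF/HF", {
  d <- spectral_decomposition(benchmark_model())
  expect_identical(nrow(d$components), 3L)
  expect_equal(d$components$frequency, c(0, 0.1, 0.25), tolerance = 1e-9)
  expect_equal(d$components$kind,
               c("real", "conjugate-pair", "conjugate-pair"))
  expect_equal(d$total_variance, process_variance(benchmark_model()),
               tolerance = 1e-10)
  # single-pole model: one component at f = 0 holding the whole variance
  d1 <- spectral_decomposition(ar_model(0.5, 1))
  expect_identical(nrow(d1$components), 1L)
  expect_equal(d1$components$frequency, 0)
  expect_equal(d1$components$power, 4 / 3)
})

test_that("component powers agree with the contour-integration oracle", {
  m <- benchmark_model()
  d <- spectral_decomposition(m)
  orc <- contour_component_powers(m$a, m$sw, m$dt)
  orc <- orc[order(orc$frequency), ]
  expect_equal(d$components$power, orc$power, tolerance = 1e-8)
  # and so does the LF/HF ratio computed from them
  lf <- orc$power[orc$frequency >= 0.04 & orc$frequency <= 0.15]
  hf <- orc$power[orc$frequency > 0.15 & orc$frequency <= 0.4]
  expect_equal(lf_hf_ratio(d), sum(lf) / sum(hf), tolerance = 1e-8)
})

test_that("component powers conserve the process variance on random models", {
  set.seed(4242)
  n_neg <- 0L
  for (i in 1:500) {
    p <- sample(1:5, 1)
    a <- random_stable_coefs(p)
    sw <- runif(1, 0.2, 3)
    m <- ar_model(a, sw)
    d <- suppressWarnings(spectral_decomposition(m))
    expect_equal(d$total_variance, process_variance(m),
                 tolerance = 1e-6)
    if (any(d$components$power < 0)) n_neg <- n_neg + 1L
    expect_true(all(d$components$frequency >= 0 &
                      d$components$frequency <= 1 / (2 * m$dt)))
  }
  # the residue method does produce negative powers for interacting poles
  expect_gt(n_neg, 0L)
})

test_that("repeated poles are rejected", {
  a <- poles_to_coefficients(c(0.5, 0.5), c(0, 0))   # double real pole
  expect_error(spectral_decomposition(ar_model(a, 1)), "epeated poles")
})

test_that("information storage is the log variance ratio and is nonnegative", {
  expect_identical(information_storage(ar_model(0, 1)), 0)
  expect_equal(information_storage(ar_model(0.5, 1)), 0.5 * log(4 / 3))
  expect_equal(information_storage(ar_model(0.5, 1)), 0.1438, tolerance = 1e-3)
  set.seed(515)
  for (i in 1:100) {
    a <- random_stable_coefs(sample(1:5, 1))
    s <- information_storage(ar_model(a, runif(1, 0.5, 2)))
    expect_gte(s, 0)
    if (any(a != 0)) expect_gt(s, 0)
  }
  expect_error(information_storage(ar_model(0.5, 0)), "degenerate")
})

test_that("the LF peak rule picks the in-band component nearest 0.1 Hz", {
  fake <- function(freqs, powers) {
    structure(list(components = data.frame(frequency = freqs, power = powers,
                                           kind = "x", pole_modulus = 0.5),
                   total_variance = sum(powers)),
              class = "ar_decomp")
  }
  expect_equal(lf_central_frequency(fake(c(0, 0.1, 0.25), c(1, 2, 1))), 0.1)
  expect_true(is.na(lf_central_frequency(fake(c(0, 0.25), c(1, 1)))))
  expect_equal(lf_central_frequency(fake(c(0.05, 0.12), c(1, 1))), 0.12)
  expect_equal(lf_hf_ratio(fake(c(0.1, 0.3), c(2, 1))), 2)
  expect_true(is.na(lf_hf_ratio(fake(c(0, 0.3), c(1, 1)))))
  # a component above the HF edge belongs to neither band
  expect_true(is.na(lf_hf_ratio(fake(c(0.1, 0.45), c(2, 1)))))
})

test_that("the index set bundles the three indexes with explicit NAs", {
  i5 <- hrv_indexes(benchmark_model())
  expect_equal(i5$f_lf, 0.1, tolerance = 1e-9)
  expect_true(is.finite(i5$p_lfhf) && i5$p_lfhf > 0)
  expect_true(is.finite(i5$s_x) && i5$s_x > 0)
  # AR(1): only an f = 0 component -> spectral indexes undefined
  i1 <- hrv_indexes(ar_model(0.5, 1))
  expect_true(is.na(i1$f_lf) && is.na(i1$p_lfhf))
  expect_equal(i1$s_x, 0.1438, tolerance = 1e-3)
  # a white-noise fit stores almost no information
  set.seed(12)
  fit <- ar_fit(ar_ts(rnorm(1000)), order = 5)
  iw <- hrv_indexes(fit$model)
  expect_lt(iw$s_x, 0.05)
  expect_error(hrv_indexes(ar_model(1.2, 1)), "unstable")
})
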