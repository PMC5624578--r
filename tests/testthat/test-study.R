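test_that("a one-cell study produces a single row and no detections", {
  st <- run_simulation_study(list(sim_config(benchmark_model(), n = 300,
                                             label = "only")),
                             runs = 1, m = 50, seed = 4)
  expect_identical(nrow(st$rows), 1L)
  expect_null(st$detections)
  expect_identical(st$rows$label, "only")
  expect_equal(st$rows$true_f_lf, 0.1, tolerance = 1e-9)
})

test_that("the study driver is deterministic in its master seed", {
  grid <- list(sim_config(benchmark_model(), n = 120, label = "a"),
               sim_config(benchmark_model(), n = 120, label = "b"))
  s1 <- run_simulation_study(grid, runs = 3, m = 50, seed = 99)
  s2 <- run_simulation_study(grid, runs = 3, m = 50, seed = 99)
  expect_identical(s1$rows, s2$rows)
  expect_identical(s1$detections, s2$detections)
})

test_that("gold-standard percentiles can be attached to study rows", {
  st <- run_simulation_study(list(sim_config(benchmark_model(), n = 300)),
                             runs = 2, m = 50, seed = 12,
                             include_gold = TRUE, n_gold = 50)
  expect_true(all(c("gold_s_x_p5", "gold_s_x_p95") %in% names(st$rows)))
  expect_lt(st$rows$gold_s_x_p5, st$rows$gold_s_x_p95)
})

test_that("the binomial false-positive ceiling matches direct summation", {
  expect_identical(binomial_false_positive_bound(100, 0.05, 0.95), 9L)
  expect_identical(binomial_false_positive_bound(1, 0.5, 0.95), 1L)
  # direct CDF summation oracle for the third case
  cdf <- cumsum(dbinom(0:20, 20, 0.05))
  expect_identical(binomial_false_positive_bound(20, 0.05, 0.95),
                   as.integer(which(cdf >= 0.95)[1] - 1))
  expect_identical(binomial_false_positive_bound(20, 0.05, 0.95), 3L)
})

test_that("R-R files are parsed with units, headers and error locations", {
  f <- tempfile(fileext = ".txt")
  writeLines(rep("1000", 300), f)
  rr <- read_rr_series(f)
  expect_length(rr$values, 300)
  expect_equal(rr$dt, 1.0)

  writeLines(c("0.8", "0.9", "1.0", "0.85"), f)
  rr_s <- read_rr_series(f, units = "s")
  expect_equal(rr_s$values, c(800, 900, 1000, 850))

  writeLines(c("rr_ms", as.character(900:950)), f)   # header tolerated
  expect_length(read_rr_series(f)$values, 51)

  writeLines(c(as.character(900:905), "abc", "907"), f)
  expect_error(read_rr_series(f), "line 7")
  writeLines(c("900", "-5", "910"), f)
  expect_error(read_rr_series(f), "onpositive")

  fc <- tempfile(fileext = ".csv")
  writeLines(c("beat,rr", "1,800", "2,820", "3,810"), fc)
  expect_equal(read_rr_series(fc)$values, c(800, 820, 810))
  writeLines(c("beat,interval", "1,800"), fc)
  expect_error(read_rr_series(fc), "rr")
})

test_that("result tables round-trip through CSV and JSON", {
  rows <- data.frame(subject = c("s1", "s2"),
                     f_lf = c(0.1012345678, NA),
                     s_x = c(1.23456789, 0.5))
  fc <- tempfile(fileext = ".csv")
  write_results(rows, fc, "csv")
  back <- read.csv(fc)
  expect_identical(names(back), names(rows))
  expect_true(is.na(back$f_lf[2]))
  expect_equal(back$f_lf[1], signif(rows$f_lf[1], 6))

  fj <- tempfile(fileext = ".json")
  write_results(rows, fj, "json")
  bj <- jsonlite::fromJSON(fj)
  expect_equal(bj$s_x, signif(rows$s_x, 6))
  expect_true(is.na(bj$f_lf[2]))
  expect_match(paste(readLines(fj), collapse = ""), "\"NA\"")
  expect_error(write_results(rows[0, ], fc), "empty")
})

test_that("simulation configs serialize to flat key-value files", {
  cfg <- sim_config(benchmark_model(), n = 300, fit_order = 5,
                    label = "bench", trend_amplitude_rel = 0.5,
                    trend_period_s = 600)
  f <- tempfile(fileext = ".yml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$model$a, cfg$model$a)
  expect_identical(cfg2$n, cfg$n)
  expect_identical(cfg2$trend_period_s, 600)
  # pole-based specification
  writeLines(c("pole_moduli: [0.65, 0.8, 0.92]",
               "pole_frequencies: [0.0, 0.1, 0.25]",
               "n_samples: 120"), f)
  cfg3 <- read_sim_config(f)
  expect_equal(cfg3$model$a, coef(benchmark_model()))
  # two generator modes at once are rejected
  expect_error(sim_config(benchmark_model(), beta = 0.02,
                          threshold_gamma_rel = 1), "one generator mode")
})

test_that("a null synthetic cohort shows mostly non-significant changes", {
  coh <- synthetic_cohort(n_subjects = 25, tasks = c("A", "B"), seed = 61)
  res <- run_cohort_analysis(coh, m = 300, seed = 62)
  expect_identical(nrow(res$rows), 50L)
  expect_true(all(res$rows$order >= 5 & res$rows$order <= 15))
  for (k in c("f_lf", "p_lfhf", "s_x")) {
    g <- res$group[res$group$index == k, ]
    expect_gte(g$pct_ns, 80)
  }
})

test_that("a directional cohort effect is detected in the right direction", {
  models <- list(A = benchmark_model(rho_lf = 0.8),
                 B = benchmark_model(rho_lf = 0.9))
  coh <- synthetic_cohort(n_subjects = 25, tasks = c("A", "B"),
                          task_models = models, seed = 63)
  res <- run_cohort_analysis(coh, m = 300, order_range = c(5, 8), seed = 64)
  g <- res$group[res$group$index == "p_lfhf", ]
  expect_gt(g$pct_increase, g$pct_decrease)
})

test_that("subjects with missing tasks are excluded with a warning", {
  coh <- synthetic_cohort(n_subjects = 3, tasks = c("A", "B"), seed = 65)
  coh$subject02$B <- NULL
  expect_warning(res <- run_cohort_analysis(coh, m = 50,
                                            order_range = c(5, 6),
                                            seed = 66),
                 "subject02")
  expect_identical(sort(unique(res$rows$subject)),
                   c("subject01", "subject03"))
})
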