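#' Simulation configuration
#'
#' One cell of a simulation-study grid: the generating AR model, the series
#' length, the order used for fitting, and at most one deviation from the
#' plain linear stationary generator (quadratic nonlinearity, threshold
#' switching, or a sinusoidal trend).
#'
#' @param model the generating [ar_model()].
#' @param n series length.
#' @param fit_order order used when fitting each realization (defaults to
#'   the true order; the order-mismatch experiment sets it explicitly).
#' @param label configuration label used in study tables.
#' @param beta quadratic-nonlinearity strength, or `NULL`.
#' @param threshold_gamma_rel threshold as a fraction of the process SD, or
#'   `NULL`; `threshold_b` the alternative-regime coefficients.
#' @param trend_amplitude_rel,trend_period_s sinusoidal-trend amplitude
#'   (fraction of the series SD) and period in seconds, or `NULL`.
#' @param burn_in generator burn-in.
#' @return an object of class `sim_config`.
#' @seealso [run_simulation_study()], [read_sim_config()]
#' @export
sim_config <- function(model, n = 300L, fit_order = NULL, label = NULL,
                       beta = NULL, threshold_gamma_rel = NULL,
                       threshold_b = .threshold_b_default,
                       trend_amplitude_rel = NULL, trend_period_s = NULL,
                       burn_in = 1000L) {
  stopifnot(inherits(model, "ar_model"))
  if (!.is_count(n, min = 50L)) .stopf("'n' must be an integer >= 50")
  if (is.null(fit_order)) fit_order <- model$order
  if (!.is_count(fit_order)) .stopf("'fit_order' must be a positive integer")
  has_trend <- !is.null(trend_amplitude_rel) || !is.null(trend_period_s)
  if (has_trend && (is.null(trend_amplitude_rel) || is.null(trend_period_s)))
    .stopf("a trend needs both 'trend_amplitude_rel' and 'trend_period_s'")
  modes <- c(!is.null(beta), !is.null(threshold_gamma_rel), has_trend)
  if (sum(modes) > 1L)
    .stopf("at most one generator mode (beta / threshold / trend) per config")
  if (is.null(label))
    label <- sprintf("AR(%d) N=%d fit=%d", model$order, n, fit_order)
  structure(list(model = model, n = as.integer(n),
                 fit_order = as.integer(fit_order), label = label,
                 beta = beta, threshold_gamma_rel = threshold_gamma_rel,
                 threshold_b = threshold_b,
                 trend_amplitude_rel = trend_amplitude_rel,
                 trend_period_s = trend_period_s,
                 burn_in = as.integer(burn_in)),
            class = "sim_config")
}

# one realization of a configuration
.generate_series <- function(config, seed) {
  m <- config$model
  if (!is.null(config$beta))
    return(simulate_squared(m, beta = config$beta, n = config$n,
                            seed = seed, burn_in = config$burn_in))
  if (!is.null(config$threshold_gamma_rel))
    return(simulate_threshold(m$a, config$threshold_b,
                              gamma_rel = config$threshold_gamma_rel,
                              sw = m$sw, n = config$n, seed = seed,
                              burn_in = config$burn_in, dt = m$dt))
  s2 <- .child_seeds(seed, 2L)
  x <- simulate_ar(m, n = config$n, seed = s2[[1L]],
                   burn_in = config$burn_in)
  if (!is.null(config$trend_amplitude_rel))
    x <- add_trend(x, config$trend_amplitude_rel, config$trend_period_s,
                   seed = s2[[2L]])
  x
}

#' Read or write a simulation configuration as a flat key-value file
#'
#' The file is flat YAML (`key: value` per line).  Recognised keys:
#' `label`, `coefficients` or `pole_moduli` + `pole_frequencies`,
#' `innovation_variance`, `sampling_period`, `n_samples`, `fit_order`,
#' `burn_in`, `beta`, `threshold_gamma_rel`, `threshold_b`,
#' `trend_amplitude_rel`, `trend_period_s`.  Vector-valued keys
#' (`coefficients`, `pole_moduli`, `pole_frequencies`, `threshold_b`) are
#' YAML sequences.
#'
#' @param path file to read or write.
#' @return `read_sim_config()`: a [sim_config()]; `write_sim_config()`:
#'   invisibly, the path.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  kv <- yaml::read_yaml(path)
  if (!is.null(kv$coefficients)) {
    a <- as.numeric(kv$coefficients)
  } else if (!is.null(kv$pole_moduli)) {
    a <- poles_to_coefficients(as.numeric(kv$pole_moduli),
                               as.numeric(kv$pole_frequencies))
  } else .stopf("config needs 'coefficients' or 'pole_moduli'")
  model <- ar_model(a,
                    sw = if (is.null(kv$innovation_variance)) 1
                         else kv$innovation_variance,
                    dt = if (is.null(kv$sampling_period)) 1
                         else kv$sampling_period)
  sim_config(model,
             n = if (is.null(kv$n_samples)) 300L else kv$n_samples,
             fit_order = kv$fit_order, label = kv$label,
             beta = kv$beta,
             threshold_gamma_rel = kv$threshold_gamma_rel,
             threshold_b = if (is.null(kv$threshold_b)) .threshold_b_default
                           else as.numeric(kv$threshold_b),
             trend_amplitude_rel = kv$trend_amplitude_rel,
             trend_period_s = kv$trend_period_s,
             burn_in = if (is.null(kv$burn_in)) 1000L else kv$burn_in)
}

#' @rdname read_sim_config
#' @param config a [sim_config()] to serialize.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  kv <- list(label = config$label,
             coefficients = config$model$a,
             innovation_variance = config$model$sw,
             sampling_period = config$model$dt,
             n_samples = config$n,
             fit_order = config$fit_order,
             burn_in = config$burn_in)
  for (key in c("beta", "threshold_gamma_rel", "trend_amplitude_rel",
                "trend_period_s"))
    if (!is.null(config[[key]])) kv[[key]] <- config[[key]]
  if (!is.null(config$threshold_gamma_rel))
    kv$threshold_b <- config$threshold_b
  yaml::write_yaml(kv, path)
  invisible(path)
}

#' Run a simulation study over a grid of configurations
#'
#' For each configuration, `runs` realizations are generated, fitted at the
#' configured order and resampled (`m` replicates each); per-run confidence
#' summaries are averaged into a study row.  Between every pair of
#' consecutive grid configurations, the per-run replicate sets are compared
#' with [difference_test()] (run `i` of one configuration against run `i`
#' of the next) and the number of significant outcomes per index is
#' recorded -- the detection count, a false-positive count when the two
#' configurations describe the same process.
#'
#' @param grid list of [sim_config()] objects (order matters).
#' @param runs realizations per configuration (the studies use 100).
#' @param m replicates per realization (the studies use 1000).
#' @param alpha significance level of the difference tests.
#' @param method resampling scheme, `"mc"` or `"bs"`.
#' @param seed optional integer master seed; the full study is
#'   deterministic given the seed.
#' @param include_gold also compute gold-standard percentiles per
#'   configuration from `n_gold` fresh realizations of the true process.
#' @param n_gold gold-standard realizations per configuration.
#' @return an object of class `ar_study`: list with `rows` (one data frame
#'   row per configuration: label, per-index true values, mean percentiles
#'   over runs, failure count, optional gold-standard percentiles),
#'   `detections` (data frame: step, index, count of significant tests,
#'   `n_testable`), and the call parameters.
#' @examples
#' grid <- list(sim_config(benchmark_model(), n = 300, label = "base"))
#' st <- run_simulation_study(grid, runs = 2, m = 50, seed = 1)
#' st$rows
#' @export
run_simulation_study <- function(grid, runs = 100L, m = 1000L,
                                 alpha = 0.05, method = c("mc", "bs"),
                                 seed = NULL, include_gold = FALSE,
                                 n_gold = 100L) {
  method <- match.arg(method)
  if (!is.list(grid) || length(grid) == 0L ||
      !all(vapply(grid, inherits, logical(1), "sim_config")))
    .stopf("'grid' must be a nonempty list of sim_config objects")
  if (!.is_count(runs)) .stopf("'runs' must be a positive integer")
  nc <- length(grid)
  seeds <- .child_seeds(seed, nc * runs * 3L + nc + 1L)
  sidx <- 0L
  next_seed <- function() {
    sidx <<- sidx + 1L
    seeds[[sidx]]
  }

  idx_names <- c("f_lf", "p_lfhf", "s_x")
  probs <- c(5, 25, 50, 75, 95)
  reps <- vector("list", nc)       # per config: list of m x 3 index matrices
  rows <- vector("list", nc)

  for (ci in seq_len(nc)) {
    cfg <- grid[[ci]]
    run_idx <- vector("list", runs)
    perc_acc <- array(NA_real_, c(runs, 3L, length(probs)))
    point_acc <- matrix(NA_real_, runs, 3L)
    n_failed <- 0L
    for (ri in seq_len(runs)) {
      s_sim <- next_seed(); s_rep <- next_seed(); next_seed()  # reserve
      res <- tryCatch({
        x <- .generate_series(cfg, s_sim)
        fit <- ar_fit(x, order = cfg$fit_order)
        rep <- ar_replicates(fit, method = method, m = m, seed = s_rep)
        list(rep = rep,
             point = .indexes_from_params(fit$model$a, fit$model$sw,
                                          fit$model$dt))
      }, error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      run_idx[[ri]] <- res$rep$indexes
      point_acc[ri, ] <- res$point
      for (k in 1:3) {
        v <- res$rep$indexes[, k]
        if (any(!is.na(v)))
          perc_acc[ri, k, ] <- quantile(v[!is.na(v)], probs / 100,
                                        names = FALSE, type = 7)
      }
    }
    reps[[ci]] <- run_idx
    truth <- tryCatch(as.numeric(hrv_indexes(cfg$model)),
                      error = function(e) rep(NA_real_, 3L))
    row <- data.frame(label = cfg$label, n = cfg$n,
                      fit_order = cfg$fit_order, n_failed = n_failed,
                      flagged = n_failed > 0.1 * runs)
    for (k in 1:3) {
      row[[paste0("true_", idx_names[k])]] <- truth[k]
      row[[paste0("point_", idx_names[k])]] <-
        mean(point_acc[, k], na.rm = TRUE)
      for (pi in seq_along(probs))
        row[[sprintf("%s_p%d", idx_names[k], probs[pi])]] <-
          mean(perc_acc[, k, pi], na.rm = TRUE)
    }
    if (include_gold) {
      g <- gold_standard(cfg$model, n = cfg$n, n_realizations = n_gold,
                         seed = next_seed(), order = cfg$fit_order,
                         burn_in = cfg$burn_in)
      for (k in 1:3) {
        v <- g[[idx_names[k]]]
        gq <- if (any(!is.na(v)))
          quantile(v[!is.na(v)], probs / 100, names = FALSE, type = 7)
          else rep(NA_real_, length(probs))
        for (pi in seq_along(probs))
          row[[sprintf("gold_%s_p%d", idx_names[k], probs[pi])]] <- gq[pi]
      }
    } else next_seed()
    rows[[ci]] <- row
  }

  det <- NULL
  if (nc > 1L) {
    pair_seeds <- .child_seeds(seeds[[length(seeds)]],
                               (nc - 1L) * runs * 3L)
    psi <- 0L
    det_list <- list()
    for (ci in seq_len(nc - 1L)) {
      for (k in 1:3) {
        sig <- logical(0)
        n_testable <- 0L
        for (ri in seq_len(runs)) {
          psi_here <- psi + (ri - 1L) * 3L + k
          A <- reps[[ci]][[ri]]
          B <- reps[[ci + 1L]][[ri]]
          if (is.null(A) || is.null(B)) next
          tr <- tryCatch(
            difference_test(A[, k], B[, k], alpha = alpha,
                            seed = pair_seeds[[psi_here]]),
            error = function(e) NULL)
          if (is.null(tr)) next
          n_testable <- n_testable + 1L
          sig <- c(sig, tr$significant)
        }
        det_list[[length(det_list) + 1L]] <- data.frame(
          from = grid[[ci]]$label, to = grid[[ci + 1L]]$label,
          index = idx_names[k], count = sum(sig),
          n_testable = n_testable)
      }
      psi <- psi + runs * 3L
    }
    det <- do.call(rbind, det_list)
  }

  structure(list(rows = do.call(rbind, rows), detections = det,
                 runs = runs, m = m, alpha = alpha, method = method,
                 seed = seed),
            class = "ar_study")
}

#' @export
print.ar_study <- function(x, ...) {
  cat(sprintf("Simulation study: %d configuration(s), %d runs, M = %d, %s\n",
              nrow(x$rows), x$runs, x$m, toupper(x$method)))
  print(x$rows[, c("label", "n", "fit_order", "n_failed")],
        row.names = FALSE)
  if (!is.null(x$detections)) {
    cat(sprintf("Detections per %d runs (alpha = %g):\n", x$runs, x$alpha))
    print(x$detections, row.names = FALSE)
  }
  invisible(x)
}

#' Upper bound on false positives under the binomial model
#'
#' Smallest count `k` such that a `Binomial(n_trials, p)` variable is at
#' most `k` with probability at least `conf`: the largest number of false
#' positives still compatible (at confidence `conf`) with a true
#' significance level `p`.
#'
#' @param n_trials number of independent tests.
#' @param p per-test false-positive probability.
#' @param conf confidence level.
#' @return integer bound.
#' @examples
#' binomial_false_positive_bound(100, 0.05, 0.95)   # 9
#' @export
binomial_false_positive_bound <- function(n_trials, p, conf = 0.95) {
  if (!.is_count(n_trials)) .stopf("'n_trials' must be a positive integer")
  if (!is.numeric(p) || p <= 0 || p >= 1) .stopf("'p' must lie in (0, 1)")
  if (!is.numeric(conf) || conf <= 0 || conf >= 1)
    .stopf("'conf' must lie in (0, 1)")
  as.integer(qbinom(conf, n_trials, p))
}

#' Individual-by-individual cohort analysis
#'
#' For every subject and task: AIC order selection over `order_range`,
#' least-squares fit, index computation and resampled confidence limits.
#' For every subject and every pair of tasks (in the given task order):
#' a [difference_test()] on each index.  The group summary per task pair
#' and index reports the median and interquartile range of the
#' within-subject point-estimate differences, the paired Wilcoxon
#' signed-rank p-value, and the percentage of subjects with a significant
#' increase, no significant change, and a significant decrease.
#'
#' @param recordings named list of subjects, each a named list of tasks
#'   holding an [ar_ts()].  Subjects missing any task are excluded with a
#'   warning.
#' @param m replicates per recording.
#' @param alpha significance level of the individual tests.
#' @param order_range AIC scan range (default 5 to 15).
#' @param method resampling scheme (`"mc"` default; `"bs"` gives very
#'   similar limits at a much higher cost).
#' @param seed optional integer master seed.
#' @return an object of class `ar_cohort`: list with `rows` (one data
#'   frame row per subject/task: selected order, index point estimates and
#'   5/25/50/75/95 percentiles, reliability flags), `tests` (per subject,
#'   task pair and index: significance and direction), `group` (the
#'   Table-style summary described above).
#' @examples
#' coh <- synthetic_cohort(n_subjects = 3, seed = 1)
#' res <- run_cohort_analysis(coh, m = 100, order_range = c(4, 6), seed = 2)
#' res$group
#' @export
run_cohort_analysis <- function(recordings, m = 1000L, alpha = 0.05,
                                order_range = c(5L, 15L),
                                method = c("mc", "bs"), seed = NULL) {
  method <- match.arg(method)
  if (!is.list(recordings) || is.null(names(recordings)))
    .stopf("'recordings' must be a named list of subjects")
  tasks <- names(recordings[[1L]])
  if (is.null(tasks) || length(tasks) < 1L)
    .stopf("each subject must be a named list of task recordings")
  complete <- vapply(recordings, function(s) all(tasks %in% names(s)),
                     logical(1))
  if (!all(complete)) {
    warning("excluding subjects with missing tasks: ",
            paste(names(recordings)[!complete], collapse = ", "),
            call. = FALSE)
    recordings <- recordings[complete]
  }
  subjects <- names(recordings)
  if (length(subjects) == 0L) .stopf("no complete subjects")

  idx_names <- c("f_lf", "p_lfhf", "s_x")
  probs <- c(5, 25, 50, 75, 95)
  seeds <- .child_seeds(seed, length(subjects) * length(tasks) +
                          length(subjects) * choose(length(tasks), 2L) * 3L)
  sidx <- 0L
  next_seed <- function() {
    sidx <<- sidx + 1L
    seeds[[sidx]]
  }

  rows <- list()
  repsets <- list()
  for (su in subjects) {
    for (ta in tasks) {
      x <- recordings[[su]][[ta]]
      stopifnot(inherits(x, "ar_ts"))
      ord <- select_order(x, order_range[1L], order_range[2L])
      fit <- ar_fit(x, order = ord)
      rep <- ar_replicates(fit, method = method, m = m, seed = next_seed())
      repsets[[paste(su, ta, sep = "\r")]] <- rep
      sm <- summary(rep, probs = probs)
      row <- data.frame(subject = su, task = ta, order = as.integer(ord))
      for (k in 1:3) {
        row[[paste0(idx_names[k], "_point")]] <- sm$point[k]
        for (pi in seq_along(probs))
          row[[sprintf("%s_p%d", idx_names[k], probs[pi])]] <-
            sm[[paste0("p", probs[pi])]][k]
        row[[paste0(idx_names[k], "_reliable")]] <- sm$reliable[k]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  rows <- do.call(rbind, rows)

  pairs <- utils::combn(tasks, 2L, simplify = FALSE)
  tests <- list()
  for (su in subjects) {
    for (pr in pairs) {
      ra <- repsets[[paste(su, pr[1L], sep = "\r")]]
      rb <- repsets[[paste(su, pr[2L], sep = "\r")]]
      for (k in 1:3) {
        tr <- tryCatch(
          difference_test(ra$indexes[, k], rb$indexes[, k], alpha = alpha,
                          seed = next_seed()),
          error = function(e) NULL)
        tests[[length(tests) + 1L]] <- data.frame(
          subject = su, from = pr[1L], to = pr[2L], index = idx_names[k],
          significant = if (is.null(tr)) NA else tr$significant,
          direction = if (is.null(tr)) NA_character_ else tr$direction,
          median_difference = if (is.null(tr)) NA_real_
                              else tr$median_difference)
      }
    }
  }
  tests <- do.call(rbind, tests)

  group <- list()
  for (pr in pairs) {
    for (k in 1:3) {
      pa <- rows[[paste0(idx_names[k], "_point")]][rows$task == pr[1L]]
      pb <- rows[[paste0(idx_names[k], "_point")]][rows$task == pr[2L]]
      d <- pb - pa
      wp <- tryCatch(
        suppressWarnings(wilcox.test(pb, pa, paired = TRUE)$p.value),
        error = function(e) NA_real_)
      tk <- tests[tests$from == pr[1L] & tests$to == pr[2L] &
                    tests$index == idx_names[k], ]
      n_sub <- nrow(tk)
      group[[length(group) + 1L]] <- data.frame(
        from = pr[1L], to = pr[2L], index = idx_names[k],
        median_difference = median(d, na.rm = TRUE),
        iqr_difference = IQR(d, na.rm = TRUE),
        wilcoxon_p = wp,
        pct_increase = 100 * sum(tk$direction == "increase",
                                 na.rm = TRUE) / n_sub,
        pct_ns = 100 * sum(tk$direction == "none" | is.na(tk$direction)) /
          n_sub,
        pct_decrease = 100 * sum(tk$direction == "decrease",
                                 na.rm = TRUE) / n_sub)
    }
  }
  structure(list(rows = rows, tests = tests, group = do.call(rbind, group),
                 alpha = alpha, m = m, method = method, seed = seed),
            class = "ar_cohort")
}

#' @export
print.ar_cohort <- function(x, ...) {
  cat(sprintf("Cohort analysis: %d subjects x %d tasks, M = %d, %s\n",
              length(unique(x$rows$subject)),
              length(unique(x$rows$task)), x$m, toupper(x$method)))
  cat("Group summary:\n")
  print(x$group, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Generate a synthetic cohort of R-R-like recordings
#'
#' Builds a cohort in the layout expected by [run_cohort_analysis()], with
#' each recording an independent realization of a benchmark-style AR
#' process rescaled to R-R-like units (values in ms around a 1000-ms mean).
#' By default both tasks share the identical generating process, giving a
#' null cohort; `task_models` substitutes a different generating model per
#' task (e.g. an LF pole moved or strengthened) for directional-effect
#' experiments.  Synthetic stand-in for a recorded cohort: no respiration
#' coupling, no nonstationarity, Gaussian innovations.
#'
#' @param n_subjects number of subjects.
#' @param tasks character vector of task names.
#' @param task_models optional named list mapping task name to the
#'   generating [ar_model()]; defaults to the benchmark model for every
#'   task.
#' @param n samples per recording.
#' @param rr_mean,rr_scale mean R-R interval (ms) and amplitude scale
#'   applied to the unit-variance AR output.
#' @param seed optional integer master seed.
#' @return a named list of subjects, each a named list of [ar_ts()] tasks.
#' @export
synthetic_cohort <- function(n_subjects = 25L, tasks = c("A", "B"),
                             task_models = NULL, n = 300L,
                             rr_mean = 1000, rr_scale = 30, seed = NULL) {
  if (is.null(task_models))
    task_models <- stats::setNames(
      rep(list(benchmark_model()), length(tasks)), tasks)
  seeds <- .child_seeds(seed, n_subjects * length(tasks))
  sidx <- 0L
  out <- list()
  for (si in seq_len(n_subjects)) {
    subj <- list()
    for (ta in tasks) {
      sidx <- sidx + 1L
      x <- simulate_ar(task_models[[ta]], n = n, seed = seeds[[sidx]])
      subj[[ta]] <- ar_ts(rr_mean + rr_scale * x$values, dt = rr_mean / 1000,
                          label = sprintf("subject%02d_%s", si, ta))
    }
    out[[sprintf("subject%02d", si)]] <- subj
  }
  out
}

#' Write study or cohort tables to CSV or JSON
#'
#' Serializes a result table with a deterministic column order, undefined
#' values as the explicit token `"NA"`, and floating-point values at 6
#' significant digits.
#'
#' @param rows a data frame (e.g. `$rows`, `$group` or `$detections` of a
#'   study/cohort result).
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return invisibly, the path.
#' @export
write_results <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) .stopf("'rows' is empty")
  num <- vapply(rows, is.numeric, logical(1)) &
    !vapply(rows, is.integer, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 6)
  ok <- tryCatch({
    if (format == "csv") {
      write.csv(rows, path, row.names = FALSE, na = "NA")
    } else {
      jsonlite::write_json(rows, path, dataframe = "rows", na = "string",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("could not write %s: %s", path, conditionMessage(ok))
  invisible(path)
}
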