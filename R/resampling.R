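#' Empirical sampling distribution of AR indexes by resampling
#'
#' Builds `m` surrogate AR parameter sets from a single fit and computes the
#' descriptive index set for each, giving the empirical sampling
#' distribution from which confidence limits and significance tests are
#' read.
#'
#' Two schemes are available:
#' \describe{
#'   \item{`"mc"` (Monte Carlo)}{Coefficient vectors are drawn from the
#'     multivariate Gaussian with mean at the estimate and covariance
#'     `sw * (Z'Z)^-1`; the innovation variance is drawn independently from
#'     a Gaussian with mean `sw` and variance `2 sw^2 / N`.  Draws with a
#'     nonpositive innovation variance or unstable coefficients do not
#'     describe a stationary AR process and are rejected and redrawn (the
#'     count is returned in `n_rejected`); if the target cannot be reached
#'     within `20 m` draws the fit is too close to instability for the
#'     Gaussian approximation and an error is raised.}
#'   \item{`"bs"` (bootstrap)}{The mean-centered model residuals are
#'     resampled with replacement and pushed through the fitted recursion
#'     `X* = Z a + V` on the original (fixed) regressor matrix; coefficients
#'     and innovation variance are then re-estimated from `(Z, X*)` by the
#'     same least-squares formulas.  With `design = "recursive"` the
#'     surrogate series is instead regenerated recursively from the first
#'     `p` observed samples and fully re-fitted.  Unstable re-estimates are
#'     kept as parameter draws but their indexes are marked undefined.}
#' }
#'
#' @param fit an [ar_fit()]; must not be degenerate.
#' @param method `"mc"` or `"bs"`.
#' @param m number of replicates (the studies in this package use 1000).
#' @param seed optional integer seed; the same fit and seed give a
#'   bit-identical replicate set.
#' @param design bootstrap design matrix handling, see above.
#' @return an object of class `ar_replicates`: list with `method`, `m`,
#'   `coef_draws` (m x p), `sw_draws`, `indexes` (m x 3 matrix, columns
#'   `f_lf`, `p_lfhf`, `s_x`, `NA` where undefined), `n_rejected` (MC),
#'   `n_unstable` (BS), `point` (the fit's own index set), `seed`.
#' @seealso [summary.ar_replicates()], [difference_test()]
#' @examples
#' x <- simulate_ar(benchmark_model(), n = 300, seed = 11)
#' fit <- ar_fit(x, order = 5)
#' rep <- ar_replicates(fit, method = "mc", m = 200, seed = 42)
#' summary(rep)
#' @export
ar_replicates <- function(fit, method = c("mc", "bs"), m = 1000L,
                          seed = NULL, design = c("fixed", "recursive")) {
  stopifnot(inherits(fit, "ar_fit"))
  method <- match.arg(method)
  design <- match.arg(design)
  if (!.is_count(m)) .stopf("'m' must be a positive integer")
  if (fit$degenerate)
    .stopf("degenerate fit (zero innovation variance): %s",
           "the sampling distribution is a point mass and indexes undefined")
  m <- as.integer(m)
  out <- .with_seed(seed, switch(method,
    mc = .mc_replicates(fit, m),
    bs = .bs_replicates(fit, m, design)))
  point <- if (is_stable(fit$model$a)) hrv_indexes(fit$model) else NULL
  structure(c(out,
              list(method = method, m = m, seed = seed, point = point,
                   dt = fit$model$dt, n = fit$n, order = fit$order)),
            class = "ar_replicates")
}

.mc_replicates <- function(fit, m) {
  p <- fit$order
  a_hat <- fit$model$a
  sw_hat <- fit$model$sw
  sw_sd <- sqrt(fit$sw_var)
  S <- fit$coef_cov
  R <- if (max(abs(S)) == 0) matrix(0, p, p) else {
    Rc <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(Rc)) {
      # covariance numerically semi-definite: ridge at machine scale
      chol(S + diag(1e-12 * max(diag(S)), p))
    } else Rc
  }
  coefs <- matrix(NA_real_, m, p)
  sws <- numeric(m)
  idx <- matrix(NA_real_, m, 3L,
                dimnames = list(NULL, c("f_lf", "p_lfhf", "s_x")))
  dt <- fit$model$dt
  filled <- 0L
  attempts <- 0L
  cap <- 20L * m
  while (filled < m) {
    nb <- min(m - filled, cap - attempts)
    if (nb <= 0L)
      .stopf("Monte Carlo rejection rate too high after %d draws: %s",
             attempts, "fit too close to instability for the Gaussian scheme")
    z <- matrix(rnorm(nb * p), nb, p)
    a_star <- sweep(z %*% R, 2L, a_hat, "+")
    sw_star <- rnorm(nb, sw_hat, sw_sd)
    for (i in seq_len(nb)) {
      attempts <- attempts + 1L
      if (sw_star[i] <= 0) next
      ai <- a_star[i, ]
      if (all(ai == 0)) {
        row <- c(NA_real_, NA_real_, 0)
      } else {
        r <- .ar_poles(ai)
        if (any(Mod(r) >= 1)) next
        row <- .indexes_from_roots(r, ai, sw_star[i], dt)
      }
      filled <- filled + 1L
      coefs[filled, ] <- ai
      sws[filled] <- sw_star[i]
      idx[filled, ] <- row
      if (filled == m) break
    }
  }
  list(coef_draws = coefs, sw_draws = sws, indexes = idx,
       n_rejected = attempts - m, n_unstable = NA_integer_)
}

.bs_replicates <- function(fit, m, design) {
  p <- fit$order
  n_res <- length(fit$residuals)
  if (n_res < p + 2L)
    .stopf("too few residuals (%d) to bootstrap an order-%d fit", n_res, p)
  res_c <- fit$residuals - mean(fit$residuals)   # mean-centered residuals
  Z <- fit$regressors
  Rz <- fit$chol_ztz
  a_hat <- fit$model$a
  zha <- drop(Z %*% a_hat)
  coefs <- matrix(NA_real_, m, p)
  sws <- numeric(m)
  idx <- matrix(NA_real_, m, 3L,
                dimnames = list(NULL, c("f_lf", "p_lfhf", "s_x")))
  n_unstable <- 0L
  for (i in seq_len(m)) {
    v <- res_c[sample.int(n_res, n_res, replace = TRUE)]
    if (design == "fixed") {
      x_star <- zha + v
      a_t <- drop(backsolve(Rz, backsolve(Rz, crossprod(Z, x_star),
                                          transpose = TRUE)))
      r_t <- x_star - drop(Z %*% a_t)
    } else {
      xs <- c(fit$init, numeric(n_res))
      for (k in seq_len(n_res))
        xs[p + k] <- sum(a_hat * xs[(p + k - 1L):k]) + v[k]
      ref <- ar_fit(ar_ts(xs, dt = fit$model$dt), order = p, demean = FALSE)
      a_t <- ref$model$a
      r_t <- ref$residuals
    }
    sw_t <- sum(r_t^2) / (fit$n - p)
    coefs[i, ] <- a_t
    sws[i] <- sw_t
    rt <- if (all(a_t == 0)) complex(0) else .ar_poles(a_t)
    if (sw_t > 0 && all(Mod(rt) < 1)) {
      idx[i, ] <- if (length(rt) == 0L) c(NA_real_, NA_real_, 0)
                  else .indexes_from_roots(rt, a_t, sw_t, fit$model$dt)
    } else {
      n_unstable <- n_unstable + 1L
    }
  }
  list(coef_draws = coefs, sw_draws = sws, indexes = idx,
       n_rejected = NA_integer_, n_unstable = n_unstable)
}

#' @export
print.ar_replicates <- function(x, ...) {
  cat(sprintf("%s replicate set: M = %d (AR(%d) fit, N = %d)\n",
              toupper(x$method), x$m, x$order, x$n))
  if (x$method == "mc")
    cat(sprintf("  invalid draws rejected and redrawn: %d\n", x$n_rejected))
  else
    cat(sprintf("  unstable re-estimates (indexes undefined): %d\n",
                x$n_unstable))
  nd <- colSums(!is.na(x$indexes))
  cat(sprintf("  defined replicates: f_LF %d, P_LFHF %d, S_X %d of %d\n",
              nd[1L], nd[2L], nd[3L], x$m))
  invisible(x)
}

#' Percentile confidence summary of an index distribution
#'
#' Percentiles (5, 25, 50, 75, 95 by default) of the defined values of an
#' empirical index distribution, computed with the linear-interpolation
#' percentile rule (R's default quantile type 7; the rule matters because
#' the 5th/95th percentiles of 1000 replicates are sensitive to it).  A
#' summary is flagged unreliable when fewer than 90% of the replicates had a
#' defined index value.
#'
#' @param values numeric vector, possibly containing `NA` for replicates
#'   where the index was undefined.
#' @param point_estimate the single-recording point estimate of the index.
#' @param probs percentile ranks in percent.
#' @return an object of class `confidence_summary`: list with
#'   `point_estimate`, `percentiles` (named numeric), `n_defined`,
#'   `n_total`, `reliable`.
#' @examples
#' confidence_summary(1:100, point_estimate = 50)
#' @export
confidence_summary <- function(values, point_estimate = NA_real_,
                               probs = c(5, 25, 50, 75, 95)) {
  values <- as.numeric(values)
  ok <- values[!is.na(values)]
  if (length(ok) == 0L)
    .stopf("no defined values: confidence summary unavailable")
  q <- quantile(ok, probs / 100, names = FALSE, type = 7)
  structure(list(point_estimate = point_estimate,
                 percentiles = stats::setNames(q, probs),
                 n_defined = length(ok), n_total = length(values),
                 reliable = length(ok) >= 0.9 * length(values)),
            class = "confidence_summary")
}

#' @export
print.confidence_summary <- function(x, ...) {
  cat(sprintf("point estimate %.4g; percentiles (%s): %s; defined %d/%d%s\n",
              x$point_estimate,
              paste(names(x$percentiles), collapse = "/"),
              paste(sprintf("%.4g", x$percentiles), collapse = " "),
              x$n_defined, x$n_total,
              if (x$reliable) "" else "  [UNRELIABLE: <90% defined]"))
  invisible(x)
}

#' Confidence summaries for all indexes of a replicate set
#'
#' @param object an [ar_replicates()] object.
#' @param probs percentile ranks in percent.
#' @param ... unused.
#' @return a data frame with one row per index (`f_lf`, `p_lfhf`, `s_x`)
#'   and columns `point`, one per percentile (`p5` ... `p95`), `n_defined`
#'   and `reliable`.
#' @export
summary.ar_replicates <- function(object, probs = c(5, 25, 50, 75, 95),
                                  ...) {
  pts <- if (is.null(object$point)) rep(NA_real_, 3L)
         else as.numeric(object$point)
  rows <- lapply(1:3, function(k) {
    cs <- tryCatch(confidence_summary(object$indexes[, k], pts[k],
                                      probs = probs),
                   error = function(e) NULL)
    if (is.null(cs))   # index undefined in every replicate
      cs <- list(point_estimate = pts[k],
                 percentiles = stats::setNames(rep(NA_real_, length(probs)),
                                               probs),
                 n_defined = 0L, reliable = FALSE)
    c(list(index = colnames(object$indexes)[k], point = cs$point_estimate),
      stats::setNames(as.list(cs$percentiles), paste0("p", probs)),
      list(n_defined = cs$n_defined, reliable = cs$reliable))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' @export
plot.ar_replicates <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(3, 4, 2, 1))
  on.exit(par(op))
  labs <- c("f_LF [Hz]", "P_LFHF", "S_X [nats]")
  for (k in 1:3) {
    v <- x$indexes[, k]
    if (all(is.na(v))) {
      plot.new(); title(main = labs[k], sub = "undefined")
      next
    }
    boxplot(v, main = labs[k], ...)
    if (!is.null(x$point)) abline(h = as.numeric(x$point)[k], lty = 2)
  }
  invisible(x)
}

#' Percentile test for the difference between two index estimates
#'
#' Tests the null hypothesis that two single-recording index estimates are
#' equal, given the empirical replicate distributions of both.  The first
#' distribution is randomly permuted (seeded) and subtracted element-wise
#' from the second -- a random pairing of independent replicates, not all
#' `M^2` cross-pairs -- and the null is rejected at level `alpha` when zero
#' lies outside the closed interval between the `100*alpha/2` and
#' `100*(1-alpha/2)` percentiles of the difference distribution.  Zero
#' exactly on a boundary is not significant (conservative).
#'
#' Pairs in which either value is undefined are dropped; fewer than 10
#' surviving pairs is an error.
#'
#' @param values_a,values_b numeric vectors of equal length `M` (replicate
#'   index values of the first and second estimate).
#' @param alpha two-sided significance level in `(0, 0.5]`.
#' @param seed optional integer seed for the random pairing.
#' @return an object of class `ar_diff_test`: list with `alpha`, `interval`
#'   (lower and upper percentile of `values_b - values_a`), `significant`,
#'   `direction` (`"increase"`, `"decrease"` or `"none"`), `n_pairs`,
#'   `median_difference`.
#' @examples
#' a <- rnorm(1000); b <- rnorm(1000) + 5
#' difference_test(a, b, alpha = 0.05, seed = 1)$direction  # "increase"
#' @export
difference_test <- function(values_a, values_b, alpha = 0.05, seed = NULL) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  if (length(values_a) != length(values_b))
    .stopf("replicate sets have different sizes (%d vs %d)",
           length(values_a), length(values_b))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 0.5)
    .stopf("'alpha' must lie in (0, 0.5]")
  m <- length(values_a)
  perm <- .with_seed(seed, sample.int(m))
  d <- values_b - values_a[perm]
  d <- d[!is.na(d)]
  if (length(d) < 10L)
    .stopf("only %d defined difference pairs (need at least 10)", length(d))
  iv <- quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  significant <- iv[1L] > 0 || iv[2L] < 0
  direction <- if (!significant) "none"
               else if (iv[1L] > 0) "increase" else "decrease"
  structure(list(alpha = alpha, interval = iv, significant = significant,
                 direction = direction, n_pairs = length(d),
                 median_difference = median(d)),
            class = "ar_diff_test")
}

#' @export
print.ar_diff_test <- function(x, ...) {
  cat(sprintf(
    "difference test (alpha = %g): interval [%.4g, %.4g], %s%s (%d pairs)\n",
    x$alpha, x$interval[1L], x$interval[2L],
    if (x$significant) "significant " else "not significant",
    if (x$significant) x$direction else "", x$n_pairs))
  invisible(x)
}
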