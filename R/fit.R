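#' Autoregressive model parameter set
#'
#' An AR(p) process is `x(n) = sum_k a_k x(n-k) + w(n)` with white Gaussian
#' innovations `w` of variance `sw`.  The parameter set (coefficients plus
#' innovation variance, with the sampling period fixing the frequency axis)
#' is everything the descriptive indexes are computed from.
#'
#' @param a numeric coefficient vector `a_1..a_p`.
#' @param sw innovation variance (signal units squared, nonnegative).
#' @param dt sampling period in seconds.
#' @return an object of class `ar_model`.
#' @examples
#' m <- ar_model(0.5, 1)
#' process_variance(m)   # 4/3
#' @export
ar_model <- function(a, sw = 1, dt = 1) {
  a <- as.numeric(a)
  if (length(a) < 1L) .stopf("need at least one AR coefficient")
  if (!all(is.finite(a))) .stopf("non-finite AR coefficient")
  if (!is.numeric(sw) || length(sw) != 1L || !is.finite(sw) || sw < 0)
    .stopf("'sw' must be a nonnegative innovation variance")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .stopf("'dt' must be a positive sampling period")
  structure(list(a = a, sw = as.numeric(sw), dt = as.numeric(dt),
                 order = length(a)),
            class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("AR(%d) model, dt = %g s\n", x$order, x$dt))
  cat("  a:", paste(sprintf("%.4g", x$a), collapse = " "), "\n")
  cat(sprintf("  innovation variance: %.4g (%s)\n", x$sw,
              if (is_stable(x$a)) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
coef.ar_model <- function(object, ...) object$a

# poles of the AR transfer function = roots of z^p - a_1 z^(p-1) - ... - a_p
.ar_poles <- function(a) polyroot(c(-rev(a), 1))

#' Stability of an AR coefficient vector
#'
#' An AR model defines a stationary process iff all roots of
#' `A(z) = 1 - sum_k a_k z^-k` lie strictly inside the unit circle.
#'
#' @param a numeric coefficient vector.
#' @return `TRUE` or `FALSE`.  A unit-modulus root counts as unstable.
#' @examples
#' is_stable(0.5)         # TRUE
#' is_stable(1.0)         # FALSE: unit root
#' @export
is_stable <- function(a) {
  a <- as.numeric(a)
  if (length(a) < 1L) .stopf("empty coefficient vector")
  if (!all(is.finite(a))) return(FALSE)
  if (all(a == 0)) return(TRUE)
  all(Mod(.ar_poles(a)) < 1)
}

#' Least-squares identification of an AR model from one recording
#'
#' Writes the AR recursion for rows `n = p+1..N` as `X = Z A + W`, estimates
#' the coefficients by ordinary least squares (Cholesky solve of the normal
#' equations), the innovation variance as the mean squared residual with
#' divisor `N - p`, the coefficient covariance as `sw * (Z'Z)^-1`, and the
#' variance of the innovation-variance estimate as `2 sw^2 / N`.  The sample
#' mean of the series is removed before regression, since the model describes
#' a zero-mean process while recorded series (e.g. R-R intervals) are not.
#'
#' When `order` is `NULL` the order is selected by [select_order()] over
#' `order_range` before fitting.
#'
#' A fit whose residual variance collapses to (numerical) zero is flagged
#' `degenerate`: the series is a noiseless recursion, the index set is
#' undefined and resampling refuses to run.
#'
#' @param x an [ar_ts()] or numeric vector.
#' @param order model order `p`, or `NULL` to select by AIC.
#' @param order_range length-2 integer range scanned when `order` is `NULL`.
#' @param dt sampling period (seconds) when `x` is a bare numeric vector.
#' @param demean remove the sample mean first (default `TRUE`).
#' @return an object of class `ar_fit` with components `model` (an
#'   [ar_model()]), `coef_cov` (p x p), `sw_var`, `residuals` (length
#'   `N - p`), `n`, `order`, `mean`, `degenerate`, and (when order was
#'   selected) `aic`.
#' @seealso [ar_replicates()], [hrv_indexes()], [select_order()]
#' @examples
#' x <- simulate_ar(ar_model(c(0.6, -0.3), 1), n = 400, seed = 1)
#' fit <- ar_fit(x, order = 2)
#' coef(fit)
#' summary(fit)
#' @export
ar_fit <- function(x, order = NULL, order_range = c(5L, 15L), dt = 1,
                   demean = TRUE) {
  x <- .as_ar_ts(x, dt = dt)
  if (is.null(order))
    order <- select_order(x, order_range[1L], order_range[2L],
                          demean = demean)
  if (!.is_count(order)) .stopf("'order' must be a positive integer")
  p <- as.integer(order)
  n <- length(x$values)
  if (n <= 2L * p + 1L)
    .stopf("series too short (N = %d) for order %d: need N > 2p + 1", n, p)

  mu <- if (demean) mean(x$values) else 0
  v <- x$values - mu
  X <- v[(p + 1L):n]
  Z <- sapply(seq_len(p), function(i) v[(p + 1L - i):(n - i)])
  Z <- matrix(Z, ncol = p)

  ztz <- crossprod(Z)
  R <- tryCatch(chol(ztz), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= sqrt(.Machine$double.eps) * max(diag(R))))
    .stopf("identification failed: regressor matrix is singular %s",
           "(constant or degenerate series)")
  a <- drop(backsolve(R, backsolve(R, crossprod(Z, X), transpose = TRUE)))
  res <- drop(X - Z %*% a)
  sw <- sum(res^2) / (n - p)
  ztz_inv <- chol2inv(R)
  degenerate <- sw <= 1e-12 * mean(v^2) || sw == 0

  structure(list(model = ar_model(a, sw = max(sw, 0), dt = x$dt),
                 coef_cov = sw * ztz_inv,
                 sw_var = 2 * sw^2 / n,
                 residuals = res,
                 n = n, order = p, mean = mu, degenerate = degenerate,
                 regressors = Z, response = X, chol_ztz = R,
                 init = v[seq_len(p)],
                 label = x$label),
            class = "ar_fit")
}

#' Select the AR model order by the Akaike information criterion
#'
#' Fits each candidate order and returns the one minimising
#' `AIC(p) = N * log(sw(p)) + 2 p`, ties broken toward the smaller order.
#'
#' @param x an [ar_ts()] or numeric vector.
#' @param min_order,max_order scan range (inclusive).
#' @param dt,demean as in [ar_fit()].
#' @return the selected order (integer), with the scanned AIC values
#'   attached as attribute `"aic"`.
#' @examples
#' x <- simulate_ar(benchmark_model(), n = 1000, seed = 7)
#' select_order(x, 1, 8)
#' @export
select_order <- function(x, min_order = 5L, max_order = 15L, dt = 1,
                         demean = TRUE) {
  if (!.is_count(min_order) || !.is_count(max_order) ||
      max_order < min_order)
    .stopf("invalid order range [%s, %s]", min_order, max_order)
  x <- .as_ar_ts(x, dt = dt)
  n <- length(x$values)
  if (n <= 2L * max_order + 1L)
    .stopf("series too short (N = %d) to scan up to order %d", n, max_order)
  orders <- seq.int(min_order, max_order)
  aic <- vapply(orders, function(p) {
    # a candidate whose regression is singular (e.g. a noiseless recursion
    # makes higher-order regressors exactly collinear) drops out of the scan
    fit <- tryCatch(ar_fit(x, order = p, demean = demean),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    n * log(fit$model$sw) + 2 * p
  }, numeric(1))
  if (all(!is.finite(aic) & aic > 0))
    .stopf("identification failed at every order in [%d, %d]",
           min_order, max_order)
  best <- orders[which.min(aic)]   # which.min takes the first (smallest p) tie
  structure(as.integer(best), aic = stats::setNames(aic, orders))
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("AR(%d) least-squares fit%s: N = %d, dt = %g s\n",
              x$order,
              if (nzchar(x$label)) paste0(" of '", x$label, "'") else "",
              x$n, x$model$dt))
  cat("  coefficients:", paste(sprintf("%.4f", x$model$a), collapse = " "),
      "\n")
  cat(sprintf("  innovation variance: %.4g%s\n", x$model$sw,
              if (x$degenerate) "  [degenerate fit: noiseless recursion]"
              else ""))
  invisible(x)
}

#' @export
summary.ar_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$coef_cov), 0))
  idx <- if (object$degenerate || !is_stable(object$model$a)) NULL
         else hrv_indexes(object$model)
  out <- list(fit = object,
              coef_table = cbind(estimate = object$model$a, se = se),
              indexes = idx,
              stable = is_stable(object$model$a))
  class(out) <- "summary.ar_fit"
  out
}

#' @export
print.summary.ar_fit <- function(x, ...) {
  print(x$fit)
  cat("  coefficient standard errors:",
      paste(sprintf("%.4f", x$coef_table[, "se"]), collapse = " "), "\n")
  if (!x$stable) {
    cat("  fitted coefficients are unstable; spectral indexes undefined\n")
  } else if (!is.null(x$indexes)) {
    cat("  indexes: ")
    print(x$indexes)
  }
  invisible(x)
}

#' @export
coef.ar_fit <- function(object, ...) object$model$a

#' @export
vcov.ar_fit <- function(object, ...) object$coef_cov

#' @export
residuals.ar_fit <- function(object, ...) object$residuals

#' @export
fitted.ar_fit <- function(object, ...)
  object$response - object$residuals + object$mean

#' @export
simulate.ar_fit <- function(object, nsim = 1, seed = NULL, n = object$n,
                            burn_in = 1000L, ...) {
  seeds <- .child_seeds(seed, nsim)
  out <- lapply(seeds, function(s)
    simulate_ar(object$model, n = n, seed = s, burn_in = burn_in))
  if (nsim == 1L) out[[1L]] else out
}

#' @export
predict.ar_fit <- function(object, n_ahead = 1L, ...) {
  if (!.is_count(n_ahead)) .stopf("'n_ahead' must be a positive integer")
  p <- object$order
  a <- object$model$a
  state <- rev(tail(object$response, p))        # demeaned recent values
  if (length(state) < p)
    state <- rev(c(object$init, object$response))[seq_len(p)]
  out <- numeric(n_ahead)
  for (h in seq_len(n_ahead)) {
    out[h] <- sum(a * state)
    state <- c(out[h], state[-p])
  }
  out + object$mean
}

#' @export
plot.ar_fit <- function(x, n_freqs = 256L, ...) {
  if (!is_stable(x$model$a))
    .stopf("cannot plot the spectrum of an unstable fit")
  s <- ar_psd(x$model, n_freqs = n_freqs)
  plot(s$frequency, s$density, type = "l", lwd = 2,
       xlab = "frequency [Hz]", ylab = "PSD [units^2/Hz]",
       main = sprintf("AR(%d) spectrum", x$order), ...)
  d <- tryCatch(spectral_decomposition(x$model), error = function(e) NULL,
                warning = function(w) suppressWarnings(
                  spectral_decomposition(x$model)))
  if (!is.null(d))
    abline(v = d$components$frequency, lty = 3, col = "grey40")
  invisible(x)
}
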