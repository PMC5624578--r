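#' AR coefficients from a pole configuration
#'
#' Expands the characteristic polynomial `A(z) = 1 - sum a_k z^-k` as a
#' product of first-order factors `(1 - rho z^-1)` for real poles and
#' second-order factors `(1 - 2 rho cos(2 pi f) z^-1 + rho^2 z^-2)` for
#' complex-conjugate pairs, and returns the coefficient vector `a`.
#'
#' A pole with normalized frequency 0 is a real positive pole, frequency
#' 0.5 a real negative pole; any other frequency in `(0, 0.5)` denotes a
#' conjugate pair and contributes two to the model order.
#'
#' @param modulus numeric vector of pole moduli, each in `[0, 1)`.
#' @param frequency numeric vector of normalized frequencies in
#'   `[0, 0.5]` cycles/sample, same length as `modulus`.
#' @return numeric coefficient vector `a_1..a_p`.
#' @examples
#' poles_to_coefficients(0.65, 0)                 # a single real pole
#' poles_to_coefficients(c(0.5, 0.3), c(0, 0))    # a1 = 0.8, a2 = -0.15
#' round(poles_to_coefficients(c(0.65, 0.8, 0.92), c(0, 0.1, 0.25)), 3)
#' @export
poles_to_coefficients <- function(modulus, frequency) {
  modulus <- as.numeric(modulus)
  frequency <- as.numeric(frequency)
  if (length(modulus) != length(frequency) || length(modulus) == 0L)
    .stopf("'modulus' and 'frequency' must be nonempty and the same length")
  if (any(modulus < 0) || any(modulus >= 1))
    .stopf("pole moduli must lie in [0, 1) for a stable process")
  if (any(frequency < 0) || any(frequency > 0.5))
    .stopf("normalized pole frequencies must lie in [0, 0.5]")
  poly <- 1
  for (i in seq_along(modulus)) {
    rho <- modulus[i]
    f <- frequency[i]
    fac <- if (f == 0) c(1, -rho)
           else if (f == 0.5) c(1, rho)
           else c(1, -2 * rho * cos(2 * pi * f), rho^2)
    poly <- .convolve_poly(poly, fac)
  }
  -poly[-1L]
}

.convolve_poly <- function(u, v) {
  out <- numeric(length(u) + length(v) - 1L)
  for (i in seq_along(u)) {
    idx <- i + seq_along(v) - 1L
    out[idx] <- out[idx] + u[i] * v
  }
  out
}

#' The benchmark fifth-order HRV-like AR process
#'
#' A fifth-order AR process emulating the oscillatory structure of a 5-min
#' R-R interval series with a 1-s mean heart period: a real pole of modulus
#' 0.65 giving the slowly decaying very-low-frequency trend, a conjugate
#' pole pair of modulus 0.8 at 0.1 Hz (the LF Mayer-wave peak) and a pair
#' of modulus 0.92 at 0.25 Hz (the respiratory HF peak), with unit-variance
#' Gaussian innovations.  `benchmark_poles()` returns the pole table;
#' `benchmark_model()` the ready-made [ar_model()].  Changing `rho_lf` or
#' `f_lf` reproduces the parameter sweeps used in the simulation studies.
#'
#' @param rho_vlf,rho_lf,rho_hf pole moduli.
#' @param f_lf,f_hf pole frequencies in cycles/sample (equal to Hz at
#'   `dt = 1`).
#' @param sw innovation variance.
#' @param dt sampling period in seconds.
#' @return `benchmark_poles()`: data frame with columns `modulus` and
#'   `frequency`; `benchmark_model()`: an [ar_model()].
#' @examples
#' round(coef(benchmark_model()), 3)   # 1.944 -2.328 2.062 -1.254 0.352
#' @export
benchmark_poles <- function(rho_vlf = 0.65, rho_lf = 0.8, f_lf = 0.1,
                            rho_hf = 0.92, f_hf = 0.25) {
  data.frame(modulus = c(rho_vlf, rho_lf, rho_hf),
             frequency = c(0, f_lf, f_hf))
}

#' @rdname benchmark_poles
#' @export
benchmark_model <- function(rho_vlf = 0.65, rho_lf = 0.8, f_lf = 0.1,
                            rho_hf = 0.92, f_hf = 0.25, sw = 1, dt = 1) {
  sp <- benchmark_poles(rho_vlf, rho_lf, f_lf, rho_hf, f_hf)
  ar_model(poles_to_coefficients(sp$modulus, sp$frequency), sw = sw, dt = dt)
}

#' Simulate a realization of a linear AR process
#'
#' Feeds the recursion with Gaussian white innovations from a zero initial
#' state and discards the first `burn_in` samples.  The default burn-in of
#' 1000 samples is generous for poles of modulus up to ~0.95 (the slowest
#' benchmark pole, 0.92, has a time constant of ~12 samples).
#'
#' @param model a stable [ar_model()].
#' @param n output length (>= 2).
#' @param seed optional integer seed.
#' @param burn_in samples discarded at start-up.
#' @return an [ar_ts()] of length `n` with the model's sampling period.
#' @examples
#' x <- simulate_ar(ar_model(0.5, 1), n = 1000, seed = 1)
#' var(x$values)    # near 4/3
#' @export
simulate_ar <- function(model, n, seed = NULL, burn_in = 1000L) {
  stopifnot(inherits(model, "ar_model"))
  if (!.is_count(n, min = 2L)) .stopf("'n' must be an integer >= 2")
  if (!is_stable(model$a)) .stopf("unstable model: simulation would diverge")
  w <- .with_seed(seed, rnorm(n + burn_in, 0, sqrt(model$sw)))
  x <- .ar_recursion(model$a, w)
  ar_ts(x[(burn_in + 1L):(burn_in + n)], dt = model$dt)
}

# shared recursion kernel: every simulator uses the same arithmetic so that
# degenerate settings (beta = 0, threshold never crossed) reduce to the
# linear generator bit-for-bit under a common seed
.ar_recursion <- function(a, w) {
  p <- length(a)
  nt <- length(w)
  ar <- rev(a)
  x <- c(numeric(p), w)      # zero initial state
  for (i in seq_len(nt)) {
    j <- i + p
    x[j] <- x[j] + sum(ar * x[i:(j - 1L)])
  }
  x[(p + 1L):(p + nt)]
}

#' @export
simulate.ar_model <- function(object, nsim = 1, seed = NULL, n = 300L,
                              burn_in = 1000L, ...) {
  seeds <- .child_seeds(seed, nsim)
  out <- lapply(seeds, function(s)
    simulate_ar(object, n = n, seed = s, burn_in = burn_in))
  if (nsim == 1L) out[[1L]] else out
}

.check_explosion <- function(x, seed, what) {
  if (any(!is.finite(x)) || max(abs(x)) > 1e6)
    .stopf("%s simulation diverged (|x| > 1e6)%s", what,
           if (is.null(seed)) "" else sprintf(" [seed %d]", as.integer(seed)))
}

#' Simulate an AR process with quadratic nonlinearity
#'
#' The linear recursion is augmented with the term
#' `beta * (x(n-1)^2 - x(n-2)^2)`, introducing squared nonlinear dynamics of
#' strength `beta` (the study grid spans 0 to 0.06).  With `beta = 0` the
#' output is bit-identical to [simulate_ar()] under the same seed.
#'
#' @param model a stable [ar_model()] providing the linear part.
#' @param beta nonlinearity strength.
#' @param n,seed,burn_in as in [simulate_ar()].
#' @return an [ar_ts()] of length `n`.
#' @export
simulate_squared <- function(model, beta, n, seed = NULL, burn_in = 1000L) {
  stopifnot(inherits(model, "ar_model"))
  if (!.is_count(n, min = 2L)) .stopf("'n' must be an integer >= 2")
  if (!is_stable(model$a)) .stopf("unstable linear part")
  a <- model$a
  p <- length(a)
  ar <- rev(a)
  nt <- n + burn_in
  w <- .with_seed(seed, rnorm(nt, 0, sqrt(model$sw)))
  x <- c(numeric(p), w)
  for (i in seq_len(nt)) {
    j <- i + p
    nl <- if (beta == 0) 0
          else if (p >= 2L) beta * (x[j - 1L]^2 - x[j - 2L]^2)
          else beta * x[j - 1L]^2
    x[j] <- x[j] + sum(ar * x[i:(j - 1L)]) + nl
    if (abs(x[j]) > 1e6) .check_explosion(x[j], seed, "quadratic-AR")
  }
  .check_explosion(x, seed, "quadratic-AR")
  ar_ts(x[(p + burn_in + 1L):(p + nt)], dt = model$dt)
}

# printed b-regime coefficients of the switching benchmark (slower, more
# irregular LF component: pole pair modulus 0.4 at 0.07 cycles/sample)
.threshold_b_default <- c(1.363, -1.470, 1.257, -0.528, 0.088)

#' Simulate a threshold (regime-switching) AR process
#'
#' Generates `x(n)` from regime `a` when `x(n-1) <= gamma` and regime `b`
#' otherwise, with the threshold expressed as a multiple `gamma_rel` of the
#' a-regime process standard deviation.  The default b-regime coefficients
#' are the study values giving a slower, more irregular LF oscillation.
#' With a very large `gamma_rel` regime `b` never triggers and the output
#' is bit-identical to [simulate_ar()] on regime `a` with the same seed.
#'
#' @param coeff_a coefficient vector of the primary regime (stable).
#' @param coeff_b coefficient vector of the alternative regime (stable);
#'   both regimes share the innovation sequence.
#' @param gamma_rel threshold as a fraction of the a-regime process SD
#'   (the study grid is 3.0, 1.8, 1.4, 1.0).
#' @param sw innovation variance.
#' @param n,seed,burn_in,dt as in [simulate_ar()].
#' @return an [ar_ts()] of length `n` with attribute `"regime_b_fraction"`,
#'   the fraction of retained samples generated by regime `b`.
#' @export
simulate_threshold <- function(coeff_a, coeff_b = .threshold_b_default,
                               gamma_rel, sw = 1, n, seed = NULL,
                               burn_in = 1000L, dt = 1) {
  coeff_a <- as.numeric(coeff_a)
  coeff_b <- as.numeric(coeff_b)
  if (length(coeff_a) != length(coeff_b))
    .stopf("the two regimes must share the model order")
  if (!is_stable(coeff_a) || !is_stable(coeff_b))
    .stopf("both regimes must be stable")
  if (!is.numeric(gamma_rel) || gamma_rel <= 0)
    .stopf("'gamma_rel' must be a positive multiple of the process SD")
  if (!.is_count(n, min = 2L)) .stopf("'n' must be an integer >= 2")
  p <- length(coeff_a)
  gamma <- gamma_rel * sqrt(.process_variance(coeff_a, sw))
  ar_a <- rev(coeff_a)
  ar_b <- rev(coeff_b)
  nt <- n + burn_in
  w <- .with_seed(seed, rnorm(nt, 0, sqrt(sw)))
  x <- c(numeric(p), w)
  in_b <- logical(nt)
  for (i in seq_len(nt)) {
    j <- i + p
    use_b <- x[j - 1L] > gamma
    x[j] <- x[j] + sum((if (use_b) ar_b else ar_a) * x[i:(j - 1L)])
    in_b[i] <- use_b
    if (abs(x[j]) > 1e6) .check_explosion(x[j], seed, "threshold-AR")
  }
  out <- ar_ts(x[(p + burn_in + 1L):(p + nt)], dt = dt)
  attr(out, "regime_b_fraction") <- mean(in_b[(burn_in + 1L):nt])
  out
}

#' Superimpose a sinusoidal trend on a time series
#'
#' Adds `A * sin(2 pi t / period_s + phi)` with amplitude
#' `A = amplitude_rel * sd(series)` and a seeded uniform random phase
#' (or a fixed phase when `phase` is supplied), emulating slow
#' nonstationary drifts in R-R recordings.
#'
#' @param series an [ar_ts()].
#' @param amplitude_rel trend amplitude as a fraction of the series SD
#'   (the study grid is 0, 0.5, 1.0, 1.5).
#' @param period_s trend period in seconds (study grid 300, 600, 1200).
#' @param seed optional integer seed for the random phase.
#' @param phase optional fixed phase in radians (overrides the seed).
#' @return an [ar_ts()] of the same length.
#' @export
add_trend <- function(series, amplitude_rel, period_s, seed = NULL,
                      phase = NULL) {
  stopifnot(inherits(series, "ar_ts"))
  if (!is.numeric(period_s) || period_s <= 0)
    .stopf("'period_s' must be a positive period in seconds")
  if (!is.numeric(amplitude_rel) || amplitude_rel < 0)
    .stopf("'amplitude_rel' must be nonnegative")
  phi <- if (!is.null(phase)) phase
         else .with_seed(seed, runif(1, 0, 2 * pi))
  amp <- amplitude_rel * sd(series$values)
  t_s <- seq_along(series$values) * series$dt
  ar_ts(series$values + amp * sin(2 * pi * t_s / period_s + phi),
        dt = series$dt, label = series$label)
}

#' Gold-standard index distribution from multiple realizations
#'
#' Generates `n_realizations` independent realizations of a known AR
#' process, fits each at the given order and computes the index set,
#' yielding the sampling distribution of the indexes that single-recording
#' resampling schemes try to reproduce.  Only available in simulation,
#' where the true process is known.
#'
#' @param model the true [ar_model()].
#' @param n length of each realization.
#' @param n_realizations number of realizations (the studies use 1000).
#' @param seed optional integer master seed.
#' @param order fit order (defaults to the true order).
#' @param burn_in burn-in per realization.
#' @return a data frame with columns `f_lf`, `p_lfhf`, `s_x` (one row per
#'   realization, `NA` where undefined) and attribute `"n_failed"` counting
#'   realizations whose fit failed.
#' @examples
#' g <- gold_standard(benchmark_model(), n = 300, n_realizations = 50,
#'                    seed = 3)
#' confidence_summary(g$s_x)
#' @export
gold_standard <- function(model, n, n_realizations = 1000L, seed = NULL,
                          order = NULL, burn_in = 1000L) {
  stopifnot(inherits(model, "ar_model"))
  if (!.is_count(n_realizations)) .stopf("'n_realizations' must be >= 1")
  if (is.null(order)) order <- model$order
  seeds <- .child_seeds(seed, n_realizations)
  out <- matrix(NA_real_, n_realizations, 3L,
                dimnames = list(NULL, c("f_lf", "p_lfhf", "s_x")))
  n_failed <- 0L
  for (i in seq_len(n_realizations)) {
    row <- tryCatch({
      x <- simulate_ar(model, n = n, seed = seeds[[i]], burn_in = burn_in)
      fit <- ar_fit(x, order = order)
      if (fit$degenerate || !is_stable(fit$model$a)) stop("bad fit")
      .indexes_from_params(fit$model$a, fit$model$sw, fit$model$dt)
    }, error = function(e) NULL)
    if (is.null(row)) n_failed <- n_failed + 1L else out[i, ] <- row
  }
  res <- as.data.frame(out)
  attr(res, "n_failed") <- n_failed
  res
}
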