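#' Power spectral density of an AR model
#'
#' Evaluates `P(f) = sw * dt / |A(exp(i 2 pi f dt))|^2` on a uniform grid
#' over `[0, 1/(2 dt)]`.  The sampling-period factor makes `P(f)` a density
#' per Hz, so that the two-sided integral over `[-1/(2dt), 1/(2dt)]` equals
#' the process variance; with `dt = 1` it coincides with the dimensionless
#' form.
#'
#' @param model an [ar_model()]; must be stable.
#' @param n_freqs number of grid points (>= 2).
#' @return a data frame with columns `frequency` (Hz) and `density`.
#' @examples
#' s <- ar_psd(ar_model(0.5, 1), n_freqs = 5)
#' s$density[1]    # 1 / (1 - 0.5)^2 = 4 at f = 0
#' @export
ar_psd <- function(model, n_freqs = 256L) {
  stopifnot(inherits(model, "ar_model"))
  if (!.is_count(n_freqs, min = 2L)) .stopf("'n_freqs' must be >= 2")
  if (!is_stable(model$a))
    .stopf("unstable model: stationary spectrum undefined")
  f <- seq(0, 1 / (2 * model$dt), length.out = n_freqs)
  dens <- .ar_psd_at(model$a, model$sw, model$dt, f)
  data.frame(frequency = f, density = dens)
}

.ar_psd_at <- function(a, sw, dt, f) {
  k <- seq_along(a)
  A <- vapply(f, function(fi)
    1 - sum(a * exp(-2i * pi * fi * dt * k)), complex(1))
  sw * dt / Mod(A)^2
}

#' Stationary variance implied by an AR model
#'
#' Solves the stationary (Yule-Walker) covariance equation for the companion
#' form of the recursion: `vec(S) = (I - F (x) F)^-1 vec(Q)`, and returns
#' the (1,1) element.  This is the model-implied process variance, not a
#' sample variance.
#'
#' @param model an [ar_model()]; must be stable.
#' @return the process variance (signal units squared).
#' @examples
#' process_variance(ar_model(0.5, 1))   # 1 / (1 - 0.25)
#' @export
process_variance <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  if (!is_stable(model$a))
    .stopf("unstable model: stationary variance undefined")
  .process_variance(model$a, model$sw)
}

.process_variance <- function(a, sw) {
  p <- length(a)
  if (all(a == 0)) return(sw)
  if (p == 1L) return(sw / (1 - a^2))
  F <- rbind(a, cbind(diag(p - 1L), 0))
  vq <- numeric(p * p)
  vq[1L] <- sw
  S <- solve(diag(p * p) - kronecker(F, F), vq)
  S[1L]
}

#' Decompose the AR spectrum into oscillatory components
#'
#' Splits the AR power spectral density into one component per real pole and
#' per complex-conjugate pole pair, by the residue (partial-fraction) method
#' applied to the autocovariance generating function
#' `G(z) = sw / (A(z) A(1/z))`.  Each component carries a central frequency
#' (the pole phase mapped to Hz) and a power; the powers sum to the process
#' variance.  Individual component powers can be negative when poles
#' interact strongly -- they are retained (conservation still holds) and a
#' warning is emitted.
#'
#' @param model an [ar_model()]; must be stable with distinct poles (poles
#'   closer than `1e-8` in the complex plane raise an error, as the residue
#'   formula assumes simple poles).
#' @return an object of class `ar_decomp`: a list with `components` (data
#'   frame with columns `frequency` in Hz, `power`, `kind`, `pole_modulus`),
#'   `total_variance`, and `model`.
#' @examples
#' d <- spectral_decomposition(benchmark_model())
#' d$components$frequency       # 0, 0.1, 0.25 Hz
#' sum(d$components$power) - process_variance(benchmark_model())  # ~0
#' @export
spectral_decomposition <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  comp <- .decompose(model$a, model$sw, model$dt)
  if (any(comp$power < 0))
    warning("negative component power in spectral decomposition; ",
            "powers are retained (they still sum to the process variance)",
            call. = FALSE)
  structure(list(components = comp,
                 total_variance = sum(comp$power),
                 model = model),
            class = "ar_decomp")
}

# residue-method decomposition; stops on instability or repeated poles
.decompose <- function(a, sw, dt) {
  if (all(a == 0))                     # white noise: single flat component
    return(data.frame(frequency = 0, power = sw, kind = "real",
                      pole_modulus = 0))
  r <- .ar_poles(a)
  if (any(Mod(r) >= 1))
    .stopf("unstable model: spectral decomposition undefined")
  p <- length(r)
  if (p > 1L) {
    dmat <- Mod(outer(r, r, "-"))
    if (min(dmat[upper.tri(dmat)]) < 1e-8)
      .stopf("repeated poles (within 1e-8): residue decomposition %s",
             "assumes simple poles")
  }
  # residue of G(z)/z = sw z^(p-1) / (prod(z - r_k) prod(1 - r_k z)) at r_i
  res <- .pole_residues(r, sw)
  im <- Im(r)
  keep_pair <- im > 1e-12 * (1 + Mod(r))
  keep_real <- abs(im) <= 1e-12 * (1 + Mod(r))
  freq <- c(Arg(r[keep_pair]), ifelse(Re(r[keep_real]) >= 0, 0, pi)) /
    (2 * pi * dt)
  pow <- c(2 * Re(res[keep_pair]), Re(res[keep_real]))
  mod <- c(Mod(r[keep_pair]), Mod(r[keep_real]))
  kind <- c(rep("conjugate-pair", sum(keep_pair)),
            rep("real", sum(keep_real)))
  o <- order(freq)
  data.frame(frequency = freq[o], power = pow[o], kind = kind[o],
             pole_modulus = mod[o])
}

.pole_residues <- function(r, sw) {
  p <- length(r)
  if (p == 1L) return(sw * r^(p - 1) / (1 - r * r))
  D <- outer(r, r, "-"); diag(D) <- 1
  t1 <- exp(rowSums(log(D)))            # prod_{k != i} (r_i - r_k)
  t2 <- exp(rowSums(log(1 - outer(r, r))))  # prod_k (1 - r_k r_i)
  sw * r^(p - 1) / (t1 * t2)
}

#' @export
print.ar_decomp <- function(x, ...) {
  cat(sprintf("Spectral decomposition of AR(%d): total variance %.4g\n",
              x$model$order, x$total_variance))
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Information storage of an AR process
#'
#' `S_X = 0.5 * log(process_variance / innovation_variance)` in nats: the
#' amount of information in the present sample that is predictable from the
#' process past.  Zero for white noise, strictly positive for any other
#' stable model.
#'
#' @param model an [ar_model()]; must be stable with positive innovation
#'   variance.
#' @return information storage in nats.
#' @examples
#' information_storage(ar_model(0.5, 1))   # 0.5 * log(4/3)
#' @export
information_storage <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  if (model$sw <= 0)
    .stopf("degenerate model (zero innovation variance): %s",
           "information storage undefined")
  0.5 * log(process_variance(model) / model$sw)
}

#' Central frequency of the low-frequency spectral component
#'
#' Among decomposition components whose central frequency falls inside the
#' LF band, returns the frequency of the one nearest the target (the Mayer
#' wave frequency, 0.1 Hz).  `NA` when the band holds no component.
#'
#' @param decomp an `ar_decomp` from [spectral_decomposition()].
#' @param lf_band closed frequency interval in Hz (default `c(0.04, 0.15)`).
#' @param target target frequency in Hz (default 0.1).
#' @return frequency in Hz, or `NA_real_`.
#' @export
lf_central_frequency <- function(decomp, lf_band = c(0.04, 0.15),
                                 target = 0.1) {
  stopifnot(inherits(decomp, "ar_decomp"))
  f <- decomp$components$frequency
  inband <- f >= lf_band[1L] & f <= lf_band[2L]
  if (!any(inband)) return(NA_real_)
  fb <- f[inband]
  fb[which.min(abs(fb - target))]
}

#' LF/HF power ratio from the spectral decomposition
#'
#' Ratio of the summed component powers in the LF band (closed,
#' `[0.04, 0.15]` Hz) to those in the HF band (half-open,
#' `(0.15, 0.4]` Hz).  Components above the HF upper edge (and below the LF
#' lower edge) belong to neither band.  `NA` when either band is empty.
#'
#' @param decomp an `ar_decomp` from [spectral_decomposition()].
#' @param lf_band,hf_band band edges in Hz.
#' @return dimensionless power ratio, or `NA_real_`.
#' @export
lf_hf_ratio <- function(decomp, lf_band = c(0.04, 0.15),
                        hf_band = c(0.15, 0.4)) {
  stopifnot(inherits(decomp, "ar_decomp"))
  f <- decomp$components$frequency
  pw <- decomp$components$power
  in_lf <- f >= lf_band[1L] & f <= lf_band[2L]
  in_hf <- f > hf_band[1L] & f <= hf_band[2L]
  if (!any(in_lf) || !any(in_hf)) return(NA_real_)
  sum(pw[in_lf]) / sum(pw[in_hf])
}

#' Descriptive index set of an AR model
#'
#' Bundles the three indexes: `f_lf` (LF peak frequency, Hz), `p_lfhf`
#' (LF/HF power ratio) and `s_x` (information storage, nats).  Undefined
#' indexes -- no component in the LF or HF band -- are explicit `NA`s.
#'
#' @param model an [ar_model()] (e.g. the `model` element of an [ar_fit()]);
#'   must be stable.
#' @param lf_band,hf_band,target band edges and LF target frequency in Hz.
#' @return an object of class `ar_indexes`: list with elements `f_lf`,
#'   `p_lfhf`, `s_x`.
#' @examples
#' hrv_indexes(benchmark_model())
#' @export
hrv_indexes <- function(model, lf_band = c(0.04, 0.15),
                        hf_band = c(0.15, 0.4), target = 0.1) {
  stopifnot(inherits(model, "ar_model"))
  if (!is_stable(model$a))
    .stopf("unstable model: indexes undefined")
  if (model$sw <= 0)
    .stopf("degenerate model (zero innovation variance): indexes undefined")
  v <- .indexes_from_params(model$a, model$sw, model$dt,
                            lf_band = lf_band, hf_band = hf_band,
                            target = target)
  structure(list(f_lf = v[[1L]], p_lfhf = v[[2L]], s_x = v[[3L]]),
            class = "ar_indexes")
}

# fast path used in resampling loops: returns c(f_lf, p_lfhf, s_x) with NA
# for undefined entries; NAs everywhere if the coefficients are unstable.
.indexes_from_params <- function(a, sw, dt, lf_band = c(0.04, 0.15),
                                 hf_band = c(0.15, 0.4), target = 0.1) {
  if (all(a == 0)) return(c(NA_real_, NA_real_, 0))
  r <- .ar_poles(a)
  if (any(Mod(r) >= 1)) return(c(NA_real_, NA_real_, NA_real_))
  .indexes_from_roots(r, a, sw, dt, lf_band, hf_band, target)
}

# same, with the characteristic roots already at hand (hot resampling loop)
.indexes_from_roots <- function(r, a, sw, dt, lf_band = c(0.04, 0.15),
                                hf_band = c(0.15, 0.4), target = 0.1) {
  p <- length(r)
  if (p > 1L) {
    dmat <- Mod(outer(r, r, "-"))
    if (min(dmat[upper.tri(dmat)]) < 1e-8) {
      # (near-)repeated poles: residues blow up; covariance solve for S_X
      sx_tot <- .process_variance(a, sw)
      return(c(NA_real_, NA_real_, 0.5 * log(sx_tot / sw)))
    }
  }
  res <- .pole_residues(r, sw)
  im <- Im(r)
  keep_pair <- im > 1e-12 * (1 + Mod(r))
  keep_real <- abs(im) <= 1e-12 * (1 + Mod(r))
  f <- c(Arg(r[keep_pair]), ifelse(Re(r[keep_real]) >= 0, 0, pi)) /
    (2 * pi * dt)
  pw <- c(2 * Re(res[keep_pair]), Re(res[keep_real]))
  in_lf <- f >= lf_band[1L] & f <= lf_band[2L]
  in_hf <- f > hf_band[1L] & f <= hf_band[2L]
  f_lf <- if (any(in_lf)) {
    fb <- f[in_lf]
    fb[which.min(abs(fb - target))]
  } else NA_real_
  p_lfhf <- if (any(in_lf) && any(in_hf)) sum(pw[in_lf]) / sum(pw[in_hf])
            else NA_real_
  tot <- sum(pw)
  # residues of a draw grazing the unit circle can lose positivity
  s_x <- if (tot > 0) 0.5 * log(tot / sw) else NA_real_
  c(f_lf, p_lfhf, s_x)
}

#' @export
print.ar_indexes <- function(x, ...) {
  fmt <- function(v, d = 4) if (is.na(v)) "undefined" else sprintf("%.*g", d, v)
  cat(sprintf("f_LF = %s Hz, P_LFHF = %s, S_X = %s nats\n",
              fmt(x$f_lf), fmt(x$p_lfhf), fmt(x$s_x)))
  invisible(x)
}

#' @export
as.numeric.ar_indexes <- function(x, ...)
  c(f_lf = x$f_lf, p_lfhf = x$p_lfhf, s_x = x$s_x)
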