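# Independent oracles used to freeze expected values.  These deliberately
# avoid the package's residue/covariance algebra: component powers come from
# numerical contour integration of the autocovariance generating function,
# autocovariances from a direct Yule-Walker solve written here.

# power of each oscillatory component by contour integration of
# G(z)/z = sw / (z A(z) A(1/z)) on a small circle around each pole
contour_component_powers <- function(a, sw, dt = 1) {
  p <- length(a)
  r <- polyroot(c(-rev(a), 1))
  G_over_z <- function(z) {
    k <- seq_len(p)
    Az  <- vapply(z, function(zz) 1 - sum(a * zz^(-k)), complex(1))
    Azi <- vapply(z, function(zz) 1 - sum(a * zz^(k)), complex(1))
    sw / (z * Az * Azi)
  }
  sing <- c(r, 1 / r)                      # all poles of G(z)/z (p >= 1)
  res <- vapply(seq_along(r), function(i) {
    eps <- 0.4 * min(Mod(r[i] - sing[-i]))
    th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
    z <- r[i] + eps * exp(1i * th)
    mean(G_over_z(z) * eps * exp(1i * th))   # (1/2pi) * integral
  }, complex(1))
  im <- Im(r)
  tol <- 1e-12 * (1 + Mod(r))
  data.frame(
    frequency = c(Arg(r[im > tol]), ifelse(Re(r[abs(im) <= tol]) >= 0,
                                           0, pi)) / (2 * pi * dt),
    power = c(2 * Re(res[im > tol]), Re(res[abs(im) <= tol])))
}

# autocovariances gamma_0..gamma_max_lag of a stable AR process by solving
# the Yule-Walker system directly
yw_autocov <- function(a, sw, max_lag = 1L) {
  p <- length(a)
  # unknowns gamma_0..gamma_p; equations:
  # gamma_0 = sum a_k gamma_k + sw; gamma_j = sum a_k gamma_{|j-k|}, j=1..p
  A <- matrix(0, p + 1L, p + 1L)
  b <- c(sw, numeric(p))
  A[1L, 1L] <- 1
  A[1L, 1L + seq_len(p)] <- -a
  for (j in seq_len(p)) {
    A[j + 1L, j + 1L] <- A[j + 1L, j + 1L] + 1
    for (k in seq_len(p)) {
      col <- abs(j - k) + 1L
      A[j + 1L, col] <- A[j + 1L, col] - a[k]
    }
  }
  g <- solve(A, b)
  if (max_lag <= p) return(g[seq_len(max_lag + 1L)])
  out <- c(g, numeric(max_lag - p))
  for (j in (p + 1L):max_lag)
    out[j + 1L] <- sum(a * out[j + 1L - seq_len(p)])
  out
}

# rejection-sample a random stable AR coefficient vector with simple poles
random_stable_coefs <- function(p) {
  repeat {
    a <- runif(p, -1.2, 1.2)
    if (!is_stable(a)) next
    r <- polyroot(c(-rev(a), 1))
    if (p == 1L) return(a)
    d <- Mod(outer(r, r, "-"))
    if (min(d[upper.tri(d)]) > 1e-6) return(a)
  }
}

# an ar_fit whose parameter uncertainty has been zeroed out (the degenerate
# Gaussian fixture: N -> infinity at fixed estimates)
zero_uncertainty_fit <- function(fit) {
  fit$coef_cov[] <- 0
  fit$sw_var <- 0
  fit
}
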