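---
title: "Confidence limits for descriptive indexes of autoregressive time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence limits for descriptive indexes of autoregressive time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arclim)
```

## The problem

Short physiological recordings -- the motivating case is a 5-minute
beat-to-beat R-R interval series, roughly 300 samples with a mean heart
period near 1 s -- are routinely summarised by descriptive indexes computed
from an autoregressive (AR) model fitted to the single recording:

* `f_LF`, the central frequency of the low-frequency spectral component
  (the Mayer-wave peak near 0.1 Hz);
* `P_LFHF`, the ratio of oscillatory power in the LF band (0.04--0.15 Hz)
  to that in the HF band (0.15--0.4 Hz);
* `S_X`, the information storage, `0.5 * log(Sigma_X / Sigma_W)` in nats,
  where `Sigma_X` is the stationary process variance and `Sigma_W` the
  innovation variance -- how much of the present sample is predictable from
  the past.

All three are strongly nonlinear functions of the AR parameters, so their
sampling distributions have no usable closed form, yet individual-level
inference ("did this subject's LF/HF ratio really change between tasks?")
needs confidence limits for a *single* recording. arclim reproduces the
sampling distribution numerically and reads confidence limits and tests off
the empirical distribution.

## Model and estimators

The recursion is `x(n) = sum_{k=1..p} a_k x(n-k) + w(n)` with Gaussian white
innovations of variance `Sigma_W`. Stacking rows `n = p+1..N` as
`X = Z A + W`, `ar_fit()` estimates

* `A` by ordinary least squares (Cholesky solve of the normal equations
  `Z'Z A = Z'X`; no explicit inversion);
* `Sigma_W` as the mean squared residual with divisor `N - p`;
* the coefficient covariance as `Sigma_W (Z'Z)^{-1}`;
* the variance of the `Sigma_W` estimate as `2 Sigma_W^2 / N`.

For `N` above roughly 100 the t-type sampling distribution of the
coefficients is indistinguishable from the Gaussian used by the Monte Carlo
scheme below; no exact small-sample inference is attempted.

The sample mean is removed before regression (`demean = TRUE` by default).
The model describes a zero-mean process while recorded R-R series are not;
whether the original analyses pre-centred their series is not documented,
so per-recording mean removal -- the only choice that works for raw data --
is the default and can be switched off.

Model order is selected by `select_order()` minimising
`AIC(p) = N log(Sigma_W(p)) + 2p`, ties broken toward the smaller order;
the cohort driver scans 5--15 as is customary for short-term HRV. A
candidate order whose regression is exactly singular (this happens for
orders above 1 on a noiseless recursion, whose higher-lag regressors are
collinear) drops out of the scan rather than aborting it; only a scan in
which *every* order fails is an error. Note that AIC overfits with
appreciable probability (~25--30% in our order-recovery experiments on the
benchmark process at N = 3000) -- it is modal at the true order, not a
consistent estimator.

A fit whose residual variance collapses numerically to zero (a noiseless
recursion) is flagged `degenerate`; every index involving
`log(Sigma_X / Sigma_W)` is undefined there and resampling refuses to run,
rather than silently propagating infinities.

## Spectrum, decomposition and indexes

The AR power spectral density is
`P(f) = Sigma_W * T / |A(e^{i 2 pi f T})|^2` with `A(z) = 1 - sum a_k z^-k`.
The sampling-period factor `T` is included so `P(f)` is a density per Hz
whose two-sided integral equals `Sigma_X`; with `T = 1`, as in all
simulations here, the printed and density forms coincide. For recorded R-R
series the frequency axis is calibrated by `T =` mean R-R interval in
seconds, the standard mapping from beat-domain spectra to Hz.

`spectral_decomposition()` splits `P(f)` into one component per real pole
and per complex-conjugate pole pair of `A(z)`, by the residue method applied
to the autocovariance generating function `G(z) = Sigma_W / (A(z) A(1/z))`:
the power of the component anchored at pole `r_i` is the residue of
`G(z)/z` there (doubled real part for a conjugate pair), and the component
powers sum exactly to `Sigma_X`. The central frequency is the pole phase
mapped to Hz (0 for positive real poles, the Nyquist frequency for negative
ones). Two numerical choices deserve note:

* **Repeated poles.** The residue formula assumes simple poles; poles
  closer than `1e-8` in the complex plane raise an error. In the resampling
  hot path a near-repeated draw falls back to the stationary-covariance
  solve for `S_X` and marks the spectral indexes undefined -- a measure-zero
  event in practice.
* **Negative component powers.** When poles interact strongly, individual
  residues can be negative while the total is conserved. Values are
  retained (discarding them would destroy conservation) and a warning is
  emitted; this is an inherent property of the decomposition, not a bug.

`Sigma_X` itself (`process_variance()`) is computed from the stationary
covariance equation of the companion form, `vec(S) = (I - F %x% F)^{-1}
vec(Q)` -- the *model-implied* variance. The sample variance would be an
alternative reading for `S_X` on data, but Monte Carlo replicates have no
data attached, so the model-implied form is the only one that can be used
consistently across point estimates and replicates, and is used everywhere.

Band rules for the indexes: `f_LF` is the component frequency inside the
closed LF band `[0.04, 0.15]` Hz nearest 0.1 Hz; the band restriction is
inferred from the behaviour of under-ordered fits, whose only component
sits in the HF band and must *not* be reported as an LF peak. `P_LFHF`
sums component powers over LF and over the half-open HF band
`(0.15, 0.4]`; components outside both bands (VLF below 0.04 Hz, anything
above 0.4 Hz) count toward neither. An empty band makes the corresponding
index explicitly undefined (`NA`), never silently zero.

## Resampling schemes

`ar_replicates()` builds `M` surrogate parameter sets from one fit
(`M = 1000` in all study drivers; smaller `M` only trades resolution of the
5th/95th percentiles):

* **Monte Carlo** (`"mc"`): coefficients drawn from
  `N(A_hat, Sigma_W (Z'Z)^{-1})`, the innovation variance independently
  from `N(Sigma_W, 2 Sigma_W^2 / N)`. Draws with nonpositive variance or
  unstable coefficients do not describe a stationary AR process; they are
  rejected and redrawn (the count is reported), which preserves the support
  of valid models rather than clipping. If `20 M` draws cannot produce `M`
  valid ones the fit is too close to instability for the Gaussian
  approximation and the function stops.
* **Bootstrap** (`"bs"`): mean-centred residuals are resampled with
  replacement and pushed through `X* = Z A_hat + V` on the *original*
  regressor matrix; parameters are re-estimated by the same least-squares
  formulas. Keeping the design fixed is the natural reading of the
  generating equation (the surrogate series only defines samples
  `p+1..N`; rebuilding lagged regressors from it would discard another `p`
  points); a fully recursive regeneration from the first `p` observed
  samples is available via `design = "recursive"`. Residuals are
  mean-centred before resampling, standard residual-bootstrap practice.
  Unstable re-estimates are kept as parameter draws but their indexes are
  marked undefined.

Monte Carlo is roughly three orders of magnitude cheaper (no re-fit per
replicate) and is the default in the study drivers; the bootstrap does not
assume Gaussian coefficients and is preferable for very short or clearly
non-Gaussian recordings. On the benchmark process the two give interquartile
widths within a few percent of each other.

`confidence_summary()` reports the 5/25/50/75/95 percentiles of the defined
replicate values using the linear-interpolation percentile rule (R's
default type 7). The rule is fixed and documented because the extreme
percentiles of 1000 replicates are sensitive to it. A summary with fewer
than 90% defined replicates (e.g. `f_LF` when the LF component keeps
vanishing) is flagged unreliable.

`difference_test()` compares two replicate sets: the first is randomly
permuted (seeded) and subtracted element-wise from the second -- a random
pairing of independent replicates, deliberately not all `M^2` cross-pairs,
which would not be independent samples -- and the null of equal indexes is
rejected at level `alpha` when zero falls outside the closed interval
between the `100*alpha/2` and `100*(1-alpha/2)` percentiles of the
differences. Zero exactly on a boundary is *not* significant (the
conservative convention; it also makes the all-constant degenerate case
behave sensibly). Pairs with an undefined member are dropped; fewer than 10
surviving pairs is an error rather than a silent verdict.

**Seeding.** Every stochastic function takes one integer seed and restores
the caller's RNG state afterwards. Drivers derive per-run/per-purpose child
seeds deterministically from their master seed, so a whole simulation study
or cohort analysis is bit-reproducible from a single integer.

## Simulators and the study drivers

The benchmark process (`benchmark_model()`) is a fifth-order AR process
built from poles -- real pole 0.65 (VLF), conjugate pair 0.8 at 0.1 Hz
(LF), conjugate pair 0.92 at 0.25 Hz (HF), unit innovation variance --
emulating a typical short-term R-R spectrum at a 1-s mean heart period.
Coefficients are always *derived from the poles* by polynomial expansion
(`poles_to_coefficients()`): a printed coefficient vector circulating for
this configuration disagrees with its own pole specification in the signs
and one magnitude of the even-lag coefficients and is in fact unstable,
while the expansion matches it at the odd lags to 3 decimals. The expansion
is the self-consistent choice and the discrepancy is pinned down in the
test suite.

Deviations from the plain linear generator, each available through
`sim_config()` (one mode per configuration):

* `simulate_squared()` adds `beta (x(n-1)^2 - x(n-2)^2)`. At the benchmark
  amplitude the quadratic term leaves its contraction basin for `beta`
  around 0.06 and the recursion escapes to infinity for most seeds; the
  generator therefore monitors `|x| > 1e6` and aborts naming the seed.
  `beta = 0.02` is reliably finite and is what the mild-nonlinearity tests
  use.
* `simulate_threshold()` switches between two coefficient regimes on the
  previous sample crossing `gamma`. Thresholds and trend amplitudes are
  scaled by the process *standard deviation* (not variance): percentages
  of a squared quantity would not be commensurable with the signal, and the
  SD reading is the one consistent with "50% of the AR process standard
  deviation" phrasing of mild nonstationarity.
* `add_trend()` superimposes a sinusoid with amplitude relative to the
  series SD and a seeded uniform random phase (fixed phase available).
  Note that over a half-period window the sample mean absorbs part of the
  sinusoid, so the added variance is `(1/2 - 2/pi^2) A^2` rather than
  `A^2/2`; the tests check both regimes.
* Burn-in is 1000 samples by default -- generous for the slowest pole
  (modulus 0.92, time constant ~12 samples) and cheap.

`gold_standard()` provides the reference the resampling schemes are judged
against: indexes from many fresh realizations of the *true* process,
available only in simulation.

`run_simulation_study()` orchestrates a grid of configurations: per
configuration it simulates, fits, resamples and averages the per-run
percentiles; between consecutive configurations it difference-tests each
index on run-matched pairs and records the detection count out of `runs`.
With no parameter change between configurations the count is a
false-positive count, bounded (at 95% confidence, 100 trials, alpha 0.05)
by 9 under the binomial model -- `binomial_false_positive_bound()` computes
that ceiling.

`run_cohort_analysis()` applies the pipeline per subject and task (AIC
order selection, fit, Monte Carlo limits, pairwise task tests) and
summarises the group with the median/IQR of within-subject differences, a
paired Wilcoxon signed-rank p-value (base R's `wilcox.test`; supporting
output, not part of the method), and the percentage of subjects with
significant increase / no change / decrease. `synthetic_cohort()` generates
a stand-in cohort from the benchmark process for testing; it emulates the
amplitude and spectral shape of R-R series but none of the physiological
couplings (respiration, nonstationarity between tasks, non-Gaussian
innovations), so a passing null-cohort test demonstrates the statistical
machinery, not fidelity to recorded humans.

## Problem sizes used by the test suite

The acceptance-level experiments in the package tests use the study
conditions as such: 100 simulated pairs per comparison, N = 300 samples
(120/300/600 in the length sweep), AR(5) fits, `M = 1000` Monte Carlo
replicates, alpha 0.05. Supporting property tests use what each property
needs: 500 random stable models for power conservation, 200 runs with
`M = 500` for interval coverage, 20 averaged runs for the MC/BS/gold width
comparison, 1000 realizations for gold-standard distributions.

## Known limitations

* All inference assumes the recording is a realization of a stationary
  linear Gaussian AR process of the fitted order. The nonlinear and
  nonstationary simulators exist precisely to probe mild violations;
  strong violations bias the indexes themselves, and no confidence-limit
  construction can compensate for that.
* The index estimators are biased (nonlinear functions of nearly unbiased
  parameter estimates). Resampling reproduces dispersion around the
  *estimate*, not around the truth, so empirical coverage of the true value
  sits slightly below nominal -- the coverage tests accept 80--98% for a
  nominal 90% interval for exactly this reason.
* `f_LF` is only meaningful when an LF component exists; its confidence
  summary is flagged unreliable when many replicates lose the component,
  which is itself diagnostic of an absent LF peak.
* Percentile intervals are used throughout; no bias-corrected or
  accelerated bootstrap variants, and no analytical delta-method intervals.
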