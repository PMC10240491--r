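---
title: "Models and methods behind xpcsdyn"
author: "xpcsdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xpcsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`xpcsdyn` analyzes X-ray photon correlation spectroscopy (XPCS) data of
slow, beam-stimulated nanoscale dynamics — the regime encountered in
hydrated protein powders, granular soft solids and glasses, where coherent
small-angle speckle fluctuates over seconds to hours and the X-ray beam
itself drives stress–relaxation. This vignette explains the models the
package implements, the choices made where the methodology is genuinely
open, and what the synthetic generators do and do not emulate.

## The observables

**Intensity autocorrelation.** For the photon counts `I(Q, t)` of detector
pixels in a thin annulus around momentum transfer
`Q = (4*pi/lambda) * sin(theta)` (exact trigonometry, no small-angle
approximation), the package estimates

    g2(Q, t) = < I(Q, t0) I(Q, t0 + t) > / ( <I(Q, t0)> <I(Q, t0 + t)> )

averaging over start times `t0` and annulus pixels (`computeG2`). The
symmetric two-mean normalization is used instead of a single squared mean:
under stationarity they coincide, but the two-mean form is robust to slow
intensity drift. Decays are fitted with the Kohlrausch–Williams–Watts
(KWW) model

    g2(t) = c + beta * exp( -2 (t / tau)^alpha )

(`fitKWW`), with speckle contrast `beta`, baseline `c`, time constant
`tau` (s) and shape exponent `alpha`. The factor 2 in the exponent makes
the underlying *field* correlation `exp(-(t/tau)^alpha)` (Siegert
relation); the convention is applied identically in the fitters and in
both synthetic generators, so recovered `tau` always refers to the field
decay. `alpha < 1` indicates stretched (heterogeneous) relaxation,
`alpha > 1` compressed, ballistic-like driven dynamics.

**Two-time correlation.** Non-stationary and intermittent dynamics are
resolved by the two-time correlation matrix (`computeTTC`)

    C(t1, t2) = <I(t1) I(t2)>_pix / ( <I(t1)>_pix <I(t2)>_pix ),

averaged over pixels only. Its diagonal variance at fixed lag `dt`,
normalized by the squared contrast,

    chi_T(dt) = Var_t[ C(t, t + dt) ] / beta^2

(`computeChiT`), is an experimentally accessible estimator of the
four-point dynamic susceptibility: a peak in `chi_T` signals dynamical
heterogeneity. `chi0 = max_dt chi_T(dt)` is tracked across temperature
(`chi0VsTemperature`), with the peak temperature located by a three-point
parabola around the discrete argmax.

**Kinetic models.** Three parametric laws connect the fitted time
constants to the physics:

* beam-flux coupling `1/tau = 1/tau0 + a F` (`fitFluxCoupling`), with
  equilibrium constant `tau0` (s) and coupling `a` (um^2/ph) against flux
  density `F` ((ph/s)/um^2);
* Arrhenius temperature dependence `tau0(T) = A exp(Ea / (R T))`
  (`fitArrhenius`), fitted as a weighted regression of `ln tau0` on
  `1/T`; activation energies are molar, so `R = 8.314462618 J/(mol K)`
  plays the role of the Boltzmann constant and `Ea` is reported in
  kJ/mol;
* a Gaussian dip `alpha(T) = alpha0 - depth * exp(-(T-Tmin)^2/(2 w^2))`
  for the KWW-exponent minimum (`locateKWWMinimum`), with a deterministic
  argmin fallback (ties resolved towards lower temperature) when the fit
  does not converge.

Because the temperature scan is acquired at finite flux, the observed
rates contain the beam term. `runTemperatureScan` therefore inverts the
known coupling, `1/tau0 = 1/tau - a F`, before the Arrhenius regression;
temperatures where the beam term exceeds the measured rate are dropped
with a warning. Without this correction the beam contribution flattens
the apparent temperature dependence and the activation energy is not
recoverable.

**Flux rescaling.** `rescaleTimeAxis` expresses each curve's lag axis in
units of its flux-dependent decay by applying the factor
`1 + a F tau0 = tau0 / tau(F)`; all curves then collapse onto the
equilibrium decay and the `F = 0` axis is unchanged. (Only this
orientation of the factor superposes the family: dividing the lag axis by
it would map `tau` to `tau^2/tau0`, which separates the curves further.)
The collapse score is the maximum, over a common rescaled-lag grid, of
the spread of the normalized decays `(g2 - c)/beta` across curves,
reported alongside the quadrature-pooled interpolated errors.

## Synthetic data: two independent generators

No public generative model exists for this class of measurements, so the
package ships two deliberately different ones that validate each other
(anti-circularity: neither is derived from the estimators they test).

**Ballistic scatterer sum** (`simulateBallisticSeries`). Each pixel is an
independent speckle realization of `E(t) = sum_j exp(i q x_j(t))` over
point scatterers moving ballistically with velocities drawn from a
symmetric Lévy-stable law of index `mu` (Chambers–Mallows–Stuck sampler).
The stable characteristic function makes the field correlation exactly
`exp(-(c q t)^mu)` with `c` the velocity scale, so the fitted KWW
exponent equals `mu` and the decay rate `1/tau = c q` is linear in `q` —
the ballistic signature. Poisson-timed velocity redraws model discrete
stress-release events. Intensities are averaged over `M` independent
coherence modes (contrast `beta = 1/M`, Gamma-speckle statistics) and
Poisson-sampled at the configured count rate. Lévy draws are truncated
at the ~`1 - 1e-6` tail quantile (computed from the asymptotic Pareto
tail) by resampling, a controlled bias that prevents position overflow at
small `mu`.

**Gaussian-field oracle** (`kwwOracleSeries`). Stationary circularly
symmetric complex Gaussian processes with autocorrelation exactly
`exp(-(t/tau)^alpha)` are drawn by circulant spectral embedding
(`exp(-|t|^alpha)` is a stable characteristic function, hence positive
definite for `alpha <= 2`). The embedding ring is at least twice the
series length, so all used lags carry the exact covariance; eigenvalues
are checked for positivity, tiny negative roundoff is clipped, and
genuinely indefinite embeddings double the ring and eventually fail
loudly. The expected correlation `g2 = 1 + beta exp(-2 (t/tau)^alpha)`
is known analytically, which makes this path the oracle for the
correlators and fitters.

**Intermittency.** Dynamical heterogeneity is modeled as a stationary
two-state telegraph process that modulates the instantaneous decay rate
(`telegraphSpeedFactor`). The two speed factors are mean-rate preserving
(`k*gamma` and `gamma` with `gamma = 1/(p k + 1 - p)`, fast-state
occupancy `p`), so switching redistributes relaxation between fast
bursts and slow stretches without moving the mean rate off the
Arrhenius-plus-flux curve — the line shape stretches (the
`alpha(T)` dip) and the two-time diagonal fluctuates (the `chi_T` peak)
while `tau(T)` stays smooth. Defaults model rare stress-release bursts in
a predominantly slow matrix: fast occupancy 0.3 (dwell times 200 s fast /
467 s slow), state constants 26 s and 220 s, and a Gaussian
intermittency amplitude of width 6 K peaked at `T* = 227 K`. The
telegraph process is the simplest stationary model with these
signatures; the amplitude profile is this package's choice, not an
established law.

**Study conditions.** The generator defaults reproduce the conditions of
the measurements the package targets: flux family of six densities
spanning 0–90% attenuation of `4.4e6 (ph/s)/um^2` with ground truth
`tau0 = 336 s`, `a = 1.1e-8 um^2/ph` and `mu = 1.5` at
`Q = 0.08 1/nm`; a ten-temperature cooling grid
290, 270, 250, 240, 230, 225, 220, 210, 195, 180 K (densified near the
expected anomaly) at `F = 1.5e6 (ph/s)/um^2` with `A = 1.8 s`,
`Ea = 9.4 kJ/mol`, analyzed at `Q = 0.1 1/nm`; detector geometry 12.4 keV
and 75 um pixels with annulus bins of 10% fractional width (bin widths
are not standardized in this field; they are config-exposed here).

What the generators do *not* emulate: spatial speckle-field correlations
between pixels (each pixel is an independent realization — adequate
because every implemented estimator averages over pixels and none uses
cross-pixel structure), detector artifacts beyond hot pixels and streak
sectors, structural (WAXS) signatures, radiolysis chemistry, and beam
heating. Passing tests therefore demonstrate estimator correctness and
parameter recoverability under the stated statistical model, not detector
realism.

## Error models and numerical choices

* **g2 errors** are leave-one-pixel-out jackknife estimates; pixels are
  independent by construction (and approximately so in annuli of real
  detectors), whereas time samples are not.
* **KWW parameter errors**: the usual weighted-least-squares covariance
  underestimates badly here because residuals are correlated across lags
  (overlapping time averages); Monte-Carlo coverage of the nominal
  1-sigma interval was ~0.3. `fitKWW` therefore refits the model on each
  leave-one-pixel-out g2 curve and jackknifes the parameters, which
  restores calibrated intervals (coverage ~0.7 in the test suite's
  Monte-Carlo). The plain `vcov` is the fallback when no per-pixel
  information accompanies a curve.
* **chi_T errors** come from a moving-block bootstrap over diagonal
  segments (default 8 blocks, 200 replicates), respecting the serial
  correlation of diagonal samples; the variance uses the standard
  `n/(n-1)` correction.
* **Finite-span bias**: time-averaged correlation estimators are biased
  low by terms of order `tau/T_span`. Empirically the fitted `tau` is ~5%
  low at `T_span = 60 tau` and unbiased within errors beyond
  `~200 tau`. All default problem sizes in the pipelines and the
  acceptance analyses keep `T_span >= 150-350 tau` (e.g. 10000 frames of
  2 s for the temperature scan, where the equilibrium inversion amplifies
  rate errors at low temperature). This matters most for the Arrhenius
  amplitude `A`, an extrapolation to infinite temperature.
* **Multi-tau lag grid**: the classic 16-channels-per-level doubling grid
  supplies quasi-logarithmic lags, but every lag is evaluated with the
  exact linear estimator (no frame pre-averaging): at these problem sizes
  the O(N · lags) cost is negligible and all lags remain exact, which is
  also what lets the production correlator agree with the brute-force
  reference to 1e-12. Two-time matrices above 4000 frames are
  pre-averaged in non-overlapping windows (window size recorded in the
  object metadata).
* **Contrast estimation** extrapolates `g2 - 1` to zero lag from the
  first lags (the compressed exponential is flat at the origin, so the
  linear extrapolation is nearly unbiased); the alternative variance
  method uses the Poisson-corrected normalized pixel variance
  `(Var I - <I>)/<I>^2`. Estimates not exceeding twice their standard
  error raise an error — that is the designed behavior on speckle-free
  (pure shot noise) input.
* **Fast-timescale windows** (`timescaleAtChiPeak`): the diagonal of the
  TTC at the chi-peak lag is smoothed with a running mean of one peak-lag
  width and segmented into two states by k-means. Diagonal windows of
  width 4x the peak lag (never narrower than 50 frames) are centered on
  the accelerated epochs — the low-C cluster, which dominates the
  variance when the fast state is the minority — and must lie at least
  80% inside that cluster; a local KWW fit per window (contrast and
  baseline held fixed) yields the fast time constant as the window mean.
  When the two cluster centers are closer than 4 within-cluster standard
  deviations (a plain Gaussian splits at ~2.7), the diagonal is treated
  as homogeneous and windows are taken evenly spaced instead, so the
  selection cannot chase noise dips.
* **Determinism**: every generator draws from R's RNG under the seed
  recorded in its configuration; identical configurations produce
  bit-identical frame stacks, and pipeline manifests carry MD5 hashes of
  all deterministic artifacts.

## Known limitations

* The `chi_T` normalization (`beta^2` by default, `mean^2` and raw
  variance available) and the sub-window construction for the fast
  timescale are methodological choices; published analyses rarely state
  theirs, so cross-study comparisons of absolute `chi_T` values should be
  made with the normalization mode in hand (it is recorded in every
  output).
* The telegraph intermittency model produces a symmetric, single-peaked
  anomaly; real dynamical transitions need not be symmetric in
  temperature, and the Gaussian dip/`chi0` peak widths here are inputs,
  not predictions.
* Frame stacks are dense photon-count arrays; event-mode (photon list)
  correlation is out of scope.
* The plain-text frame-stack container is built for reproducibility and
  portability, not storage efficiency; converting vendor detector
  formats is upstream of this package.
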