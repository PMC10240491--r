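# xpcsdyn

Speckle correlation analysis of beam-stimulated nanoscale dynamics for
X-ray photon correlation spectroscopy (XPCS).

In ultrasmall-angle XPCS of hydrated protein powders and similar soft
granular solids, the coherent speckle pattern fluctuates over seconds to
hours, and the X-ray beam itself stimulates the stress–relaxation it
probes. `xpcsdyn` implements the full analysis chain for this regime:

* **Correlators** — the intensity autocorrelation
  `g2(Q,t) = <I(t0)I(t0+t)> / (<I(t0)><I(t0+t)>)` per momentum-transfer
  annulus (multi-tau lag grid, pixel-jackknife errors), and the two-time
  correlation matrix `C(t1,t2)` that resolves intermittent dynamics.
* **Kinetic fits** — the Kohlrausch–Williams–Watts decay
  `g2 = c + beta * exp(-2 (t/tau)^alpha)`; the linear Q-dispersion of the
  rate `1/tau` (ballistic test); the beam-coupling law
  `1/tau = 1/tau0 + a*F`; the time-axis rescaling by `1 + a*F*tau0` that
  collapses flux families; the Arrhenius law `tau0 = A*exp(Ea/RT)`; and
  the Gaussian dip of `alpha(T)`.
* **Dynamical heterogeneity** — the normalized diagonal variance
  `chi_T(dt) = Var_t[C(t, t+dt)]/beta^2` (an accessible estimator of the
  four-point dynamic susceptibility), its maximum `chi0`, the `chi0(T)`
  peak, and a TTC sub-window analysis that extracts the fast process at
  the `chi_T` peak.
* **Synthetic speckle** — two independent generators with known ground
  truth: a ballistic Lévy-stable scatterer sum (KWW exponent = Lévy
  index, rate linear in Q, telegraph intermittency, Poisson photons) and
  a circulant-embedding Gaussian-field oracle with exactly known
  `g2`. Detector geometry, Q-maps, masks, azimuthal profiles and a
  plain-text frame-stack container round out the toolkit.

The methods vignette (`vignettes/xpcsdyn-methods.Rmd`) documents every
model, default and numerical choice.

## Worked example

Simulate a flux family at six flux densities spanning 0–90% attenuation
(equilibrium constant 336 s, coupling 1.1e-8 um^2/ph, KWW exponent 1.5 at
Q = 0.08 1/nm), then fit the full chain:

```r
library(xpcsdyn)

b <- runFluxExperiment(fluxExperimentConfig(seed = 1111))
b$fluxFit
#> Flux coupling 1/tau = 1/tau0 + a F: tau0 = 342.9 +/- 10 s, a = 1.1e-08 +/- 4.4e-11 um^2/ph
round(b$perFlux$tau, 1)
#> [1]  19.4  23.4  29.7  39.9  60.4 128.7
b$collapse$score < 3 * b$collapse$pooledSE   # rescaled curves overlap
#> [1] TRUE
```

The fitted `tau0` is the equilibrium relaxation time extrapolated to zero
flux; `a` quantifies how strongly the beam accelerates the dynamics; the
per-flux time constants shorten from 129 s to 19 s as the flux density
grows, and after rescaling the lag axes by `1 + a*F*tau0` all six decays
collapse onto the equilibrium curve.

A temperature scan with the telegraph intermittency schedule locates the
dynamic anomaly twice — as a dip of the KWW exponent and as a peak of the
heterogeneity measure `chi0`:

```r
b <- runTemperatureScan(
  temperatureScanConfig(seed = 5, het = HeterogeneitySchedule()))
b$minimum
#> KWW-exponent minimum (gaussian): Tmin = 224.7 K, depth = 0.47 (significant)
b$chi0
#> Chi0Series over 10 temperatures: Tpeak = 226.1 +/- 2.5 K (significant)
```

Both localizations agree with the configured anomaly temperature
(227 K) within the scan resolution.

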