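---
title: "Methods: chamber isotope fluxes, xylogenesis and allocation coherence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chamber isotope fluxes, xylogenesis and allocation coherence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`carboniso` analyses how tree organ growth and carbon allocation shape the
magnitude and carbon-isotope composition (delta13C) of shoot, stem and soil
CO2 fluxes over a growing season. This vignette documents the models, the
numerical choices, the synthetic-data generator and the package's own
resolutions of design questions the measurement protocol leaves open.

## 1. Chamber model and flux inversion

A closed chamber flushed by a free ambient leak obeys, per isotopologue,

$$\frac{dC}{dt} = \frac{F \, S \, V_m}{V} + q\,(C_\mathrm{amb} - C),$$

with concentration $C$ in ppm, flux $F$ in umol m-2 s-1, exchange surface
(or leaf area) $S$ in m2, chamber volume $V$ in litres, molar volume $V_m$
(ideal gas at the configured chamber temperature, 1 atm) and leak rate $q$
in s-1. Its solution through the closure start is the saturating
exponential fitted by `fit_closure()`. Assumptions: well-mixed chamber air,
constant flux over the (short) fit window, and a closure that starts at
ambient concentration, so the intercept at $t=0$ estimates
$C_\mathrm{amb}$. With that boundary condition the three parameters per
trace (intercept, initial slope, shared $q$) are identifiable; without it,
ambient concentration and the saturation asymptote are confounded.

Numerics. The model is linear in intercept and initial slope once $q$ is
fixed, so the fit is solved by variable projection: an exact linear
least-squares solve per candidate $q$ inside a 1-D minimisation of the
pooled residual sum of squares over $q \in [-q_{max}, q_{max}]$
(`q_max = 0.02` s-1 by default). $(1-e^{-qt})/q$ is evaluated via
`expm1` with a series fallback so the $q \to 0$ (purely linear) limit is
smooth. $q$ is shared between the two isotopologue traces because the
physical replacement rate cannot depend on the isotopologue; this also
stabilises the low-abundance 13CO2 fit, whose residuals are up-weighted
(x1e4) to put both traces on a comparable numerical scale. A negative or
boundary optimum for $q$ triggers the linear-slope fallback (the $q=0$
limit of the same model) and flags the record; traces whose concentration
change over the window is indistinguishable from the residual noise are
flagged `zero_flux` and their delta is undefined. Fit windows default to
5-50 s (shoot), 10-40 s (stem) and 40-200 s (soil) to exclude
pressure-transient effects at closure, and efflux is reported positive for
stem/soil while influx is positive for the shoot.

The delta13C of a flux is computed from the fitted isotopologue fluxes as
$\delta = (F^{13}/F^{12}/R_\mathrm{VPDB} - 1)\cdot 1000$ with
$R_\mathrm{VPDB} = 0.0111802$. Because both traces share the fitted $q$,
any error in $q$ cancels exactly in the ratio: the delta estimate is
considerably more robust than the flux estimate, which is the property the
downstream coherence analysis relies on. Two-point (or least-squares)
reference-gas calibration is applied by `calibrate_delta()`.

Daily aggregation classifies a closure as nighttime when PAR at closure is
below 30 umol m-2 s-1, averages daytime shoot influx, nighttime stem
efflux and all-day soil efflux per calendar day (site-local day of the
closure start; the simplest reproducible rule), and weights delta by the
absolute member fluxes. Days without usable closures are omitted rather
than zero-filled. Linear-fallback records keep their flux estimate and
remain in the aggregation; only `zero_flux` records are excluded.

## 2. Gompertz xylogenesis model

Cumulative tracheid counts per phenophase are normalized by each tree's
previous-year ring width and pooled across trees per date (per-tree values
are retained for the mixed models). Total and mature counts are fitted
with $y(t) = A \exp(-\beta e^{-\kappa t})$, $t$ in day of year — the
standard three-parameter form in xylogenesis; the fit is `nlsLM` on the
reparameterisation $\log\beta$ with bounds keeping $A, \kappa > 0$,
initialised from the maximum count ($A$), a log-linearisation of the
mid-rise observations ($\kappa$, $\beta$), and at least five jittered
restarts against local minima. Pooled fitting is the default; per-tree
fits use the same function (the repeated-measures protocol does not state
which was used in the field; both are available).

The daily active-phase count is the fitted total minus the fitted mature
curve, clipped at zero with a warning if the curves cross (a finite-sample
artefact). The tracheid growth rate is defined as the day-over-day
increase of the fitted *total* curve: new cells enter through the
enlargement phase, so this equals the daily recruitment into the active
phases and is non-negative by construction, whereas differencing the
active-phase count itself goes negative once maturation outpaces
production. Growth periods are threshold rules on the fitted rates:
production (maturation) period where the rate exceeds `f1` (default 5%) of
its seasonal maximum, maximum-rate periods where it exceeds `f2` (default
75%), and earlywood/latewood bounds where the fitted total curve crosses
`ew_frac` (65%) and `lw_frac` (90%) of its asymptote. The field dates such
periods are reported with cannot be reproduced from curves alone, so all
four thresholds are exposed configuration, not constants; raising `f1` can
only narrow a period (tested property). Root growth periods are detected
per scanner by a centred 7-day moving mean, thresholded at `min_amp`
(default 0.5 mm day-1), with runs closer than `min_gap_days` merged within
a scanner and overlapping pulses merged across scanners.

## 3. Detrending and association models

Nighttime stem efflux is regressed on nightly mean air temperature (the
night window defined by the same PAR threshold) as $R = a e^{bT}$ by
`nlsLM`, initialised in log space when all fluxes are positive and from
quartile ratios otherwise; the residuals are the temperature-detrended
signal and $Q_{10} = e^{10b}$. The residual series is shifted by one day
(`lag_shift`) because stem CO2 efflux lags the respiration driving it by
about a day through within-stem diffusion. Root growth and soil efflux are
detrended by an additive linear regression on soil temperature and soil
moisture (the functional form is unstated in the protocol; additive linear
is the minimal choice and leaves residuals orthogonal to both drivers).

Associations between growth, NSC pools and detrended fluxes use two model
families mirroring the measurement design: a linear mixed-effects model
with a per-tree random intercept (maximum likelihood, `nlme`) when both
variables are measured repeatedly on the same trees, and ordinary least
squares on stand averages otherwise. Day of year starts in every model as
a covariate and is removed when its p-value is at or above 0.05 (the
conventional threshold; the protocol states the rule but not the number).
Non-significant interactions are likewise excluded; the models fitted by
the pipeline are main-effects only. A singular or non-converging mixed fit
falls back to OLS with a note in the result. Mixed-model R2 is reported as
the variance-partition marginal/conditional pair, since a bare "model R2"
is ambiguous for mixed models. `fit_lm()` accepts exclusion dates for
observation days where starch re-mobilization blurs the isotopic link
between sugars and respiration. No multiple-testing correction is applied
(none is applied in the emulated analysis; the model table reports raw p).

## 4. Wavelet coherence

Daily delta13C series are gap-filled by linear interpolation (interior
gaps only, ceiling 10% by default; leading/trailing gaps are trimmed). The
continuous wavelet transform uses the analytic Morlet wavelet with
$\omega_0 = 6$, zero padding to the next power of two, and a dyadic scale
grid with 12 voices per octave. Squared coherence follows the standard
recipe $|S(W_{xy}/s)|^2 / (S(|W_x|^2/s) \, S(|W_y|^2/s))$ with smoothing
$S$ a Gaussian of standard deviation equal to the scale in time (applied
in the Fourier domain) and a boxcar over 0.6 octave across scales. The
cone of influence is the e-folding distance $\sqrt{2}s$ of the Morlet
envelope; reporting is restricted to inside the cone. Phase is the
argument of the smoothed cross-spectrum with the convention that phase in
$(0, \pi)$ means the first series leads; the implied lag at period $P$ is
$\mathrm{phase} \cdot P / 2\pi$ days. Because the isotopic signal travels
from assimilation to respiration, only cells where assimilation leads are
summarised as lags; phases are averaged circularly.

Significance uses surrogate pairs of independent AR(1) processes matched
to each series' lag-1 autocorrelation and variance — the default surrogate
family for autocorrelated daily series. Null coherence values are pooled
over time inside the cone per period, and a cell is significant when the
observed coherence exceeds the $(1-\alpha)$ null quantile of its period
row. The protocol this emulates delegates wavelet settings to a software
package without printing them, so $\omega_0$, the voice count, the
smoothing widths, $\alpha$ and the surrogate count are all exposed in the
configuration; the defaults above are community standards, not claims
about the original settings.

## 5. The synthetic-data generator

The generator produces one boreal growing season (May 1 - Sep 30, 2018
calendar) with known ground truth; it emulates the *structure* of the
field record, not its statistics:

- **Environment** (30-min grid): seasonal + diurnal air temperature with
  day-level AR(1) anomalies; soil temperature as a damped 5-day running
  mean; PAR as a half-sine daylight course (exactly zero in the
  configured night hours); bucket-model soil moisture with precipitation
  suppressed inside the configured dry window (Aug 16 - Sep 11), so
  moisture declines monotonically through the dry-down and recovers after.
- **Flux truth**: stem efflux $a e^{bT}$ plus a term proportional to the
  tracheid growth-rate truth (defaults sized so the nighttime range spans
  roughly 0.1-1.2 umol m-2 s-1); soil efflux as a moisture-modulated
  exponential of soil temperature plus a root-growth-linked term; shoot
  influx as a saturating light response with seasonal amplitude.
- **Isotope truth**: the assimilate delta13C varies with a
  vapour-pressure-deficit proxy (day-level temperature anomaly), a
  seasonal declining trend and AR(1) noise; stem and soil efflux delta13C
  equal the assimilate signal delayed by the allocation lags (1 d stem,
  4 d soil) minus apparent fractionations (4.5 and 1.0 per mil), blended
  with an uncoupled drifting baseline outside configured high
  carbon-demand windows. With full coupling and zero fractionation the
  delayed-copy identity is exact, which the tests exploit.
- **Closures**: the analytic chamber solution per isotopologue plus
  independent Gaussian analyzer noise (0.1 ppm on 12CO2 and the
  VPDB-proportional 0.0011 ppm on 13CO2 by default; instrument precision
  is not published for the emulated system, so it is configurable).
  Chamber geometry defaults (shoot 2.1 l / 0.01 m2, stem 1.0 l /
  0.075 m2, soil 80 l / 0.4 m2) are sized so a closure resolves the
  day-scale isotopic variability: with the default noise they give
  per-closure delta uncertainties of a few per mil and daily flux-weighted
  values well below 1 per mil, consistent with a system that can observe
  a double-digit per-mil seasonal range in efflux delta13C. The closure
  schedule is the protocol's (shoot 60x65 s, stem 48x90 s, soil 8x840 s
  per day).
- **Tracheids**: five trees (configurable) with tree-specific Gompertz
  asymptotes, a mature curve delayed ~30 days at the same asymptote
  (every cell matures), counts scaled by tree ring width, 5% observation
  noise, weekly sampling.
- **NSC**: piecewise-linear seasonal templates; phloem starch peaks at
  72 mg g-1 and falls to 26 mg g-1 across the earlywood-latewood
  transition while sucrose rises (re-mobilization); WSC is the sum of the
  sugar pools by construction and sucrose averages ~34% of it; starch
  delta13C is more stable than sugar delta13C.
- **Roots**: three scanners expressing raised-cosine pulses in the three
  configured growth-period windows with multiplicative lognormal noise.

What it does **not** emulate: weather fronts and synoptic correlation
between drivers, instrument drift and autocorrelated analyzer noise,
chamber temperature artefacts, missing data and quality-control gaps,
between-tree phenology differences beyond the asymptote, and any
statistical match to the real site record. Tests passing on this
generator therefore validate the estimators' correctness and calibration
(bias, type-I error, lag recovery) under known truth — not the field
conclusions themselves.

## 6. Problem sizes and reproducibility

The test suite and the acceptance script run the chamber grid (60
noise-free closures), a 100-day season at 40 closures per day for the
delta-recovery check, 200 simulated trees for Gompertz recovery, 1000
null replicates each for the LM and LMM type-I rates, 200 replicates for
sign recovery, ten white-noise pairs x 1000 AR(1) surrogates for the
significance-mask calibration, and one full-schedule season (~16,000
closures, 300 surrogates) for the end-to-end coupling-window check —
sizes chosen so each experiment's Monte-Carlo error is small against the
property it checks while the whole suite stays interactive. Every
generator draws from seeds derived deterministically from a single master
seed; identical configuration and seed reproduce every table and mask
byte-identically.

Known limitations: the inversion assumes the closure starts at ambient
(a purged or vented chamber); fluxes below the analyzer noise floor carry
no delta information and are flagged rather than estimated; period
classification depends on explicit thresholds with no field-true values
to compare against; the AR(1) surrogate null under-represents
long-memory processes; and the one-command pipeline fits pooled (not
per-tree) Gompertz curves.
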