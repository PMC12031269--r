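---
title: "Models and methods behind ncis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ncis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncis)
```

Non-contact impedance spectroscopy (NCIS) couples a pair of electrodes
capacitively through the insulating wall of standard labware and records the
complex impedance of the solution inside. This vignette explains the models
the package implements, the parameters that matter, the numerical choices
made where the design was genuinely open, and what the synthetic-data
generators do and do not emulate.

## The parallel-RC cell model

Because the wall capacitance is constant, it cancels when impedance *changes*
relative to a baseline solution are analysed, and the cell reduces to the
simplest equivalent circuit of an electrolytic conductivity cell: a solution
resistance $R = K_\mathrm{cell}/\kappa$ in parallel with a coupling
capacitance $C_1$,

$$Z = \frac{R}{1 + i\omega R C_1}, \qquad
C_1 = \frac{\varepsilon_r \varepsilon_0}{K_\mathrm{cell}}.$$

The relation between $C_1$ and $K_\mathrm{cell}$ deserves a note: written as
a product the two would have inconsistent units (F/m · 1/m is not F), while
the quotient form yields a capacitance in farads and makes the cell's RC time
constant $\tau_{RC} = \varepsilon_r\varepsilon_0/\kappa$ independent of
geometry, as it must be for a homogeneous dielectric. `impedance_rc()`,
`cell_constant_from_c1()` and `c1_from_cell_constant()` implement this
corrected reading consistently; under it, substituting
$R = K_\mathrm{cell}/\kappa$ into the complex divider reproduces the closed
forms used for sweeps exactly, which the test suite verifies against the
complex-arithmetic oracle at $10^{-10}$ relative tolerance.

Writing $a = \omega\varepsilon_r\varepsilon_0$, the impedance changes between
a solution of conductivity $\kappa_0$ and the baseline $\kappa_b$ are

$$\mathrm{Re}\,\Delta Z = \frac{\varepsilon_0\varepsilon_r}{C_1}
  \left[\frac{\kappa_0}{\kappa_0^2 + a^2} -
        \frac{\kappa_b}{\kappa_b^2 + a^2}\right], \qquad
  -\mathrm{Im}\,\Delta Z = \frac{\omega(\varepsilon_r\varepsilon_0)^2}{C_1}
  \left[\frac{1}{\kappa_0^2 + a^2} - \frac{1}{\kappa_b^2 + a^2}\right].$$

The single-solution real term peaks at $\kappa_{0,d} = 2\pi f
\varepsilon_r\varepsilon_0$ (`peak_conductivity()`), is log-symmetric about
it, and has maximum $1/(2\omega C_1)$. The usable dynamic range spans about a
decade either side of $\kappa_{0,d}$ (`sensitivity_band()`); outside it the
response flattens, and in particular $-\mathrm{Im}\,\Delta Z$ saturates at
$-1/(\omega C_1)$ once $\kappa_0 \gg a$. That saturation also means the
complex difference of two nearly saturated impedances cancels
catastrophically, which is why the package's oracle tests draw their random
conductivities inside the sensitivity band — the regime where sweeps are
actually measured.

### Calibration

Both model channels are exactly proportional to $1/C_1$, so the joint
weighted least-squares calibration of a sweep is *linear* in $1/C_1$ and
`fit_circuit()` solves it in closed form — no iteration, no starting value,
no convergence failure modes. Residuals are weighted per channel by the
inverse square of the channel's maximum absolute value so that the
imaginary-channel values (often two orders of magnitude smaller) carry equal
weight; one capacitance must describe both curve families at all
frequencies. Defaults: $\varepsilon_0$ fixed at
$8.8541878128\times 10^{-12}$ F/m, $\varepsilon_r = 78$ (water, configurable),
baseline conductivity from the sweep metadata.

At the characterised noise levels (0.7% on the real channel, 0.04% on the
imaginary channel), calibration from a four-frequency, seven-solution sweep
recovers $C_1$ with bias well under 1% and RMSE near 0.1% over 50 replicates.

## Growth-curve models

Individual channels are fitted with the logistic law
$$U(t) = \frac{U_a}{1 + e^{-(t - t_0)/\tau}},$$
where $U_a$ is the amplitude in channel units (negative for channels that
fall during growth — no absolute-value preprocessing is applied), $\tau$ the
volume growth time constant in hours, and $t_0$ the time lag (the midpoint of
the rise). All times in the growth modules are in hours. `fit_sigmoid()` uses
Levenberg–Marquardt with start values from the signed data range, the
half-range crossing and the quartile-crossing spread $(t_{75}-t_{25})/2.2$;
$\tau$ is bounded to $[10^{-3}, 100]$ h.

### The unified two-region model

Optical reflection (wall-adjacent) channels respond hours before optical
density (bulk) in the same culture, and low-frequency impedance tracks the
former while high-frequency impedance tracks the latter. The unified model
rationalises this with two coaxial regions between the electrodes: a central
bulk rod of radius $r_1$ and resistivity index $\rho_1(t)$ following the
logistic law with lag $t_{0b}$, and a wall annulus (outer radius $r_2$,
constant index $\rho_{a2}$) whose growth front advances inward from the wall
with the cube root of exponential volume growth,
$r_1 = r_2 e^{-(t - t_{0w})/3\tau_u}$ for $t \ge t_{0w}$
(`wall_radius()`, `two_region_re_dz()`). The reduced growth signal is

$$U_u(t) = U_n\left[
  \frac{e^{-2(t-t_{0w})/3\tau_u}}{1 + e^{-(t-t_{0b})/\tau_u}}
  + \left(1 - e^{-2(t-t_{0w})/3\tau_u}\right)\frac{\rho_{a1}}{\rho_{a2}}
\right], \quad t \ge t_{0w},$$

reducing to the plain sigmoid before the wall lag. The two branches agree at
$t_{0w}$ and the signal saturates at $U_n\,\rho_{a1}/\rho_{a2}$; the relative
deviation from that asymptote at $t_{0w} + 10\tau_u$ is exactly
$e^{-20/3}(1 + \rho_{a2}/\rho_{a1})$ times the saturated logistic factor —
about 1% once the ratio exceeds 0.15. The package implements the reduced
form with parameters $(U_n, \tau_u, t_{0w}, t_{0b}, \rho_{a1}/\rho_{a2})$;
$U_n$ absorbs the geometry, which is exposed separately through
`two_region_re_dz()` so the parallel-cylinder composition can be checked
against an independent conductance oracle. The reduction from the full
two-region resistance to the mixed form above is heuristic — the stated
parallel-resistance composition and the area-weighted mixture are not
algebraically identical — so the package treats the reduced law as the model
in its own right.

### Two-stage versus joint fitting

`fit_unified()` defaults to the two-stage procedure used in practice: stage 1
fits the plain sigmoid to each curve and fixes $t_{0w}$ from the
low-frequency fit and $(t_{0b}, \tau_u)$ from the high-frequency fit; stage 2
min–max-normalises each curve and estimates its ratio by one-dimensional
least squares on the log scale, with the scale profiled out linearly.

The two-stage shortcut has a structural bias worth understanding: a sigmoid
fit reports the *midpoint* of a rise, but $t_{0w}$ in the unified law is the
*onset* of wall mixing, and for a curve dominated by the mixing term the
midpoint trails the onset by roughly $\tfrac{3}{2}\tau_u \ln 2$ (about 1 h at
$\tau_u = 1$ h). On data generated from the unified law itself, the fixed
lags therefore land away from the generating values and drag the ratio
estimate with them. For parameter *recovery* the package offers
`joint_refit = TRUE`: a Levenberg–Marquardt fit of the stacked, normalised
pair with shared $(\tau_u, t_{0w}, t_{0b})$, per-curve log-ratios, and a free
affine scale per curve (min–max normalisation is affine, so this keeps the
objective smooth). A small multi-start — the stage-1 lags, onset-corrected
lags, and unit ratios — guards against the wrong local basin; the
lowest-deviance solution wins. On unified-law pairs the joint fit recovers
all parameters exactly without noise, and at 1% noise recovers lags within
0.01 h and the ratio within a few percent (median over 50 replicates). A
consequence verified in the tests: with shared lags, the *high*-ratio curve's
normalised half-rise trails the low-ratio curve's by a fraction of an hour,
because its rise is carried by the slower mixing weight.

## The comparison pipeline

`compare_experiment()` mirrors the full workflow on an `ncis_experiment()`:

* **Delays from fitted lags.** Each channel's $t_0$ comes from its own
  sigmoid fit to the raw values; the delay is $t_0 - t_{0,\mathrm{ref}}$
  (negative = leads the reference). Threshold crossings of raw data are
  deliberately not used — they are noise-sensitive and depend on the
  normalisation.
* **Normalisation.** Min–max to $[0,1]$; channels flagged `invert` (optical
  reflection falls during growth) are plotted and normalised as $1 - u_N$.
  Inversion is driven by the channel-metadata flag, never by name matching.
* **Slot averaging.** The continuously sampled impedance record is averaged
  in closed windows $[t_i - t_\mathrm{sample}/2,\, t_i +
  t_\mathrm{sample}/2]$ around each OD sampling time, by default centred at
  $t_i + t_\mathrm{delay}$ so each OD sample is paired with the impedance
  value at the same growth stage. A point on a boundary shared by two
  windows goes to the earlier slot (a deterministic tie-break; the
  convention is a package decision since ties are measure-zero in real
  data). Empty slots are data (`n = 0`), not errors.
* **Regression window.** Ordinary least squares of slot means against OD,
  restricted to OD in $[0.16, 1.3]$ (configurable), closed on both ends —
  again a deterministic choice where open/closed is not physically
  distinguished. $R^2$ is the OLS coefficient of determination.

On noise-free synthetic experiments built from the reference per-channel
time parameters, the pipeline returns the reference delays exactly
($-1.6$, $0$, $-2.1$ h for *S. epidermidis*; $-2.7$, $-1.0$, $-2.4$ h for
*E. coli*), and channel regressions stay above $R^2 = 0.99$ at 1% noise.
Exact $R^2 = 1$ requires the *linear regime*: equal time constants between
channel and reference and delay-aligned sampling, in which case the paired
values are exactly proportional.

## Synthetic data: what it emulates, and what it does not

Generators are seeded and bit-reproducible; zero-noise output equals the
forward model exactly, and any nonzero noise or sampling jitter requires an
explicit seed.

* **Noise** is multiplicative Gaussian per point ($u \mapsto u(1 +
  \sigma_\mathrm{rel} z)$). The characterised percentage standard deviations
  are quoted without a reference scale; per-point relative noise is the
  choice that behaves sensibly across the six decades of conductivity a
  sweep spans. Reference levels: 0.7%/0.04% (lab-bottle sweeps),
  3.6%/0.14% and 0.7%/0.06% (well-plate sweeps), 1% for growth channels.
* **Scenario amplitudes.** Only normalised growth responses are typically reported
  for the bottle experiments, so the scenario amplitudes (5 kΩ at 15 kHz,
  800 Ω at 300 kHz, OD plateau 1.5, −0.2 a.u. reflection) are package
  choices at realistic magnitudes; the comparison pipeline is invariant to
  them by construction.
* **OD sampling** occurs every 0.5–1 h with hand-collection timing; the
  generator jitters sampling times uniformly within ±10% of the interval
  (seeded, disabled for noise-free runs).
* **Temperature** enters as a multiplicative conductivity factor
  $1 + c\,(T - \bar T)$ with $c = 2\%/^\circ$C by default (the coefficient
  implied by the reference medium conductivities, 1.49 S/m at 25 °C versus
  1.75 S/m at 37 °C, is slightly lower at about 1.45%/°C). At the recorded
  millikelvin stabilities the factor deviates from unity by under 0.1%,
  which is why no temperature correction is applied to growth data.
* **Not emulated:** instrument drift, the low-frequency/high-conductivity
  deviations of the bottle configuration from the RC model, the mortality
  phase (the *E. coli* impedance decline at high OD), electrode geometry
  and fringe fields, and any mechanistic link between metabolism and medium
  conductivity. Passing tests on synthetic data therefore demonstrate the
  correctness of the estimators under the stated statistical model, not
  robustness to these real-data effects.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for interactive use: sweeps of
4 frequencies × 7 conductivities, growth grids of 100–300 points, and
Monte-Carlo loops of 50 replicates, which keep the full suite under a
minute. Comparisons to two-significant-figure reference values round with
`signif(x, 2)` before testing equality; identity-type oracles are held to
$10^{-10}$–$10^{-12}$ relative; Monte-Carlo recoveries use the tolerances
stated with each test (2% for $C_1$, 10% for $\tau$, 15% for the resistivity
ratio).

## Known limitations

* The two effective cell constants of the well-plate electrodes (the
  resistive path implies $K_\mathrm{cell} \approx 114$ m⁻¹ at 30 S/m, while
  $C_1 = 2$ pF implies $\approx 345$ m⁻¹ through the capacitive relation)
  are not reconciled; resistances are reported from whichever cell constant
  the caller supplies.
* No alternative circuit elements (constant-phase, Warburg, inductive) are
  offered; for this measurement class the single-capacitance RC model is
  the accepted description and more elaborate models add parameters without
  physical interpretability.
* Only the logistic growth law is implemented (no Gompertz/Baranyi, no
  death-phase term), and the two-region geometry is the only spatial
  structure — there is no spatially resolved biofilm model.
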