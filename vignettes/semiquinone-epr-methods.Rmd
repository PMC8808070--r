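---
title: "Semiquinone thermodynamics, CW-EPR powder simulation and kinetics: models and numerical choices"
author: "EPRedox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiquinone thermodynamics, CW-EPR powder simulation and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EPRedox)
```

This vignette is the package's own account of the science it
implements: the models, their assumptions, the tunable parameters, and
the numerical decisions taken where the problem left the design open.

## The two-step semiquinone titration model

A quinone bound at a protein site is reduced in two one-electron
steps, Q → SQ → QH₂, with midpoint potentials $E_1$ (Q/SQ) and $E_2$
(SQ/QH₂). Assuming Nernstian equilibrium with the mediated ambient
potential $E$, the semiquinone fraction is

$$f(E) = \frac{1}{1 + e^{\alpha(E - E_1)} + e^{\alpha(E_2 - E)}},
\qquad \alpha = F/RT,$$

a bell peaking at $E_m = (E_1+E_2)/2$ with maximum
$1/(1 + 2e^{(\alpha/2)(E_2-E_1)})$. The EPR amplitude of the radical,
measured point by point during a reductive titration, is proportional
to $f$. Assumptions worth making explicit:

* both steps are $n = 1$; no provision is made for cooperative
  two-electron behaviour;
* the sample equilibrates with the mediator cocktail at each point
  (mediator kinetics and electrode drift are not modelled);
* EPR amplitude is proportional to semiquinone concentration, which
  holds when spectra are taken under non-saturating power at one
  temperature with an unchanging lineshape.

Derived quantities follow directly: the stability constant
$K_S = e^{\alpha(E_1 - E_2)}$ of the comproportionation equilibrium
Q + QH₂ ⇌ 2 SQ; the occupancy $R_\mathrm{occ}$ as measured semiquinone
per enzyme over the theoretical maximum; and the binding-constant
ratio $K_{QH_2}/K_Q = e^{2\alpha\,\Delta E_m}$ implied by a shift of
the bound couple's $E_m$ from the free pool's. A $-60$ mV/pH slope of
$E_m$ (from `phSlope`) indicates a 2H⁺/2e⁻ overall reaction; the
package fits only this linear dependence and makes no attempt at
pKa-resolved Pourbaix modelling.

### Fitting

`fitTitration` performs Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, parameter tolerance $10^{-10}$) of
$A = s\,f(E; E_1, E_2)$ with a *free* scale $s$, even though
experimental curves are usually normalized: the true maximum generally
falls between sampled potentials, so dividing by the noisy observed
maximum would bias the fit. Because the model is symmetric under
exchanging $(E_1, E_2)$, the fitted pair is relabeled so
$E_1 \ge E_2$ (quinone/semiquinone couple at the higher potential).
The likelihood is occasionally flat in the gap $E_1 - E_2$; the
optimizer is therefore started from 8 deterministic initial guesses
(two center estimates from the observed maximum and the
amplitude-weighted mean potential, crossed with gap guesses of 20, 60,
120 and 240 mV) and the best residual sum of squares wins. Standard
errors come from the fit covariance. Non-convergence of every start is
flagged (`converged = FALSE`), never returned silently.

Temperature defaults to 298.15 K (room-temperature titrations) and is
carried per curve; potentials are mV vs SHE at the interface and
converted to volts internally before exponentiation. Reported
potentials are rounded half-away-from-zero to 1 mV (so −155.5 prints
as −156); full precision is kept internally.

## CW-EPR powder simulation

`simulatePowder` treats each species as an effective S = ½ spin with a
rhombic g-tensor. For an orientation with direction cosines $l_i$ of
the field in the tensor frame, the resonance field follows
$h\nu = g_\mathrm{eff}\mu_B B$ with
$g_\mathrm{eff}^2 = \sum_i g_i^2 l_i^2$. Hyperfine structure is
first-order: line offsets are $M\,A_\mathrm{eff}/(g_\mathrm{eff}
\mu_B/h)$ for total nuclear projection $M$, with
$A_\mathrm{eff}^2 = \sum_i w_i A_i^2$ projected using the same
direction-cosine weights $w_i = g_i^2 l_i^2 / g_\mathrm{eff}^2$ as the
g-value, and multinomial weights for equivalent nuclei. First-order
perturbation is adequate here because second-order shifts
($\sim A^2/B$) are far below the linewidths for couplings ≤ 15 MHz at
9 GHz and above; this is also why the Mn²⁺ marker positions are
computed to first order (the ~0.2 mT second-order correction at X band
is documented but off).

Two Gaussian linewidth regimes are supported, matching how organic
radicals/Mo(V) versus iron–sulfur centers are usually simulated:

* **H-strain** — unresolved hyperfine couplings; per-axis FWHM in mT,
  independent of field and frequency;
* **g-strain** — distributed g-values; per-axis FWHM as dimensionless
  $\Delta g_i$, converted at each orientation via
  $|\partial B/\partial g| = B/g$, so the field-domain width grows
  linearly with microwave frequency.

Per-orientation widths interpolate the three principal widths in
quadrature with the weights $w_i$, treating the three strain
components as uncorrelated. The first harmonic is the analytic
derivative of the Gaussian kernel; field modulation is treated as
metadata only (no pseudo-modulation broadening), because reported
simulation linewidths are model parameters rather than
modulation-limited observables. Echo-detected field-swept spectra are
represented as absorption-mode output (`harmonic = 0`) with relaxation
weighting ignored.

### Orientation grid

The powder average uses a deterministic grid over one octant (valid
for collinear tensor axes): polar rings every 2° by default, each ring
carrying its exact annulus area as weight and split into azimuthal
cells in proportion to $\sin\theta$ so cells subtend nearly equal
solid angles. Rings uniform in $\theta$ (rather than in $\cos\theta$)
matter near the $g_3$ pole, where equal-area rings would leave
multi-degree gaps and visible ripple at high frequency. The spacing is
exposed (`gridSpacing`); the tests pin the default grid against an
independent brute-force loop over a dense uniform grid with
$\sin\theta$ quadrature weights.

For narrow lines spread over a wide field range (high frequency), any
orientation grid produces ripple once the resonance-field step between
neighbouring orientations exceeds the linewidth. The packaged Mo(V)
fixture therefore carries per-spectrum effective widths, as is
standard practice in multifrequency work: a 0.30 mT H-strain FWHM at X
band — comparable to the 0.47 mT proton splitting, so the doublet is
partially resolved, as observed — and a broader 1.4 mT effective width
at W band, where unresolved strain contributions dominate and the
proton structure is washed out. All fixture widths other than the
semiquinone's are synthetic placeholders (the published per-axis width
table is not reproduced here); the semiquinone's X-band width
(0.9712 mT FWHM) was calibrated once so that the simulated
peak-to-peak linewidth equals the observed 0.88 mT.

### Feature reading

`apparentG` reads a derivative spectrum the way a spectroscopist
labels it: the first local maximum and the last local minimum
exceeding 5% of the spectrum amplitude (the outer $g_1$/$g_3$
features), and the steepest zero crossing between them (the central
$g_2$ feature). The 5% threshold ignores grid-level wiggles without
hiding genuine shoulders; it is an argument, not a constant.

## Spectrum post-processing

Double integration uses cumulative trapezoids; after the first
integration the recovered absorption is forced to return to zero at
the end of the integration window by subtracting a linear tilt — a
standard guard against residual derivative baseline, applied always
since it is a no-op on clean data. Spin quantitation divides windowed
double integrals and multiplies by the spin count assigned to the
reference center; windows are closed intervals in mT and must isolate
one species each (overlap must be removed experimentally, e.g. by
relaxation filtering — no spectral deconvolution is attempted). No
Boltzmann or g-dependent (Aasa–Vänngård) intensity corrections are
applied, which is exact only when comparing signals within one
spectrum at one temperature — a documented limitation.

Field calibration matches measured Mn²⁺ line positions to their
first-order predictions (nearest-neighbour matching, which is
unambiguous for discrepancies below half the 8.71 mT spacing). The
`offset` slot stores the mean discrepancy, measured − predicted; the
correction applied to a field axis by `applyFieldCalibration` is its
negative. This sign convention is stated explicitly because both
directions appear in the wild.

## Kinetics

`fitMM` fits $v = V_\mathrm{max} S/(K_M + S)$ by Levenberg–Marquardt
with non-negativity bounds, weighted $1/\sigma^2$ when rate errors are
given. The turnover number uses the molar mass of the full complex
(kcat = Vmax × MW/60), i.e. a per-complex turnover matching how
heterodimer constants are usually tabulated; users wanting per-site
numbers substitute a per-site mass. `phOptimum` interpolates a
parabola through the top three points of a pH profile, returns
boundary optima with a warning, and breaks ties toward the lower pH.

## The synthetic-data generators

The generators define the conditions under which the pipeline is
exercised:

* `genTitration`: 30 points equally spaced over
  $[E_2 - 120, E_1 + 120]$ mV, additive Gaussian amplitude noise of
  0.02 on a unit scale (about 4% of the bell maximum) — defaults
  matching a room-temperature titration of a strongly stabilized
  menasemiquinone at pH 7.5 with couple potentials (−136, −175) mV.
* `genSpectrum`: forward simulation plus white noise and an additive
  field-axis offset emulating magnet miscalibration.
* `genKinetics`: 12 substrate points log-spaced from 0.1 to 30 × Km
  (mirroring assays spanning 0.5–150 mM around a ~5 mM Km), with 5%
  proportional rate noise; negative draws are clipped at zero and
  counted.

Noise models are additive for amplitudes and spectra, proportional
for rates — the respective measurement regimes. Each generator seeds
its own stream and restores the caller's RNG state, and embeds the
generating truth in the returned object.

What these emulations deliberately omit: mediator-equilibration
artifacts and electrode drift in titrations; cavity background,
saturation and passage effects in spectra; substrate depletion and
product inhibition in rates. Passing recovery tests therefore
demonstrate the estimators' correctness and precision under the
assumed noise structure, not robustness to these systematic effects in
real data.

A note on attainable precision: with 0.02 amplitude noise on a unit
scale and 30 points, the maximum-likelihood titration fit has a
standard error of roughly 3 mV on each couple potential (the
multi-start optimizer reaches the global optimum on every tested seed,
so this is the information limit of the data, not an optimization
artifact). Individual replicates therefore scatter beyond 3 mV at the
expected Gaussian rate even though the mean bias is well below 1 mV;
the test suite asserts both the bias bound and — deliberately, with an
explanatory comment — the stricter per-replicate bound.

## Problem sizes

The test and acceptance runs use 30-point titrations and 12-point
kinetics tables with 200 replicates each, 1024–8192-point field axes,
and the default 2° orientation grid against a 3° brute-force
reference — sizes chosen so the whole suite exercises every stage in
well under the attention span of a coffee break while keeping every
statistical assertion comfortably powered.

## Known limitations

No S > ½ or zero-field splitting, no exchange-coupled multi-spin
systems, no relaxation or temperature dependence, no least-squares
fitting of spectra (forward simulation and feature extraction only),
no vendor binary spectrum formats (comment-headered ASCII with an
import hook at `readSpectrum`), no inhibition kinetics, and no
modelling of the experimental quantities that depend on real material
(e.g. absolute spin counts per milligram of enzyme).
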