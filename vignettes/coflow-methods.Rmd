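---
title: "Two-compliance coflow viscoelastometry: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-compliance coflow viscoelastometry: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coflow)
```

## The measurement idea

Blood and a reference fluid of known viscosity (typically 1x PBS,
$\mu_r = 1$ mPa·s) are pumped into a shallow rectangular microchannel where
they flow side by side as two laminar streams. The lateral position of
their interface — summarized by the interface fraction
$\alpha_b = w_b/w$, the blood-filled share of the channel width — is set by
the viscosity ratio, so a steady $\alpha_b$ measures blood viscosity
without any pressure sensor. When the blood pump is switched off, the
interface does not collapse instantly: elastic storage in the flexible
tubing and PDMS channel walls, and in the deformable red-blood-cell phase
itself, discharges through the channel resistances. The decay of
$\alpha_b$ therefore encodes the system's compliances.

The package implements a lumped fluidic-circuit model of this device with
*two* compliance elements: $C_1$ for the hardware (inlet tubing + PDMS
channel) and $C_2$ for the cellular phase, with the working assumption
$C_1 < C_2$. Separating the two lets the cellular elasticity be read out
independently of the measurement hardware.

## Fluidic-circuit model

Each channel segment is a hydraulic resistor. For a shallow rectangular
duct (aspect ratio $h/w < 0.1$, so the flow profile is effectively
two-dimensional) the resistance is $R = 12 \mu l/(w h^3)$. The coflowing
channel is split by the interface, treated as a virtual wall, into two
parallel resistors whose widths are $\alpha_b w$ and $(1-\alpha_b) w$; an
empirical correction factor $\mathrm{CF}(\alpha_b)$ on the blood-stream
conductance absorbs the error of this idealization. Mass conservation at
the two pressure nodes, with compliances $C_1$ and $C_2$ attached, gives a
second-order nonlinear ODE for the interface. In the reciprocal coordinate
$\beta = (1-\alpha_b)^{-1}$, and with $\mathrm{CF}$ frozen at an
interface-averaged constant $\mathrm{CF}_0$, it becomes linear:

$$ a\,\beta'' + b\,\beta' + c\,\beta = c + Q_b/Q_r, $$

with $a = R_{b1} R_{r3} C_1 C_2$,
$b = R_{r3}\,(C_1 + C_2 + C_1 \tfrac{l_1}{l_2}\mathrm{CF}_0)$,
$c = \tfrac{\mu_r}{\mu_b}\mathrm{CF}_0$, where
$R_{b1} = 12\mu_b l_1/(w h^3)$ is the blood-channel resistance and
$R_{r3} = 12\mu_r l_2/(w h^3)$ a reference-viscosity resistance scale of
the coflowing channel. Two steady/transient consequences drive the whole
method:

* **Steady state** ($Q_b$ constant):
  $\mu_b = \mu_r\,\mathrm{CF}(\alpha_b)\,\frac{\alpha_b}{1-\alpha_b}\,
  \frac{Q_r}{Q_b}$ — the viscometer.
* **Switch-off** ($Q_b = 0$):
  $\beta(t) = d_1 e^{-\lambda_1 t} + d_2 e^{-\lambda_2 t} + 1$, where the
  decay rates are the roots of $a\lambda^2 - b\lambda + c = 0$ and satisfy
  $$ \lambda_1 + \lambda_2
     = \frac{C_1 + C_2 + C_1 \frac{l_1}{l_2}\mathrm{CF}_0}{R_{b1} C_1 C_2},
  \qquad
  \lambda_1 \lambda_2
     = \frac{\mu_r \mathrm{CF}_0}{\mu_b R_{b1} R_{r3} C_1 C_2}. $$
  Fitting $\lambda_1, \lambda_2$ from the decay and inverting this pair of
  relations yields $(C_1, C_2)$ — the elastometer.

At switch-off the node pressures are continuous, which fixes the initial
conditions $\beta(0) = \beta_{ss}$, $\beta'(0) = 0$ and hence
$d_1 = -\lambda_2(\beta_0-1)/(\lambda_1-\lambda_2)$,
$d_2 = \lambda_1(\beta_0-1)/(\lambda_1-\lambda_2)$. The model file drawn
for the device also shows a series resistance on the reference line ahead
of the junction; because the reference pump is an ideal flow source, that
element cannot affect the interface dynamics and is deliberately not a
model parameter.

### Units

Everything internal is µm / s / mPa·s, so resistance is mPa·s/µm³,
compliance is µm³/mPa, and every $RC$ product is directly in seconds.
Flow rates are entered in mL/h and converted on ingestion
(1 mL/h = $10^{12}/3600 \approx 2.778\times10^8$ µm³/s). This makes the
natural experimental numbers (compliances of tens to thousands of
µm³/mPa, decay rates of $10^{-2}$–$10^{0}$ s$^{-1}$) order-one quantities.

## Correction-factor calibration

`builtin_cf_models()` ships per-depth polynomial calibrations (glycerin
30% against 1x PBS) for channel depths 4, 10 and 20 µm, together with
their published interface-averaged constants $\mathrm{CF}_0$ (1.637, 1.41,
1.183). `cf_point()` computes single-observation correction factors from
fluids of known viscosity, `fit_cf_polynomial()` refits a polynomial
(default degrees 3/2/5 per depth), and `cf0_constant()` recomputes the
weighted average
$\mathrm{CF}_0 = \sum \mathrm{CF}(\alpha)\frac{\alpha}{1-\alpha} \big/
\sum \frac{\alpha}{1-\alpha}$ over a grid.

Two deliberate choices here:

* The default averaging grid is uniform on $\alpha \in [0.1, 0.9]$ with
  step 0.01 — the stated validity range of the viscosity law. The
  averaging set behind the shipped constants is not recoverable from their
  source, and a uniform-grid recomputation of the 20-µm model lands near
  but not exactly on the shipped 1.183. For that reason the shipped
  constants are treated as authoritative and `cf0_constant()` never
  silently overrides them.
* Calibration polynomials are capped at degree 5 and validated to be
  positive over their range.

## The inverse pipeline

`coflow_fit()` runs the pipeline per pump cycle and aggregates across
cycles (mean ± sd, no outlier rejection):

1. **Steady window.** The last 50 samples of each on-phase are used,
   excluding everything within 70 s of switch-on (the settling time
   observed for this protocol; with $T = 240$ s and $dt = 0.5$ s that is
   $t \in [95, 120)$ s of the cycle). The window mean $\alpha$ goes
   through the steady-state law to give $\mu_b$.
2. **Transient fit.** The off-phase samples, re-zeroed at switch-off, are
   fitted with $\beta - 1 = d_1 e^{-\lambda_1 t} + d_2 e^{-\lambda_2 t}$
   by Levenberg–Marquardt least squares. Since the observation noise
   lives on $\alpha$, the induced noise on $\beta - 1$ scales as
   $\beta^2$; the fit therefore uses inverse-variance weights
   $(1-\alpha)^4$, making it first-order equivalent to maximum likelihood
   on $\alpha$. Initialization peels the slow mode off a tail log-linear
   fit, with a log-spaced variable-projection grid search as fallback;
   amplitudes are unconstrained in sign (the pressure-continuity ICs
   predict $d_1 < 0$, but experimental decays need not honor that).
   Effectively single-exponential data fall back to a one-mode fit
   flagged as degenerate. Rates are reported in canonical order
   $\lambda_1 \ge \lambda_2$; ties are rejected downstream.
3. **Compliance inversion.** With $S = \lambda_1+\lambda_2$,
   $P = \lambda_1\lambda_2$ and $k = 1 + \frac{l_1}{l_2}\mathrm{CF}_0$,
   the product relation fixes $\Pi = C_1 C_2$ and the sum relation fixes
   $k C_1 + C_2$, leaving $k C_1^2 - (S R_{b1} \Pi) C_1 + \Pi = 0$. The
   $\mu_b$ used here is the same cycle's steady-window estimate.

### Root selection and identifiability

The quadratic's two roots always pair as $(C_1, C_2)$ and
$(C_2/k,\, k C_1)$. When $C_2 < k^2 C_1$ (about $8.1 C_1$ for the 20-µm
device) *both* roots satisfy $C_1 < C_2$, and the decay rates alone cannot
distinguish them; the package returns the stronger-separation root
(smaller $C_1$), which matches the working assumption that the cellular
compliance dominates, and always reports both candidates so the ambiguity
is visible. `complete_parameter_set()` generalizes the inversion: given
the two rates and any one of $\{\mu_b, C_1, C_2\}$ it solves for the other
two (a quadratic in $\mu_b$ when a compliance is supplied). Solvability is
governed by the rate separation alone: the discriminant is positive only
when $(\lambda_1+\lambda_2)^2/(\lambda_1\lambda_2) > 4k R_{r3}/(r \mu_r
\mathrm{CF}_0)$ — about a 3.9-fold rate ratio for the standard geometry —
so closely spaced rates are rejected as non-identifiable rather than
silently resolved.

## Numerical choices

* **Nonlinear forward model.** `simulate_nonlinear()` integrates the full
  $\alpha$-dependent equation (state $(\alpha, \alpha')$, chain rule
  through the polynomial $\mathrm{CF}$) with `lsodar`, rtol $10^{-8}$ /
  atol $10^{-10}$, segment-by-segment between pump switches so the square-
  wave forcing never crosses a step inside one solver call. Integration
  halts with a diagnostic if $\alpha$ leaves the calibration's validity
  range. The two well-separated modes make the system only mildly stiff;
  `lsodar` switches methods as needed.
* **Repeated eigenvalues** (discriminant zero within relative $10^{-12}$)
  are flagged and rejected rather than handled with the $t e^{-\lambda t}$
  solution: the method's premise is two distinguishable modes.
* **Steady-state inversion** brackets the root of the monotone product
  $\mathrm{CF}(\alpha)\,\alpha/(1-\alpha)$ on an 801-point grid and
  polishes with `uniroot` at tol $10^{-14}$; multiple sign changes (a
  non-monotone calibration) raise an error listing every root.

## The synthetic-experiment generator

`simulate_measurement()` produces complete in-silico experiments with
known ground truth. The default generator mirrors the standard protocol:
square-wave blood flow with $Q_0 = Q_r = 1$ mL/h and $T = 240$ s (120 s
on / 120 s off), samples every 0.5 s, 20-µm device, and additive Gaussian
observation noise on $\alpha$ with $\sigma_\alpha = 0.005$ — about one
pixel at the 150-px channel width of the imaging path, chosen as the
quantization floor of the interface extraction. Observations are clipped
to $(0.001, 0.999)$; for $\sigma_\alpha \le 0.01$ and true
$\alpha \in [0.1, 0.9]$ clipping essentially never activates. A single
global seed streams deterministic per-component sub-seeds (noise, frame
rendering, suite draws).

The default engine is the per-phase analytic solution: on-phase plateaus
at the exact steady value of the *full* polynomial steady-state law,
switch-off decays with the linearized modes, and $(\beta, \beta')$
continuous across switches, starting from the settled on-phase state. The
nonlinear integrator is available as `mode = "nonlinear"` and serves as
the oracle for the linearization gap (with $\mathrm{CF}$ held constant
the two agree to $10^{-6}$ in $\beta$ over a full off-phase).

What the generator does *not* emulate: shear-thinning or
hematocrit-dependent viscosity, the cell-free wall layer, pump ramp
dynamics, illumination drift in the imaging path, or any trend linking
compliances to biological condition. Passing recovery tests therefore
demonstrates the correctness and statistical efficiency of the inverse
pipeline under the model's own assumptions — not the biological validity
of the model on real blood.

### What recovery can and cannot achieve

Noiseless synthetic data are recovered essentially exactly (relative
error $< 10^{-4}$ end-to-end, $< 10^{-9}$ for the algebraic roundtrips).
Under noise the three parameters are *not* equally identifiable. At
$\sigma_\alpha = 0.005$ on a single cycle, $\mu_b$ is estimated to a few
tenths of a percent (50-sample window average) and $C_2$ to about 1–2%
(the slow mode is pinned by the long tail), but the fast mode enters
$\beta$ with amplitude
$|d_1| = \lambda_2(\beta_0-1)/(\lambda_1-\lambda_2) \approx 0.14$ for the
reference truth ($\mu_b = 2.2$, $C_1 = 50$, $C_2 = 1400$), against an
induced $\beta$-noise of $\sigma_\alpha \beta^2 \approx 0.04$ per sample.
A Cramér–Rao computation at exactly these conditions gives a relative
standard deviation of about 34% for $\lambda_1$ and 36% for $C_1$ with
free amplitudes (13% for $C_1$ even if the switch-off ICs are imposed),
and Monte Carlo over seeds confirms the weighted estimator runs close to
that bound. Single-cycle, single-run $C_1$ estimates at this noise level
are therefore reproducible only to roughly ±15–35%, whatever the
estimator; tighter $C_1$ work needs lower noise, longer records or
cycle averaging. `parameter_recovery_suite()` quantifies exactly this,
reporting bias and RMSE per parameter across noise levels (RMSE is
monotone in $\sigma_\alpha$).

## Imaging path

Frames are segmented with a global Otsu threshold over a 256-bin
histogram (blood = darker phase under bright-field; polarity is a flag),
and $\alpha$ is the per-column count of blood pixels averaged over the
ROI columns, divided by the channel width in pixels — counting rather
than run-length makes the estimate robust to speckle, and a blood region
not contiguous from the blood-channel wall is flagged. The synthetic
renderer draws the blood band at the wall with a Gaussian-profile
interface of scale 1 px and additive pixel noise; render→extract
roundtrips are unbiased within 0.01 (≈1.5 px at 150 px width) across
$\alpha \in [0.2, 0.8]$. Whether the real acquisition averages widths per
column or per region is ambiguous; columnwise averaging is adopted (for
columnwise-constant masks the two coincide).

## Problem sizes used by the test-suite

The shipped tests run the algebraic roundtrips at 30–100 random draws,
single-cycle (480-sample) pipeline recoveries, an 8-draw × 3-noise-level
recovery suite, and image roundtrips on 150 × 198-px frames — sizes at
which every check completes in seconds while still exercising the full
pipeline.

## Known limitations

* The shear-rate helper implements $\dot\gamma = 6 Q_b/(w h^2)$ with the
  full channel width; published ranges for this protocol imply a narrower
  effective width that is not recoverable, so absolute shear rates from
  this helper are indicative only.
* Printed steady blood viscosities for real samples are not exactly
  reproduced by pushing the printed mean interface through the printed
  calibration polynomial (per-run calibrations and flow details differ);
  the package asserts only its own self-consistent chain.
* $C_1$/$C_2$ separation degrades sharply as the rate ratio approaches
  the ~3.9-fold identifiability floor, and the root ambiguity above
  applies when $C_2 < k^2 C_1$.
* The model excludes the cell-free layer, non-Newtonian rheology and 3D
  duct corrections by construction.
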