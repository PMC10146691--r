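# coflow

Blood viscoelasticity from coflowing microchannel interface dynamics.

## What it does

In a coflow viscometer, blood and a reference fluid of known viscosity run
side by side through a shallow rectangular microchannel; the interface
fraction α_b (blood-filled share of the channel width) encodes the
viscosity ratio. This package implements a *two-compliance* extension of
that method for people building or analyzing such devices: the microfluidic
system is modeled as a lumped fluidic circuit in which C₁ captures the
elastic storage of the inlet tubing and PDMS channel and C₂ that of the
red-blood-cell phase (C₁ < C₂). In the reciprocal coordinate
β = (1 − α_b)⁻¹ the linearized circuit obeys

    a β″ + b β′ + c β = c + Q_b/Q_r,
    a = R_b1 R_r3 C₁ C₂,
    b = R_r3 (C₁ + C₂ + C₁ (l₁/l₂) CF₀),
    c = (µ_r/µ_b) CF₀,

so that under steady blood flow

    µ_b = µ_r · CF(α_b) · α_b/(1 − α_b) · Q_r/Q_b,

and after the blood pump switches off

    β(t) = d₁ e^(−λ₁ t) + d₂ e^(−λ₂ t) + 1,

with λ₁, λ₂ the roots of aλ² − bλ + c = 0. Fitting the two decay rates and
inverting their sum/product relations (given µ_b from the steady phase)
yields C₁ and C₂ — blood viscosity and *two* separate compliance
coefficients from a single on/off pump cycle, disentangling cellular
elasticity from the hardware.

The package covers the full workflow:

* **Forward model** — resistances, characteristic coefficients, decay
  rates, analytic transients, and stiff integration of the full nonlinear
  interface equation (`rect_resistance`, `eigenvalues_forward`,
  `analytic_beta`, `simulate_nonlinear`).
* **Calibration** — empirical correction-factor polynomials per channel
  depth with their interface-averaged constants CF₀ (`builtin_cf_models`,
  `cf_point`, `fit_cf_polynomial`, `cf0_constant`).
* **Inference** — `coflow_fit()` runs steady-window viscometry, weighted
  two-exponential transient fitting and the eigenvalue→compliance
  inversion per cycle, returning a classed fit object with `print`,
  `summary`, `coef`, `predict`, `residuals`, `plot` and `simulate`
  methods; `complete_parameter_set()` solves the eigenvalue relations
  given any one of µ_b, C₁, C₂.
* **Imaging** — Otsu segmentation of coflow frames and column-averaged
  interface extraction (`otsu_threshold`, `interface_fraction`,
  `series_from_stack`), plus a synthetic frame renderer.
* **Synthetic experiments** — seeded generators with known ground truth
  (`ground_truth`, `simulate_measurement`, `parameter_recovery_suite`).
* **CLI** — `inst/cli/coflow` with `simulate`, `extract`, `calibrate-cf`
  and `fit` subcommands composable through CSV/JSON contracts.

## Worked example

Simulate one 240 s on/off cycle of the standard 20 µm device (truth:
µ_b = 2.2 mPa·s, C₁ = 50, C₂ = 1400 µm³/mPa, observation noise
σ_α = 0.005) and run the inverse pipeline:

```r
library(coflow)
truth <- ground_truth(mu_b = 2.2, C1 = 50, C2 = 1400,
                      sigma_alpha = 0.005, seed = 7)
fit <- coflow_fit(simulate_measurement(truth))
summary(fit)
#> Two-compliance coflow viscoelastometry fit
#>   cycles analyzed: 1
#>   mu_b = 2.198 mPa.s
#>   C1   = 57.54 um^3/mPa (tubing + channel)
#>   C2   = 1397 um^3/mPa (RBC elasticity)
#>   steady alpha = 0.6768 (sd 0.0064, n = 50)
#>
#> Per-cycle estimates:
#>  cycle alpha_mean     mu_b   lambda1    lambda2       C1       C2 converged
#>      1  0.6768045 2.197713 0.1835335 0.01280741 57.54074 1397.288      TRUE
```

µ_b comes back to 0.1% and C₂ to 0.2%; C₁ lands within ~15%, which is the
expected single-cycle precision at this noise level — the fast mode enters
β with amplitude |d₁| ≈ 0.14 against a noise floor of σ_α β² ≈ 0.04, and
the Cramér–Rao bound for C₁ under these exact conditions is ~13–36%
relative (see the methods vignette). Averaging cycles or lowering the
noise tightens it.

The eigenvalue relations can also be solved directly. Supplying the
printed larger compliance of the reference demonstration together with its
fitted decay rates recovers the smaller one:

```r
complete_parameter_set(0.1945, 0.0127, c(C2 = 1398.2),
                       channel_geometry(h = 20), mu_r = 1, CF0 = 1.183)
#>      mu_b        C1        C2
#>    2.2220   53.5323 1398.2000
```

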