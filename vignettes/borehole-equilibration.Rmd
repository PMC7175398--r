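---
title: "Modeling stem-borehole equilibration of xylem water isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stem-borehole equilibration of xylem water isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boreq)
```

## The measurement idea

Drill a hole through a tree stem, push a slow stream of air through it, and
analyze the water vapor coming out with a cavity ring-down spectrometer. If
the air moves slowly enough, vapor evaporating from the wetted borehole wall
saturates the air stream and brings its isotopic composition (δ¹⁸O, δ²H)
into equilibrium with the liquid xylem water around the hole. The outlet
vapor then reports the composition of the tree's source water continuously,
without destructive sampling. `boreq` implements the physical model of this
equilibration, the sensitivity sweeps used to map out when it works, the
processing chain that turns raw spectrometer cycles into liquid-equivalent
xylem values, and a seeded synthetic-campaign generator so the whole
pipeline is testable without instrument data.

## The segment model

Air enters the borehole (radius $r$, wetted length $l$, volume
$V = \pi r^2 l$, wall area $A = 2\pi r l$) with vapor mole fraction $w_i$
and isotope ratio $R_i$, and exchanges with the wall by molecular diffusion
while being advected along the axis. Because laminar flow is the opposite of
well-mixed, the borehole is discretized into $N$ equal segments along the
flow path; the outflow of one segment is the inflow of the next. Per
segment, the steady-state vapor balance gives the conductance-weighted mean

$$w_o^{ss} = \frac{u_o w_i + \tilde A \tfrac{D}{r} w_{sat}}
                  {u_o + \tilde A \tfrac{D}{r}},$$

where $u_o$ is the molar carrier flow, $\tilde A \tfrac{D}{r} = 2\pi l_{seg}
D / V_{1mol}$ the molar wall conductance (independent of the radius), $D$
the vapor diffusivity and $w_{sat} = e_{sat}(T_s)/p$ the saturation mole
fraction at stem temperature. The heavy-isotopologue balance carries the
same structure with the wall term divided by the kinetic fractionation
$\alpha_k$ (diffusion passes heavy molecules more slowly) and the surface
vapor at $R_s$:

$$0 = u_o (w_i R_i - w_o R_o)
    + \tilde A \tfrac{D}{r} \tfrac{1}{\alpha_k} (w_{sat} R_s - w_o R_o).$$

Dividing (rather than multiplying) the wall exchange by $\alpha_k$ is the
only reading consistent with the closed-form steady states and with the
property that the isotopic time constant $t_{x,x}$ collapses onto the vapor
time constant $t_w$ exactly when $\alpha_k = 1$.

### Wall closures

What fixes $R_s$, the composition of the vapor right at the evaporating
film, is the genuinely open physical question, so three closures are
provided (`surface_model()`):

* **`xylem_equilibrium`** — the film is pure xylem water and
  $R_s = R_x/\alpha^+$: the liquid pool is so much larger than the vapor
  flux that evaporation never enriches it.
* **`craig_gordon`** — the film has enriched until it exports the supply
  composition, the classical evaporating-surface steady state:
  $(w_{sat} R_s - w_o R_o)/\alpha_k = R_x (w_{sat} - w_o)$.
* **`mixed`** — a fraction $f$ of the film is fresh xylem water and
  $1-f$ sits at the Craig–Gordon state:
  $R_s = f R_x/\alpha^+ + (1-f) R_C/\alpha^+$. The Craig–Gordon surface is
  solved jointly with $R_o$ as a closed-form linear fixed point per
  segment, so $f = 1$ and $f = 0$ reproduce the limiting closures
  bit-for-bit.

The "mixing per time step" picture behind the mixed closure is interpreted
here as this steady-state mixture: the package solves only chained
steady states (the per-segment exponential relaxation kernels are exposed as
`segment_vapor_step()` for transient single-segment reasoning, but no
transient whole-borehole driver is provided).

### Time-constant diagnostics

Three time scales summarize whether equilibration can succeed:
$t_d = r^2/(4D)$ for radial diffusion, $t_u = V/u_{carrier}$ for
throughflow, and $t_w = \tilde V/(u_o + \tilde A D/r)$ for the approach of
the vapor mole fraction to its steady state. Equilibration is plausible when
$t_u \gg t_d$. Two flow conventions are exposed because the published
worked numbers mix them: the parabolic laminar profile argument takes the
effective carrier flow as twice the observed mean flow
(`"centerline_double"`, the default, needed for the published turnover
times), while the tabulated $t_w$ values require the plain `"mean"`
convention. `turnover_time()` and `vapor_time_constant()` accept either via
`airflow()`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `radius_m` | — | m | borehole radius; enters $t_d$ and $V$, cancels in the wall conductance |
| `wetted_length_m` | stem diameter − 0.02 | m | fittings screwed ~1 cm into each side block exchange; the 2 cm subtraction is required to reproduce the published turnover times and is configurable (set `fitting_penetration_m = 0` to identify the exchanging length with the stem diameter, as the model idealization does) |
| `Q_m3_s` | — | m³/s | volumetric flow; mL/min via `ml_min_to_m3_s()` |
| `alpha_k` | 1.0285 (¹⁸O), 1.0251 (²H) | — | classical molecular-diffusivity ratios; no published value exists for this system, so they are configurable and `alpha_k = 1` disables kinetic fractionation |
| `N` | 500 | — | segment count; see numerical choices |
| `f` | — | — | mixed-closure fraction; `find_min_mixing_fraction()` reports the smallest $f$ whose outlet matches the equilibrium closure within a stated per-mil tolerance (default 0.5‰, reported alongside the result because the choice is a convention) |

Physical laws: Majoube (1971) polynomials for $\alpha^+(T)$
(liquid-over-vapor convention), Murray (1967) for $e_{sat}(T)$,
$D = D_0 (p_0/p)(T/T_0)^{1.88}$ with $D_0 = 2.12\times10^{-5}$ m²/s, and
ideal-gas molar volume. Isotope ratios are stored normalized to VSMOW
(δ = 0 ↦ 1); absolute abundances cancel because every model equation is
homogeneous in $R$.

## Numerical choices

* **Segment count.** The chain converges first-order in $1/N$.
  `simulate_borehole()` defaults to $N = 500$ and, unless disabled,
  re-runs at $N/2$ and warns when the outlet deltas differ by more than
  0.01‰. For the two limiting closures the error at $N = 400$ is below
  10⁻³‰; the mixed closure converges more slowly in δ²H (about 0.013‰
  between $N = 400$ and $800$ for a strong ²H gradient), which is why the
  guard exists and why sweeps needing tight δ²H agreement should raise `N`.
* **Degenerate inputs.** Super-saturated air ($w > w_{sat}$) is an error,
  not a model state: condensation is excluded from the model's scope, as it
  is from field records. A Craig–Gordon wall at exact saturation has no net
  evaporation; the surface degenerates smoothly to equilibrium with the
  borehole vapor ($R_s = R_o$) and the segment passes composition through
  unchanged.
* **Mass balance.** Each segment's evaporation is accounted exactly, so
  inflow + total evaporation equals outflow to floating-point precision;
  the simulation object carries the residual.
* **Bisection.** `find_min_mixing_fraction()` brackets the tolerance
  crossing to $10^{-4}$ in $f$; the deviation-vs-$f$ curve is treated as
  monotone, which holds exactly for $\alpha_k = 1$ and to well within the
  bracketing resolution otherwise (with $\alpha_k > 1$ the outlet can
  overshoot the $f = 1$ limit by ~0.1‰ near $f = 1$, a kinetic effect worth
  knowing about when interpreting mixing-fraction sweeps).

## The processing chain

`process_campaign()` mirrors standard practice for this instrument class:
cycles are separated on flush gaps; means and standard deviations are taken
over the trailing 3 min of each 15 min cycle (wall-clock, not sample
count, so irregular cadence is fine); borehole relative humidity is
reconstructed as $h = w/w_{sat}(T_{stem})$; raw deltas are calibrated with a
per-species ordinary-least-squares line against headspace standards whose
targets are their known liquid values converted to vapor via $\alpha^+$ at
the recorded headspace temperature; calibrated vapor deltas are converted to
liquid equivalents at stem temperature; and QC flags mark cycles with
window SD above 0.5‰ (δ¹⁸O) or 1.5‰ (δ²H) on raw values, or $h < 0.8$.
Boundaries are inclusive-pass, flags are applied before calibration (they
describe instrument stability, not accuracy), and flagged records are kept
with their flags rather than dropped, so input and output counts always
reconcile. Because the calibration is affine, calibrating per sample and
then averaging equals averaging and then calibrating; the pipeline exploits
this and calibrates cycle means.

`breakthrough_midpoint()` dates a tracer front as the first
linearly-interpolated crossing of the midpoint between two user-chosen
plateau means, warning when the plateau separation does not exceed the
combined plateau noise. `velocity_from_lag()` and `predicted_arrival()`
close the loop against sap-flow expectations.

## What the synthetic generator emulates — and what it does not

`generate_campaign()` produces a campaign whose liquid xylem composition
follows a plateau–transition–plateau breakthrough (exponential relaxation by
default, midpoint at $t_{switch} + \tau\ln 2$; logistic optional, midpoint
at $t_{switch}$), sampled every 3 h in 15-min cycles at 5 s cadence, with a
diurnal stem temperature (16.8 ± 1.3 °C by default), borehole air at
$h = 0.98$, independent Gaussian per-sample noise, and two artifact types:
cycles whose humidity never approached saturation ($h$ forced below 0.8)
and noise-burst cycles (SD inflated 3×, beyond both QC limits). The default
per-sample noise SDs are 0.25‰ (δ¹⁸O) and 0.75‰ (δ²H) — half the QC
exclusion limits. Field experience with this setup excludes only a few
percent of cycles on the SD rule; if typical noise sat at the limits,
roughly half of all clean cycles would be excluded, so "noise at the QC
scale" is implemented as comparable to, but inside, the limits. The truth
file carries everything needed to score the pipeline (plateaus, midpoint
time, artifact table, calibration coefficients) without regeneration, and
identical seed and configuration reproduce the campaign exactly.

Real campaigns differ in ways the generator deliberately ignores:
autocorrelated instrument drift, memory effects between channels,
condensation Rayleigh distillation during dry-downs, and organic spectral
interference. Passing the recovery tests therefore demonstrates that the
pipeline's arithmetic and bookkeeping are right, not that these field
pathologies are handled; they are excluded or flagged, not corrected.

## Problem sizes used by the test suite

The suite runs entirely on generated data: simulations at $N \le 800$,
property checks over 1000 random parameter draws, and Monte-Carlo pipeline
recovery over 100 seeded 5-day campaigns (about 40 cycles × 180 samples
each) — sizes chosen so the full suite completes in well under a minute
while leaving the statistical assertions (binomial CIs, 2·SE coverage,
arrival within two sampling intervals) properly powered.

## Known limitations

* Only chained steady states are solved; the full 2-D advection–diffusion
  problem in the borehole cross-section is out of scope, as are transient
  whole-borehole responses to time-varying inflow.
* Condensation anywhere in the path is detected (errors, warnings, QC
  flags) but never modeled.
* The published worked values themselves are not fully mutually consistent:
  the tabulated $t_d = 0.24$ s is not reproducible from $r^2/(4D)$ at the
  stated borehole temperature, and the quoted equilibrium vapor value for
  −15‰ liquid at 10 °C (−25.7‰) differs from the Majoube arithmetic
  (−25.43‰) by ~0.3‰. The package reproduces what follows from the stated
  formulas at the stated conditions and treats those two numbers as
  approximate.
* Kinetic fractionation defaults are generic diffusivity ratios; nothing in
  the borehole data constrains them, and sub-saturated outlets are
  sensitive to the choice.
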