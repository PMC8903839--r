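---
title: "Models and numerical methods for cartilage self-heating studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods for cartilage self-heating studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrotherm)
```

## The scientific problem

Articular cartilage dissipates a substantial fraction of the mechanical
energy it receives during locomotion. That lost energy becomes heat:
intra-articular knee temperature climbs from about 32 °C at rest toward
38 °C during an hour of jogging. Cells in cartilage therefore never
experience cyclic loading and temperature rise separately — they are two
faces of the same physical event. `chondrotherm` packages the computational
machinery needed to study this coupling in vitro: a biomimetic temperature
law and its heater-control realization, a dissipative poro-viscoelastic
hydrogel model with the well-scale heat transfer it drives, the mechanical
characterization procedures that parameterize the hydrogel, and the
ΔΔCt gene-expression statistics used to read out the cellular response.
Every wet-lab input is replaced by a seeded synthetic generator so the full
pipeline runs, and is tested, without laboratory data.

## The intra-articular temperature model

The temperature evolution during activity is phenomenological saturation:

$$T(t) = A + B\,(1 - e^{-ct}),$$

with baseline $A = 31.62$ °C, asymptotic rise $B = 7.99$ °C and rate
constant $c = 0.023$. The printed unit of $c$ is ambiguous: per second it
implies a 43 s time constant, incompatible with the two-hour evolution of
the in vivo trace and with ~38 °C reached only after an hour. Per minute it
reproduces both, so `per_minute` is the default and `per_second` remains
selectable. Under the default the model predicts a rise of
`r round(temperature_rise(temperature_model(), 7200), 2)` °C after two
hours (~7 °C); fully saturated the rise is 7.99 °C, so either unit reading
lands near the reported "around 7 °C".

Fitting uses nonlinear least squares with eight log-spaced multistarts in
$c$ (10⁻⁴–1 s⁻¹): the likelihood is nearly flat in $c$ when the series is
short or noisy, and single-start Gauss–Newton stalls in that valley. The
quoted goodness of fit $R$ is the Pearson correlation between fitted and
observed series. A constant series leaves $B$ and $c$ jointly
unidentifiable; the fit is then flagged degenerate rather than silently
returning an arbitrary $(B, c)$ pair. The baseline $A$ is *not*
constrained to the 32 °C resting temperature — the unconstrained fit
recovers it from data.

The heater realizes the smooth model as piecewise-linear ramps (default 6
segments over 90 min starting at 32.5 °C, ending near 39 °C). Six segments
keep the schedule within 0.2 °C of the smooth model over two hours;
refinement tests confirm the interpolation error vanishes as segments are
added.

## Constitutive model of the dissipative hydrogel

The solid skeleton is linear viscoelastic with a Prony shear kernel

$$G(t) = G_\infty + \sum_{i=1}^{3} G_i\,e^{-t/\tau_i},$$

with branches (200, 58, 215) kPa at (0.42, 5.82, 1600) s. Two modeling
choices the source tables do not settle:

* **Shear vs uniaxial branches.** The branch moduli are treated as *shear*
  relaxation moduli acting on the deviatoric response, with the volumetric
  response elastic from $(E_{eq}, \nu)$ — standard poro-viscoelastic
  practice. This is a flagged assumption.
* **Long-term modulus.** $G_\infty = E_{eq} / (2(1+\nu)) \approx 203$ kPa
  is *derived* from the equilibrium modulus so that the drained long-time
  response reproduces $E_{eq} = 500$ kPa exactly.

Stress histories are computed with the exact-exponential
recursive-convolution scheme (one internal variable per branch, O(N));
the update is exact for piecewise-linear strain, so a step-strain history
reproduces $\varepsilon_0 G(t)$ to machine precision. Energy dissipation
under steady sinusoidal strain has the closed form
$\pi \varepsilon_0^2 G''(\omega)$, which serves as the analytic oracle for
the loop-area measurements (agreement within 0.03 % at 1 Hz with 200
samples/cycle).

Parameters absent from the source table get water/pHEMA defaults:
$\mu_f = 10^{-3}$ Pa·s, $\rho_{fluid} = 1000$ kg/m³,
$\rho_{solid} = 1150$ kg/m³, and a zero storage coefficient
(incompressible constituents). Each is a config default, overridable in
the plain-text material file.

## Mechanical characterization

*Hysteresis area.* Energy dissipated per cycle is the shoelace area of the
closed stress–strain polygon, conventionally at cycle 100 (after
preconditioning). Loops must close: the endpoint strain gap may not exceed
1 % of the strain amplitude — or one sampling step, whichever is larger,
since a cyclically rotated but perfectly periodic loop legitimately has its
seam at a steep part of the waveform. Dissipative power is area ×
frequency: the 9000 J/m³ loop at 1 Hz gives the 9000 W/m³ volumetric
source used in the well simulations.

*Equilibrium modulus.* From a sequential stress-relaxation record, the
"relaxed" stress of each step is the mean of the final 10 % of its hold
(`tail_fraction = 0.1`; the source protocol does not quantify
"equilibrium"), and $E_{eq}$ is the least-squares slope of relaxed stress
vs strain over the 10–20 % window.

*Loading protocol.* "10 % pre-strain, 10 % amplitude at 1 Hz" is read as
the compression-only raised cosine
$\varepsilon(t) = 0.10 + 0.05(1 - \cos 2\pi f t)$, peaking at 20 % — a
piston cannot pull. The centered reading
$\varepsilon = 0.10 + 0.10 \sin 2\pi f t$ is selectable
(`waveform = "sin"`), and is the default for the loop *generator*, whose
contract is defined on the centered waveform.

## The coupled well simulation

An axisymmetric meridian rectangle holds the 4 mm × 2.2 mm hydrogel sample
at the bottom of a cylindrical well (radius 8 mm, height derived from the
~2 ml medium volume). Structured P1 triangles, grid lines snapped to the
sample boundary.

**Mechanics (sample only).** Quasi-static Biot poroelasticity with the
Prony deviatoric solid: $\nabla\cdot(\sigma' - \alpha p I) = 0$,
$\alpha\,\partial_t(\nabla\cdot u) + \nabla\cdot v_f = 0$,
$v_f = -(k/\mu_f)\nabla p$. Equal-order P1 displacement/pressure with
Brezzi–Pitkäranta stabilization $\beta = h_e^2 / (4(K_b + \tfrac43 G_0))$
applied to the pressure increment (vanishing at steady state), backward
Euler, and one sparse LU factorization reused across steps. The
saddle-point matrix spans ~13 orders of magnitude between blocks, so it is
symmetrically equilibrated before factorization. Boundary conditions:
symmetry axis, frictionless base, rigid impermeable piston prescribing the
axial strain, lateral surface traction-free and drained ($p = 0$) against
the bathing medium. Verification: drained slow-ramp compression recovers
$E_{eq}$ exactly; a laterally confined column under step traction matches
the Terzaghi consolidation series to 0.16 % L2 at Fourier time 0.2.

**Heat transfer (sample + medium).** $(\rho C)_{eff}\,\partial_t T +
\rho_f C_f\, v_f\cdot\nabla T = \nabla\cdot(K_{eff}\nabla T) + Q$ with
porosity-weighted mixture properties in the sample, pure conduction in the
medium, backward Euler, and the 9000 W/m³ source uniform over the sample.
The culture medium is modeled as a *conductive, non-flowing* fluid — no
buoyancy or stirring; this is a stated fidelity limit, and it is
conservative for the headline question (any medium convection would only
flatten gradients further).

**Multirate coupling.** The 1 Hz mechanical problem is solved for 5 cycles
to its periodic regime; the heat equation then runs the 90-min horizon with
the constant dissipative source and the cycle-averaged Darcy velocity
field. Resolving all 5400 mechanical cycles would change nothing: in the
periodic regime the per-cycle dissipated energy is constant, and the
cycle-averaged Darcy speeds (~10⁻⁴ m/s peak at the drained edge) produce a
thermal Péclet far below 1.

**Bookkeeping invariants.** The discrete energy ledger (source input =
stored change + boundary outflux, recovered from the unconstrained residual
at Dirichlet rows) closes to ~10⁻¹¹ without advection and within 1 % with
it; the fluid mass ledger closes to ~10⁻¹¹. With the isothermal 32 °C wall
the maximum culture-medium change over 90 min is ≈ 0.02 °C — comfortably
below the 0.5 °C bound — and mesh refinement (0.8/0.4/0.2 mm) changes it by
1.2 % at the last step with an observed order ≈ 1.8. The adiabatic variant
rises monotonically (≈ 0.65 °C/90 min in the medium), strictly exceeding
the isothermal case, as the worst-case bound.

## Heater plant and PID control

The heater–well path is a first-order-plus-dead-time surrogate
($\tau\,\dot T = K P(t - L) - (T - T_{amb})$) with *fabricated* defaults —
gain 0.08 °C/W, τ = 240 s, L = 8 s, P_max = 100 W — clearly labeled as
such; no hardware identification data exists. Ambient defaults to 32 °C (a
pre-warmed chamber): with an 8 °C full-power span the 32.5→39 °C protocol
is otherwise infeasible. Tuning uses the open-loop (reaction-curve)
Ziegler–Nichols rules, $K_p = 1.2\tau/(KL)$, $T_i = 2L$, $T_d = L/2$,
chosen because the plant model is known; which variant the original
controller used is unstated. The positional PID uses a first-order filtered
derivative ($N = 10$) and conditional-integration anti-windup with the
actuator clamped to $[0, P_{max}]$. On the default plant the ZN loop tracks
the 2-h biomimetic schedule with max error ≈ 0.01 °C after a 5-min
settling window.

## ΔΔCt analysis and group comparison

Per sample, $\Delta C_t = C_t^{target} - C_t^{ref}$;
$\Delta\Delta C_t$ subtracts the control-group mean $\Delta C_t$ per gene;
the per-replicate fold is $2^{-\Delta\Delta C_t}$. The summary fold is the
*geometric* mean ($2^{-\overline{\Delta\Delta C_t}}$), so the control
group's summary fold is exactly 1 — per-replicate folds then mean is the
default ordering, since the original averaging order is unstated. Group
comparisons are two-sided Welch t-tests on log2 folds (equivalently on
$\Delta\Delta C_t$): folds are multiplicative, and the log scale restores
symmetry and approximate normality. No multiple-testing correction by
default (per-gene p < 0.05 is the reported convention); Benjamini–Hochberg
is available behind a flag. Primer efficiencies are stored and validated
(80–115 % band) but not used for efficiency correction by default — the
comparative method assumes ~100 % efficiency; an efficiency-corrected mode
would be the natural extension.

One calibration caveat, verified numerically: with only 5 replicates per
group the Welch–Satterthwaite test is intrinsically conservative — its true
type-I error at nominal α = 0.05 is ≈ 0.0435 (100 000-rep direct
simulation), and the packaged pipeline reproduces exactly that level. A
2000-simulation estimate therefore scatters around 0.0435, not 0.050, and
individual seed sets can land marginally below 0.04.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of (parameters, seed): additive Gaussian
noise throughout (the simplest model consistent with replicate scatter —
the sources are silent on error structure), with `sd = 0` reproducing the
analytic model to machine precision. Defaults follow the stated
experimental world: temperature sampled at 10 s, mechanics at 200
samples/cycle at 1 Hz, Ct tables balanced with ≥ 2 replicates (replicate
count is a parameter because the source reports varying n = 3–6). The
generators do **not** emulate: qPCR amplification chemistry (Ct values are
drawn directly), loop-shape drift during preconditioning (loops are
stationary apart from the viscoelastic transient), temperature-dependent
material properties, or inter-sample biological variability beyond the
Gaussian replicate scatter. A green test therefore establishes correctness
of the *computational* chain under the stated statistical model, not the
biological variability structure of a real experiment.

## Numerical choices and limitations

* Linear solver: sparse LU (Matrix), tolerance-free direct solves; the
  physics is linear so no Newton iteration exists anywhere.
* Time steps: heat 10 s (backward Euler, unconditionally stable; the
  0.1 mm-mesh slab benchmark uses τ/400); mechanics 1/100 of the loading
  period (contract: ≤ 1/50).
* Degenerate inputs are rejected with messages (non-positive durations,
  open loops with the measured gap, fewer than 2 usable relaxation steps,
  missing reference-gene Ct excluded with a warning).
* The well's exact boundary conditions in the original COMSOL model are in
  supplement figures unavailable as text; the defaults here (drained
  lateral sample surface, impermeable piston/base, all outer well walls at
  the bath temperature) were chosen as the physically plain reading, and
  the < 0.5 °C conclusion is robust to them — the medium change sits a
  factor ~25 below the bound, and doubling/halving the source moves it
  proportionally.
* No 3D effects, no piston contact mechanics, no buoyant medium flow, no
  large-strain or strain-dependent stiffness, no fatigue/damage of the
  hydrogel, no in-knee simulation (the intra-articular temperature is
  handled by the phenomenological model only).
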