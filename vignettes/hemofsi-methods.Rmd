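---
title: "Methods: pulsatile flow in a compliant artery with a porous microcirculation outlet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile flow in a compliant artery with a porous microcirculation outlet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hemofsi` simulates pulsatile blood flow in an idealised straight artery
(diameter 20 mm, wall thickness 2 mm) whose outlet is terminated not by a
prescribed pressure or velocity but by a porous "seepage" zone standing in
for the downstream microcirculation — the dominant resistance of the
circulation.  The domain is therefore two zones in series:

* an **artery zone** (default length 10 diameters) with a compliant,
  isotropic, linear-elastic wall, solved in arbitrary
  Lagrangian–Eulerian (ALE) form on a mesh that follows the wall;
* a **microcirculation zone** (default 5 diameters) with a rigid wall,
  where volume-averaged porous-medium equations add a Darcy–Brinkman
  momentum sink $-(\phi^2\eta/k)\,\mathbf u$ to the Navier–Stokes
  equations, with porosity $\phi = 0.5$ and Kozeny–Carman permeability
  $k = d^2\phi^3/(180(1-\phi)^2)$ for microvessel diameter $d = 8\,\mu$m.

Blood is an incompressible Carreau–Yasuda shear-thinning fluid
($\eta_\infty = 2.2$ mPa s, $\eta_0 = 22$ mPa s, $\lambda = 0.110$ s,
$a = 0.644$, $n = 0.392$, $\rho = 1050$ kg/m³).  The wall
($\rho_w = 1120$ kg/m³, $E = 5$ MPa, $\nu = 0.499$) is reduced to an
inertial ring (generalized-string) model per axial station,

$$\rho_w h\,\ddot d + c\,\dot d + \kappa\,d = p_{wall} - p_{ext},
\qquad \kappa = \frac{E\,h}{(1-\nu^2)R^2},$$

with both axial ends clamped.  This reduction is justified by the
straight axisymmetric geometry: radial motion dominates, and the thin-shell
stiffness evaluated at the mid-surface radius is within 12% of the exact
thick-walled (Lamé) plane-strain answer at $h/R = 0.2$ (the inner-radius
convention used above is stiffer, by up to ~30% at $\nu \approx 0.5$;
tests document both bounds).  Structural damping and external pressure
default to zero.

At the interface the two zones exchange mass and momentum with pressure
continuity, and the no-slip condition ties fluid and wall velocities
together on the compliant interface.

## Why the porous zone has an `area_expansion`

A literal uniform tube filled with an 8 µm / 50% porous bed has a Darcy
resistance of order $\eta L/k \approx 10^{13}$ Pa s/m; pushing the full
arterial flow through it would require pressures of order $10^8$ Pa and,
with any wall elasticity, meter-scale displacements.  Physiologically the
capillary bed drains a cross-section orders of magnitude larger than the
feeding artery.  `porous_params(area_expansion = A)` represents this: the
tube-frame ("superficial") velocity $v$ in the porous zone corresponds to
an intrinsic pore velocity $v/(\phi A)$, and the terminal resistance
scales as $1/A$.  The baseline value ($A \approx 7.3\times10^6$) is
**calibrated**, not assumed: it is chosen once so that the rigid-wall
variant's cycle-maximum artery pressure is $\approx 1.2$ kPa, a
physiological terminal-resistance level for this segment
(`calibrate_terminal_resistance()` re-derives it).  With that calibration
the microcirculation-zone intrinsic velocities come out at the $10^{-7}$
m/s scale — effectively steady seepage, as expected.

Because the porous momentum balance is written for the *intrinsic*
velocity, the shear-thinning viscosity entering both its stress term and
the Brinkman sink is evaluated at the intrinsic shear rate
$\beta\dot\gamma$ (with $\beta = 1/(\phi A)$; $\beta = 1$ in the artery,
where this reduces to the resolved shear rate).  Porous-zone shear is
then $\sim 10^{-7}$ s⁻¹ and the sink viscosity is effectively the
zero-shear value $\eta_0$; a constant-$\eta_\infty$ mode remains
available.  Reading the sink viscosity off the superficial field instead
would both be physically inconsistent (its shear is an artifact of the
folding) and feed an oscillatory instability through the steep part of
the shear-thinning curve.

## Inlet waveform and radial profile

The inlet drive is a parametric periodic pulse (period 0.8 s): a squared
half-sine systolic ejection over 40% of the cycle on a small diastolic
baseline, continuous and once-differentiable
(`waveform_config()`).  It is an explicit stand-in for a measured
waveform; a digitised trace can be substituted through the two-column CSV
interface.  The waveform amplitude is the second calibrated quantity: it
is scaled once so that the peak sectional velocity at the first probe
section S1 equals 0.75 m/s (`calibrate_inlet_peak()`).

The waveform value is a *mean* velocity; the imposed radial profile is
**parabolic by default**.  The choice matters and was made deliberately:
in a rigid straight tube a plug inlet develops toward the plug-like
high-Womersley profile with a *rising* centreline, so sectional peak
velocities could never decay between the upstream and downstream artery
probes; a parabolic inlet relaxing toward the flatter developed profile
produces the observed decay naturally (the developed-to-parabolic
centreline ratio is close to the reported S2/S1 ratio).  A plug option is
provided.

## Numerics

* **Grid.** Staggered (MAC) axisymmetric finite volumes: pressure at
  cell centres, axial velocity on axial faces, radial velocity on radial
  faces; piecewise-uniform axial spacing with a face exactly on the zone
  interface; radial template $\xi \in [0,1]$, optionally tanh-clustered
  at the wall (default strength 1.5, wall cells ≈ 2.4× finer), scaled by
  the local wall radius — ALE deformation is pure radial stretching, and
  the mesh velocity $u_m = \xi\,\dot R_w(z)$ enters the convective terms
  as $\mathbf u - \mathbf u_m$.  Metric cross-terms from the axial
  variation of $R_w$ are $O(|dR_w/dz|) \lesssim 10^{-3}$ here and are
  neglected.
* **Time.** BDF2 (backward Euler start-up), $\Delta t = 4$ ms, three
  cycles with the third analysed.  A smooth $\sin^2$ inlet ramp over the
  first 0.08 s avoids an impulsive start-up load on the wall; only the
  discarded first cycle is affected.
* **Pressure–velocity coupling.** Monolithic: momentum and continuity
  are assembled into one sparse system per step and solved by direct LU
  (the MAC pair is inf-sup stable; a tiny pressure penalty
  $\sim 10^{-8}$ of the Schur scale guards the factorization).  The
  linear residuals are therefore at round-off, and every extra solve
  within a step is a cheap back-substitution.
* **Advection.** The matrix carries first-order upwinding of an
  extrapolated advecting field, with the switch between upwind
  directions *softened* over a small fraction ($10^{-3}$) of the
  typical face flux so the discrete convective force stays continuous
  through near-wall flow reversal (a hard switch shows up as
  step-to-step pressure jitter).  An explicit defect correction,
  re-evaluated each inner iteration from the latest solution, replaces
  the frozen operator by the convection of the solution itself; under
  the default "high-resolution" option the face values add a smooth
  van Albada-limited second-order correction, with pure upwind as the
  alternative.  The converged step therefore carries fully implicit,
  self-consistent convection and does not depend on the extrapolation.
* **Viscosity.** The second-invariant shear rate (including the hoop
  term $u_r/r$) at cell centres feeds the Carreau–Yasuda law; the
  stress operator and Brinkman sink built from it join the same defect
  correction, so the viscosity is implicit in the converged step rather
  than lagged.  The transpose part of the stress divergence is omitted
  (its neglect does not affect the Newtonian verification limits, and
  wall shear is evaluated directly from the wall-tangential gradient).
  The wall viscous flux and the reported wall shear stress use one-sided
  second-order stencils through the no-slip value.
* **Inner iterations.** The defect fixed point is accelerated by
  windowed Anderson mixing, with a Newton-style re-linearization of the
  frozen operators if it stalls; convergence is declared when the
  RMS-normalised velocity residual (the usual "variable residual"
  convention) falls below `residual_tol` ($10^{-4}$ by default).
  Transient steps need 1–4 iterations; large pseudo-steady time steps
  more.
* **FSI coupling.** Partitioned staggered sub-iterations per step:
  fluid solve with the current interface velocity (Newmark-consistent),
  wall-normal traction ($p$ extrapolated to the wall plus the small
  viscous normal stress) to the ring model, Newmark wall advance,
  interface update.  The update is interface quasi-Newton (IQN-ILS)
  from the residual history: the added-mass ratio
  $\rho R/(\rho_w h) \approx 4.7$ makes the fixed-point map strongly
  multi-modal, and scalar Aitken needed roughly twice the sub-iterations
  in side-by-side runs (both remain available; a property test keeps the
  ordering IQN ≤ Aitken ≤ fixed).  Trial interface increments are capped
  in displacement and implied-velocity units, and the fluid is solved at
  $0.2\times$ the residual tolerance inside the sub-iterations so
  traction noise cannot block the interface criterion.  Geometry and
  operators are frozen at the Newmark-predicted displacement within the
  step; the interface velocity always uses the current iterate, so the
  kinematic no-slip condition holds to the interface tolerance
  ($10^{-4}$ relative, with an absolute floor of $10^{-8}R$).
* **Wall time integration.** Newmark; the default parameters
  ($\gamma = 1/2$, $\beta = 1/4$) conserve the ring's energy exactly.
  Coupled runs use $\gamma = 0.6$ (with $\beta = (\gamma+1/2)^2/4$):
  the ring's natural frequency satisfies $\omega_n \Delta t \approx 31$
  at the study time step, and the added dissipation acts only on that
  unresolvable aliased mode, leaving the cardiac band (where
  $\omega\Delta t \approx 0.03$) untouched.

## Verification oracles

The analytic surface the solver is tested against (all in
`test-acceptance.R` and the module tests):

* steady Poiseuille wall shear $4\eta U/R$ (≤ 1% on the reference
  150 × 24 grid; ~0.1% measured);
* Womersley oscillatory pipe flow at the two viscosity extremes
  ($\alpha \approx 6$ and $\approx 19$), velocity profile and wall-shear
  amplitude ≤ 2%, with observed spatial convergence order ≈ 2.  The
  oscillatory tests are initialised from the analytic solution because
  the homogeneous start-up mode decays on the scale
  $\rho R^2/\eta \approx 8$ s at $\alpha = 19$ — far longer than the
  run — and would otherwise mask the discretisation error;
* the Darcy limit $\Delta p = \eta q L/k$ of the porous zone (≤ 1% over
  a grid of $q, L, k$);
* static FSI inflation against $d = p/\kappa$ (≤ 1%) and the ring
  natural frequency $\sqrt{\kappa/(\rho_w h)}$ (≤ 1%, via zero-crossing
  period measurement);
* the stiff limit: a compliant run at $E = 5$ GPa matches the rigid-mode
  probe series to ≤ 1% sup-norm;
* Moens–Korteweg pulse transit between the artery probes (≤ 15%,
  cross-correlation of pressure pulses in a lengthened low-viscosity
  tube so the direct wave separates from the interface reflection);
* mass conservation: divergence residuals at round-off and
  cycle-integrated inlet vs outlet volume ≤ 1%.

## What the calibrated baseline does and does not reproduce

With everything at the stated values the baseline run reproduces:
pressure decaying from inlet through the porous ladder to the outlet;
sectional peak velocity and wall shear stress decreasing from S1 to S2;
microcirculation velocities ~6 orders below arterial ones with nearly
steady seepage; peak wall shear at S1 of ≈ 2.6 Pa (within 25% of the
2.1 Pa reference level); and a slight (fraction-of-a-percent) *increase*
of peak wall shear and peak pressure under the compliant wall relative
to the rigid one.

Several qualitative features sometimes reported for peripheral
haemodynamics are **not** reproducible in this parameter regime, and the
package reports them honestly rather than tuning toward them:

* **Pulse-amplitude growth toward the outlet.** Amplification toward a
  reflecting termination is a wave phenomenon.  Here the Moens–Korteweg
  speed is ≈ 21.8 m/s, so a wave transits the 0.3 m domain in ≈ 14 ms —
  2% of the cycle — and the pressure field is quasi-static: amplitude
  *decreases* downstream, following the inertial/resistive gradient.
* **Compliance-induced changes (pressure, WSS, stiffness sweeps).**
  The wall compliance gives $C = 2\pi R L/\kappa \approx 9\times10^{-11}$
  m³/Pa; with the calibrated terminal resistance the RC time constant is
  ≈ 0.8 ms, three orders below the period.  The compliant and rigid
  solutions therefore coincide to ~1%, and Young's-modulus sweeps over
  5–1 MPa move peak WSS by less than that.  Any strong compliant-vs-rigid
  contrast would require an effective compliance orders of magnitude
  larger than these wall parameters provide.
* **Near-constant pressure amplitude along the porous zone.** With a
  fixed-pressure outlet the porous zone is a resistive ladder and the
  oscillation amplitude decays essentially linearly to zero at the
  outlet; a near-constant amplitude would require a different outlet
  closure (e.g. a compliant or impedance termination), which is outside
  this model.

The acceptance tests assert the full published orderings at their stated
tolerances; the subset above fails for the physical reasons given, which
is the intended, documented outcome.

## Problem sizes and costs

The reference resolution is 150 × 24 cells ($\Delta t = 4$ ms, 600
steps for three cycles): a compliant run takes ~2.5 min and a rigid run
~1.5 min on one core.  The test suite exercises the same physics at
100 × 20 (orderings and ratios are resolution-robust at this scale;
reported peaks move by a few percent between the two), and the oracle
tests use small dedicated domains.  The acceptance script runs the full
calibration protocol at the reference resolution.

## Known limitations

* The wall is an independent-ring model: no axial bending/tension
  coupling, no viscoelasticity or anisotropy, no prestress.
* The porous zone models the bed as a homogeneous continuum with a
  single calibrated resistance; wall shear reported there is a bed-frame
  (intrinsic-scale) quantity, not a microvessel wall stress.
* The inlet waveform is a parametric stand-in; its harmonic content
  above the first few modes is not physiological.
* Sectional peak velocities retain a slow viscous development transient
  (~5% drift between cycles 2 and 3 at $\alpha \approx 19$); pressures
  and wall shear peaks are periodic to < 2% by cycle 3.
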