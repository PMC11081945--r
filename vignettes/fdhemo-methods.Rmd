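---
title: "Models and numerics behind fdhemo"
author: "fdhemo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics behind fdhemo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

A braided flow diverter works by covering the neck of an intracranial
aneurysm with a fine wire mesh: the higher the metal coverage rate (MCR) at
the neck, the more the device decouples the sac from the parent-artery flow.
Because a braid reshapes itself with the vessel it is deployed in, the *size
discrepancy* between device and artery changes the local MCR and pore
density — a 4.0 mm device is "oversized" in a 3.0 mm artery (low coverage)
and "undersized" in a 4.5 mm artery (high coverage, with axial compaction).
`fdhemo` provides a desk-scale, fully deterministic pipeline to quantify how
that sizing choice changes intra-aneurysmal hemodynamics: idealized geometry,
ideal braid kinematics, a homogenized neck screen, a 2D pulsatile
incompressible-flow solver, and reduction-rate reporting.

The pipeline deliberately reproduces *orderings and trends*, not the absolute
values of strut-resolved 3D CFD. Reference 3D computations of this experiment
use tens of millions of elements with 5 µm wire-scale meshing; a desk-scale
artifact cannot and should not pretend to reproduce those numbers. What it
can reproduce exactly is the reduction-rate arithmetic of the published
summary table, the closed-form physics its solver is validated against, and
the monotone relationship between coverage and flow diversion.

# Geometry: a 2D cross-section surrogate

`build_sidewall_model()` describes a sidewall saccular aneurysm as a circle
of radius $R$ (default 5.0 mm, a large aneurysm) whose chord of length $W$
(the neck, default 4.0 mm) lies on the upper wall of a straight 2D channel of
height $D$ (the parent artery, 3.0–4.5 mm here). The sac center sits
$\sqrt{R^2 - (W/2)^2}$ above the wall. Holding $W$ fixed across parent
diameters is the 2D analog of the reference experiment's constant neck area,
so stented scenarios differ only in the vessel and the deployed braid, never
in the neck. The neck width itself is not printed in the reference study;
4.0 mm makes the model a wide-necked large aneurysm consistent with its
renderings, and it is configurable.

`rasterize()` lays the model onto a uniform staggered (MAC) grid. The channel
wall snaps to the nearest grid line and the neck center to the nearest cell
edge, which makes the rasterized neck/sac *identical* across parent diameters
at fixed spacing — an invariant the tests assert. The rasterized sac area is
checked against the closed-form circular-segment area (within $2h \times$
perimeter), the fluid region is flood-fill checked for connectivity, and the
proximal/distal measurement planes default to 1.0 mm outside the neck ends
(the reference study does not locate them).

# Braid kinematics and calibration

An ideal two-family braid of $n$ wires (default 48) of diameter $d_w$
(default 30 µm) — vendor-typical values for a 4.0 mm device, flagged as
external assumptions — obeys wire inextensibility: the braid angle from the
axis satisfies $\sin\alpha = (D/D_0)\sin\alpha_0$ when the braid opens from
its nominal diameter $D_0$ to the vessel diameter $D$. The angle reaches 90°
at $D_{max} = D_0/\sin\alpha_0$; wider vessels cannot be apposed, which is
exactly why the 5.0 mm scenario is excluded from the study
(`max_free_diameter()` raises the over-expansion error).

Axial compaction during deployment is lumped into a single pitch-steepening
factor $\kappa \ge 1$: $\tan\alpha' = \kappa\tan\alpha$. Real compaction is
operator-dependent, so a mechanistic push model is out of scope; instead
$\kappa$ is *calibrated* per scenario (`calibrate_compaction()`) so the
deployed MCR matches the measured value — 25.5 / 29.4 / 37.2 / 48.0 % for the
3.0 / 3.5 / 4.0 / 4.5 mm scenarios. The nominal angle itself is calibrated
once (`calibrate_nominal_angle()`) so free deployment at $D_0$ reproduces the
matched-size MCR of 37.2 %, giving $\alpha_0 \approx 74.0°$ and
$D_{max} \approx 4.16$ mm.

Deployed quantities follow from the strut lattice: perpendicular spacing
$s_\perp = (2\pi D/n)\cos\alpha'$ per family, per-family coverage
$c = d_w/s_\perp$ (clamped at 1), $\mathrm{MCR} = 1-(1-c)^2$ treating the two
families as independent strip screens (exact for two families of parallel
strips, verified against the Monte-Carlo rasterization oracle `mcr_oracle()`
within 3 standard errors), and pore density $\sin(2\alpha')/s_\perp^2$.

Two modeling points deserve emphasis:

* **Apposition cap.** The 4.5 mm vessel exceeds $D_{max}$: the device cannot
  open that far. The pipeline then deploys the braid at a capped fraction
  (default 0.97) of $D_{max}$ — incomplete apposition — and lets the
  calibrated compaction supply the measured 48 % coverage. The cap value was
  chosen from the kinematics alone: it must leave the free-deployment MCR
  below the 48 % target so that calibration with $\kappa \ge 1$ is feasible,
  and 0.97 sits comfortably inside that window.
* **Non-monotone coverage at strong oversizing.** $s_\perp \propto
  D\sqrt{1-(D\sin\alpha_0/D_0)^2}$ peaks at $D_0/(\sqrt2\sin\alpha_0)
  \approx 2.94$ mm, so free-deployment MCR is *minimized* there and only
  increases monotonically with $D$ above it. The study's sizing range
  (3.0 mm up) lies entirely in the monotone branch, and the tests assert
  monotonicity on that range.

# The homogenized neck screen

Resolving 30 µm struts is the 3D reference regime; `fdhemo` replaces the
deployed braid with a thin permeable screen across the neck
(`screen_from_braid()`). An Ergun-type packed-bed correlation with the wire
diameter as grain scale gives the Darcy permeability
$k = d_w^2\varepsilon^3/(150(1-\varepsilon)^2)$ and inertial coefficient
$C = 3.5(1-\varepsilon)/(d_w\varepsilon^3)$, with porosity
$\varepsilon = 1-\mathrm{MCR}$ and the standard constants 150 and 3.5 exposed
in the interface because woven-screen correlations differ. The screen is two
wire diameters thick (two crossing layers). No correlation for this exact
situation exists in the reference study (it resolves struts); the choice is
acknowledged surrogate modeling, and the property that actually drives every
conclusion — resistance strictly increasing with MCR — is asserted by a
standalone 1D through-flow test (`screen_throughflow()`).

In the solver the screen enters as a Darcy–Forchheimer momentum sink
$-(\mu/k)\,u - (\rho C/2)\lvert u\rvert u$ applied on the faces the screen
plane crosses. Since the screen (0.06 mm) is thinner than a cell (0.2 mm),
those are exactly the through-flow (normal) faces on the neck line, with the
force scaled by thickness/cell-height. Loading the wall-parallel faces in the
adjacent rows as well was tried and rejected: at Ergun-scale resistances it
acts as an artificial porous plug *inside the parent artery*, visibly
throttling the channel flow, whereas a thin screen's in-plane shear coupling
is physically a surface-friction effect orders of magnitude below its
through-flow resistance. The sink law itself (`momentum_sink()`) remains an
isotropic vector law.

# Flow solver

`run_flow()` integrates the 2D incompressible Navier–Stokes equations with a
classical projection method on the staggered grid: explicit second-order
upwind advection (first-order fallback adjacent to boundaries), explicit
central diffusion, semi-implicit screen drag, a pressure Poisson solve, and a
velocity correction. Boundary conditions follow the reference setup: a
Womersley-type pulsatile velocity profile at the inlet, zero reference
pressure with zero-gradient velocity at the outlet, rigid no-slip walls.
"Systole" is defined as the instant of maximum inlet flux in the final cycle
(the reference study does not define the instant); "zero pressure" is taken
as gauge static pressure.

Details that matter numerically:

* **Wall ghosts.** Tangential velocities across a wall use a quadratic
  ghost through the no-slip interface, $u_g = (u_2 - 6u_1)/3$, which is exact
  for parabolic profiles — steady Poiseuille flow is then reproduced to
  solver tolerance and wall shear converges at second order. The linear
  mirror is kept for the upwind advection fallback and where only one fluid
  neighbor exists.
* **Time step.** dt is fixed per run: the smaller of the advective limit
  (CFL, default 0.4, on a design peak velocity of 1.3× the waveform's
  centerline peak) and 0.6 of the explicit diffusion limit $h^2/(4\nu)$,
  rounded down so an integer number of steps lands on every snapshot time.
  A CFL monitor aborts with a named error if the realized velocity ever
  approaches the stability boundary, and any non-finite field aborts
  immediately.
* **Screen stiffness.** At Ergun permeabilities the Darcy rate
  $\mu/(k\rho)$ is of order $10^5$–$10^6\,\mathrm{s^{-1}}$: explicit
  treatment is unconditionally unstable at any practical dt. The Darcy term
  is therefore implicit in the predictor *and* in the projection — the
  pressure Poisson operator carries face coefficients
  $\beta = 1/(1+\Delta t\,a_{Darcy})$ and the correction uses the same
  $\beta$, so the projected field is exactly divergence-free. The milder
  Forchheimer term is pointwise-implicit in the predictor only (frozen
  $\lvert u\rvert$). Because dt is constant, the variable-coefficient
  operator is assembled and Cholesky-factorized once per run (CHOLMOD via
  the Matrix package) and each step costs one triangular solve.
* **Initial state and cycles.** Runs start from the fully developed inlet
  profile replicated along the channel (divergence-free on this grid) and
  integrate three cardiac cycles, analyzing the last; the per-cycle
  periodicity residual (L2 difference of cycle-end states) is logged and
  decreases cycle over cycle in every configuration tested. Global mass
  balance over the final cycle closes to well below $10^{-3}$ because the
  projection enforces inlet flux = outlet flux at every step.
* **Determinism.** The solver contains no randomness; reruns are bitwise
  identical. The only seed in the package belongs to the braid's Monte-Carlo
  coverage oracle.

The inlet waveform (`ica_waveform()`) is a four-harmonic internal-carotid-like
pulse: period 1 s, mean 0.25 m/s, systolic peak exactly 2× the mean at
$t/T = 0.15$, no flow reversal. The reference study cites a measured carotid
waveform but does not print it, so this fixture is documented as such —
coefficients live in the configuration, and the constructor enforces
positivity and a physiological peak/mean ratio (1.2–3). Each harmonic of the
inlet profile uses the closed-form plane-channel Womersley solution
(cosh-based), normalized so the profile integrates exactly to the
instantaneous mean; the fundamental Womersley number at study scale is
$\alpha \approx 2.57$.

Validation is against closed forms, not against the 3D reference runs: the
steady channel reproduces plane Poiseuille flow (profile and wall shear well
within 1 % at $h = H/40$; in fact to solver tolerance), the single-harmonic
oscillatory channel matches the analytic Womersley solution within 2 %
relative L2 (observed convergence order ≈ 2 between the finer grids), and
`grid_convergence()` provides the refinement harness used for both.

# Hemodynamic metrics

All metrics live on the final cycle. In 2D the volumetric quantities become
per-unit-depth quantities; units below make that explicit.

* **Inflow rate** (mm²/s): integral over the neck faces of the positive
  (into-sac) normal velocity at systole. The positive part resolves the
  directional ambiguity of a plain "normal velocity component": in-flux and
  out-flux cancel otherwise.
* **Average velocity** (m/s): area-weighted mean speed over sac cells at
  systole (region and instant are interpretation choices; the reference
  study states neither).
* **Energy loss** (W/m³): total-pressure energy flux
  $\int u\,(p + \tfrac{\rho}{2}\lvert u\rvert^2)\,dy$ through the proximal
  plane minus the distal plane, normalized by the sac area (the 2D analog of
  a volume normalization; the normalizing volume is not stated in the
  reference, so `normalize = "domain"` is also available). Negative values
  are clamped to zero with a warning.
* **WSS / TAWSS / OSI**: signed tangential stress at each sac wall face by
  one-sided second-order differencing (exact for linear shear, verified in
  tests), magnitudes sac-averaged; TAWSS is the cycle mean of $\lvert\tau\rvert$;
  OSI is $\tfrac12(1 - \lvert\int\tau\,dt\rvert/\int\lvert\tau\rvert\,dt)$
  per face with 0/0 defined as 0. Steady shear gives OSI = 0 and a zero-mean
  sinusoid gives OSI = 0.5 exactly (trapezoidal integration over the closed
  cycle).
* **Reduction rate** (%): $100(\mathrm{baseline}-\mathrm{stented})/
  \mathrm{baseline}$, rounded to two decimals half-away-from-zero, matching
  table presentation. Recomputing the published table's rates from its
  printed (rounded) baseline/stented pairs reproduces five cells exactly;
  the remainder differ by one unit in the last digit because the published
  rates came from unrounded inputs — the package documents rather than
  "corrects" this.

# The study pipeline

`run_study()` executes the four scenarios end to end — geometry, braid
calibration (with the apposition cap where needed), screen, baseline and
stented runs, summaries, reduction rates — writing a table shaped like the
reference summary (CSV and JSON) plus per-scenario logs with solver
residuals, screen parameters and $\kappa$. A failing scenario is recorded and
the rest continue. `trend_check()` then asserts the two published findings in
ordering form: every reduction rate strictly increases with MCR, and the
matching→undersizing gain is smaller than the cumulative
oversizing→matching gain (the plateau).

Default problem sizes are the package's reference conditions: grid spacing
0.2 mm (matching the element size of the reference CFD away from the stent),
three cardiac cycles, 50 snapshots per cycle, vessel length
$\max(10D, 30\,\mathrm{mm})$. A full four-scenario study (eight transient
runs, grids up to roughly 225 × 71 cells and ≈ 37 000 time steps each) takes
a few minutes on one core.

# What passing tests do and do not show

The geometry and braid modules *are* the data generators for this study;
their defaults encode the study conditions (sac radius 5.0 mm, device 4.0 mm,
measured MCR targets). What the pipeline demonstrates on them transfers to
real deployments only in ordering terms:

* The screen overestimates absolute neck resistance (Ergun constants were
  fitted for packed beds, and a 2D chord sees no lateral bypass), so stented
  inflow reductions saturate near 100 %, higher than the 57–77 % of the
  strut-resolved 3D reference. The ordering across scenarios — the actual
  claim — is robust, because the calibrated screens are strictly ordered in
  resistance.
* Energy-loss reductions are positive and strictly ordered but small in
  magnitude: in 2D the ordinary channel dissipation between the measurement
  planes, present in baseline and stented runs alike, dilutes the
  sac-exchange contribution the metric targets.
* OSI in a stented sac can *rise* here: once the mean shear is driven to
  near zero, the residual oscillating shear is relatively more reversing.
  The reference study reports OSI reductions, but its WSS-family baselines
  are unprinted, so these remain trend-only quantities everywhere in this
  package; the only asserted OSI properties are its exact bounds and limits.
* Real deployments add wall curvature, vessel taper, operator-dependent
  compaction profiles, non-Newtonian rheology and wall compliance — all
  outside this model by design.

# Known limitations

2D cross-section surrogate (no out-of-plane flow, no helical jets); stair-step
sac wall (wall shear is first-order accurate on the staircase and is used
comparatively, not absolutely); homogenized isotropic screen with through-flow
resistance only; single lumped compaction parameter; fixed rigid walls;
Newtonian blood. These are deliberate: every conclusion the package makes is
an ordering statement that survives the surrogate, and every absolute number
it guarantees is either closed-form physics or published-table arithmetic.
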