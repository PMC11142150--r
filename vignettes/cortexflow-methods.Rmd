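---
title: "cortexflow: model, numerics and fitting methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortexflow: model, numerics and fitting methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexflow)
```

## The physical model and its assumptions

`cortexflow` treats the cytoskeleton-plus-organelle meshwork of a motile
cell as a one-dimensional active viscous fluid at steady state. Three
stresses balance at every point of the domain $x \in [0, L]$ (rear to
leading edge):

$$ f\,\frac{\partial M}{\partial x}
   + \mu\,\frac{\partial^2 v}{\partial x^2}
   - \xi(x)\,v = 0 , \qquad
   \left.\frac{\partial v}{\partial x}\right|_{0} =
   \left.\frac{\partial v}{\partial x}\right|_{L} = 0 . $$

* **Motor stress.** Motors of density $M(x) = M_0
  \exp(-((x-x_{CZ})/\sigma)^2)$, concentrated in a convergence zone of
  width $\sigma$ at $x_{CZ}$, exert contractile stress proportional to the
  *gradient* of their density: force only arises where motor activity
  varies in space. The force per motor $f$ and peak density $M_0$ enter
  every equation solely as the product $f M_0$, stored as a single
  `amplitude` field — the split is unidentifiable and never needed.
* **Viscous stress.** $F_{visc} = \mu v''$ with a single effective
  viscosity $\mu$. The fluid picture assumes observation times long
  compared with crosslinker turnover, so elastic (Maxwell) behaviour is
  outside scope by design.
* **Traction.** $T(x) = \xi(x) v(x)$: friction-like coupling to the
  substrate, with independent coefficients $\xi_L$ (lagging side,
  $x < x_{CZ}$) and $\xi_R$ (leading side). We report $T$ as the stress
  exerted *on the substrate*; its sign convention is ours to fix and is
  stated here once.
* **Boundary conditions.** Zero velocity gradient at both edges, the
  steady-state statement that polymerization forces and membrane tension
  balance at the margins so flow is uniform there.

Velocities are lab-frame, positive toward the leading edge. Because the
equation is linear in $v$ and homogeneous in $(\mu, \xi_L, \xi_R, f M_0)$,
a measured profile constrains only ratios; the ratio parameterization
(`cell_params_from_ratios()`) therefore sets $\xi_L := 1$ and works with
$\xi_R/\xi_L$, $F_{max}/\xi_L$ and $\mu/\xi_L$, which is also how fitted
values are reported. Velocity units are a carried-through label, never
converted: the preset label records that the source unit is not fully
resolved.

Two closed-form quantities organize everything. The motor stress peaks at
$x_c = x_{CZ} \pm \sigma/\sqrt 2$ with magnitude
$F_{max} = \sqrt 2 e^{-1/2} f M_0/\sigma \approx 0.86\, f M_0/\sigma$, and
the dimensionless

$$ \lambda = \frac{2\mu}{\sigma^2 \xi_L} = 2\left(\frac{\ell}{\sigma}\right)^2,
   \qquad \ell = \sqrt{\mu/\xi_L} $$

measures internal versus external dissipation. At $x_c$ the motor stress
splits as $|F_{visc}| = F_{max}\lambda/(1+\lambda)$ and $|T| =
F_{max}/(1+\lambda)$; the printed source for the traction estimate
duplicates the viscous right-hand side, which contradicts its own
small-$\lambda$ limit, so the implementation follows the text-consistent
form in which the two magnitudes sum to $F_{max}$. These estimates are
built on a three-point difference stencil with spacing $\sigma/\sqrt 2$;
comparisons between numerical and analytic stresses at $x_c$ therefore use
that defining stencil (at $\lambda \lesssim 1$ the fine-grid curvature and
the stencil genuinely differ, and it is the stencil the estimate speaks
about).

## Numerics

The solver (`solve_flow()`) uses a uniform grid (default `n_grid = 2001`),
centred second-order differences, and Neumann conditions imposed by ghost
points ($v_0 = v_2$, $v_{n+1} = v_{n-1}$), which preserves second-order
accuracy. The resulting tridiagonal system is strictly diagonally dominant
(every diagonal exceeds its neighbours by $\xi_i > 0$), so it is solved by
the Thomas algorithm without pivoting. The system is scaled by $\xi_L$
before assembly so that entries stay within a moderate dynamic range even
at the most extreme tabulated ratios ($\mu/\xi_L \sim 10^7$). Requesting
both adhesion coefficients zero is rejected at construction: a fully
detached cell has no steady state in this model.

Choices the continuous model does not dictate:

* the adhesion step at $x_{CZ}$ assigns the *right* value to the zone node
  (right-closed convention), with an optional logistic blend
  (`smooth_width`) whose midpoint sits at $x_{CZ}$;
* a grid is declared too coarse when $\sigma < 10\,\Delta x$ — a warning,
  not an error;
* `refine_check()` reports $\max|v_N - v_{2N}|/\max|v|$ at shared nodes;
  the scheme's $O(\Delta x^2)$ convergence shows as a roughly fourfold drop
  per doubling, and the default grid puts the report below $10^{-4}$ for
  the reference parameter sets;
* integrals in `flow_summary()` (centre-of-mass flow, net traction) use the
  trapezoid rule. For symmetric parameters both vanish to round-off — the
  model's statement that mechanically symmetric cells flow inward yet go
  nowhere. Which scalar to call "migration speed" (rear velocity, lagging
  plateau mean, or centre-of-mass flow) is interpretive, so the summary
  reports all of them.

## The fitting procedure

`fit_flow()` estimates $(x_{CZ}, \sigma, \xi_R/\xi_L, F_{max}/\xi_L,
\mu/\xi_L)$ from an observed profile by a staged procedure whose steps are
individually exported:

1. `locate_convergence_zone()`: $x_{CZ}$ at the maximum of the smoothed
   $|dv/dx|$ (ties broken by the midpoint of the tied plateau).
2. `estimate_sigma()`: $\sigma$ from the flanking extrema of the smoothed
   second derivative, using the $x_{CZ} \pm \sigma/\sqrt 2$ mapping.
3. `fit_adhesion_ratio()`: a monotone root search on
   $\log_{10}(\xi_R/\xi_L) \in [-6, 6]$ matching the model's ratio of
   plateau-mean speeds to the observed one.
4. `fit_force_scale()`: a closed-form rescale (the model is linear in the
   forcing) matching the lagging-side plateau speed.
5. `fit_viscosity_ratio()`: golden-section/parabolic search on
   $\log_{10}(\mu/\xi_L)$ over $[10^{-2}\sigma^2, 10^{10}\sigma^2]$
   minimizing the RMS mismatch over the lagging region, with the force
   rescale of step 4 re-applied at every trial value so the objective
   measures shape rather than magnitude.

Steps 3–5 cycle until all three ratios change by less than `tol`
(default $10^{-3}$) or `max_iter` (50) is reached; the per-iteration RMS is
recorded and the reported iterate never fits worse than the first.

Derivative smoothing is a local least-squares quadratic in a sliding
window, evaluated at the centre point — the Savitzky–Golay estimate,
implemented directly so that non-uniform grids are handled and window ends
use shifted (not truncated) windows, keeping the estimate exact for
quadratics everywhere. The default window is chosen by a pilot-bandwidth
plug-in: a pilot of about a tenth of the profile sizes the motor band,
then the window is reset to about half that width (minimum 7 points).
Plateau windows exclude `margin` $\times\,\sigma$ (default 3) around the
zone; when the zone sits close to an edge — as it does for the amoeboid and
mesenchymal geometries — the margin on that side is reduced to the largest
value keeping at least three points, and the reduction is recorded in the
diagnostics.

Four additions, each motivated by a measured failure mode of the bare
staged procedure, complete the fit:

* **Dominant-side curvature extrema with bias correction.** A sharp
  adhesion step at the zone creates a boundary-layer curvature extremum
  immediately beside it on the suppressed side; the estimator therefore
  takes the largest-magnitude extremum per side, falls back to the
  better-resolved side when the two one-sided distances disagree by more
  than a factor of two (the artifact is always too close, never too far),
  and removes the smoothing kernel's widening ($d \to \sqrt{d^2 - s^2}$,
  $s^2$ the kernel variance). At small $\lambda$ the curvature extrema sit
  nearer $0.52\sigma$ than $\sigma/\sqrt 2$, an inherent $\sim 25\%$ bias
  of the mapping in that regime; the joint polish below removes it whenever
  the data identify $\sigma$.
* **A ladder of viscosity starts.** The 3–5 cycle has multiple
  self-consistent fixed points when the starting $\lambda$ is far from the
  truth; the cycle is run from $\mu/\sigma^2 \in \{10^{-1}, 10, 10^3,
  10^5, 10^7\}$ and the best-fitting run kept, breaking near-ties (within
  10% relative RMS) toward the smallest viscosity.
* **Simulation-based bias correction.** The step 1–2 estimators are
  re-applied to the fitted noiseless model curve, where the true $x_{CZ}$
  and $\sigma$ are known; their bias there is subtracted from the data
  estimates and the fit repeated (up to `bias_passes`, default 2). This
  removes, to first order, the skew-induced shift of the smoothed gradient
  peak and residual smoothing bias.
* **Joint polish and identifiability probe.** A Nelder–Mead refinement of
  $(\log \xi_R/\xi_L, \log \mu/\xi_L, \sigma, x_{CZ})$ descends the
  full-profile RMS, with the force scale tied to the lagging plateau in
  closed form; the staged estimates are its initialization and remain the
  interpretable decomposition. Afterwards the triple $(\xi_R/\xi_L,
  F_{max}/\xi_L, \mu/\xi_L)$ is scaled tenfold and the profile re-fit: if
  the RMS changes by less than 0.1% of the peak speed, the data constrain
  only a ray and the fit reverts to the staged iterate with
  `mu_lower_bound = TRUE`.

### What a velocity profile can and cannot identify

When $\lambda \gg 1$ on *both* sides of the zone — the neuronal-migration
regime, where even $\lambda_R = 2\mu/(\sigma^2\xi_R)$ is in the thousands —
the profile is uniform on each side and the transition occupies the whole
leading side. The observable content then reduces to the two plateau
levels and the transition length $\sqrt{\mu/\xi_R}$, and the triple
$(\xi_R/\xi_L, F_{max}/\xi_L, \mu/\xi_L)$ is free along a common ray: no
estimator, staged or otherwise, can recover its absolute position from the
profile alone. The lower-bound flag is the honest output in that regime,
and the recovery tests treat a flagged fit as "correctly reported
unidentifiable" rather than comparing its ray position to the generating
values. The four other motility presets do not sit in this regime and are
required to be recovered (and unflagged). Inside the tuning cycle, a
transiently wrong $\mu$ can make the observed side-speed ratio temporarily
unreachable; there the root search clamps to the better bracket endpoint
and continues, while the exported `fit_adhesion_ratio()` keeps the
hard-error contract.

## The synthetic generator and presets

`generate_profile()` solves the forward model and samples it every 0.2 µm —
a typical kymograph pixel size — then adds independent Gaussian noise.
Two noise structures are supported: *additive* (standard deviation a fixed
fraction of the peak speed, the simplest structure consistent with scatter
in digitized profiles) and *multiplicative* (a fraction of the local
speed, matching the uncertainty of streak-slope measurements, which scales
with the slope). The recovery experiments for strongly asymmetric cells
use the multiplicative structure: with additive peak-scaled noise the
leading-side plateau of an amoeboid cell ($|v_R| \sim 10^{-4}$ of peak at
$\xi_R/\xi_L = 4\times 10^3$) lies far below the noise floor of any window
mean and no estimator could pass a factor-of-two recovery bar.

`generate_kymograph()` advects uniformly seeded tracers by fixed-step
fourth-order Runge–Kutta through the interpolated flow field and renders
Gaussian-blurred streaks into a normalized space–time matrix — the visual
analogue of a marked kymograph, with the tracer paths retained for
quantitative checks. It emulates streak geometry only: no photobleaching,
drift, or imaging noise.

The five presets carry representative fitted ratios for each motility mode
verbatim, with two documented caveats: the cytokinesis $\mu/\xi_L$ is
ambiguous in the source fits and is stored as $5.0\times 10^2$, the value
consistent with $\sigma = 1$ and the reported $\lambda \sim 10^3$; and the
mesenchymal row's reported $\lambda$ order ($\sim 10^1$) is inconsistent
with its own $\sigma$ and $\mu/\xi_L$ (which give $\lambda \approx 45$,
order $10^2$) — the row is kept verbatim, flagged
(`lam_order_consistent = FALSE`), and excluded from order-consistency
checks rather than forced into agreement. Domain lengths and zone
positions per preset are package defaults placing the zone as in the
corresponding cell geometries (centred for cytokinesis; near the front for
crawling modes; inside the growth cone, 5 µm from the tip, for the
neuronal modes), since the source tabulates only ratios.

Synthetic data share the fits' statistical assumptions by construction —
independent Gaussian noise around an exactly steady 1D model. Passing
recovery tests therefore demonstrates the estimator's correctness and
conditioning, not robustness to what real kymographs add: drift,
correlated tracking errors, unsteady flow, multiple contractile zones, or
2D/3D geometry.

## Problem sizes and runtime choices

Default solves use 2001 grid points; forward solves inside fitting use 1001
(for the preset geometries this keeps $\sigma \ge 10\,\Delta x$). The test
suite fits all five presets noiselessly, runs a 20-replicate noisy recovery
for the amoeboid preset, and a 3-replicate noise-monotonicity experiment;
these sizes make the full suite run in a couple of minutes on one core
while leaving every recovery margin comfortably resolved.

## Known limitations

* Steady state only: no Maxwell relaxation, no response to abrupt force
  changes, no moving boundaries or length change during the observation.
* A single Gaussian contractile zone; multiple zones, extensile
  (microtubule-sliding) stresses, membrane tension and polymerization
  forces are not modelled.
* One spatial dimension: widths, 2D flow patterns and out-of-plane
  structure are projected away.
* Absolute mechanical parameters (in Pa·s, N, …) are not recoverable from
  a velocity profile; only the ratio set is.
* In the double-uniform regime ($\lambda \gg 1$ on both sides) the ratio
  triple is identified only up to a ray; the flag reports this, and any
  downstream interpretation should use the constrained combinations
  ($\sqrt{\mu/\xi_R}$ and the plateau levels) rather than the individual
  ratios.
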