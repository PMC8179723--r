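---
title: "Models and Monte Carlo methods for nanowaveguide-illuminated FCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and Monte Carlo methods for nanowaveguide-illuminated FCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nifs)
```

## The measurement this package simulates

Fluorescence correlation spectroscopy (FCS) infers concentrations and
diffusion constants from the fluctuations of a fluorescence signal recorded
from a small illuminated region: molecules diffuse in and out of the bright
spot, the photon count rate fluctuates, and the normalised intensity
autocorrelation

$$G(\tau) \;=\; \frac{\langle \delta F(t)\,\delta F(t+\tau)\rangle}
{\langle F\rangle^2}$$

decays on the timescale a molecule needs to cross the spot.  A
diffraction-limited confocal spot has a femtolitre effective volume, which
limits the technique to roughly nanomolar concentrations — too dilute for
many membrane processes that operate at 1–100 µM.  Nanowaveguide-illuminated
FCS (NIFS) replaces the focused beam by the near field emerging from a
metal-clad dielectric nanowire of ~40 nm diameter: the transmitted light is
laterally confined to the wire cross-section and decays evanescently within
tens of nanometres of the exit surface, shrinking the illuminated volume by
about four orders of magnitude (to the zeptolitre range) and providing the
axial sectioning needed to watch membrane-bound molecules without cytosolic
background.

The package implements the three illumination regimes as analytic,
peak-normalised profiles:

* **Gaussian ellipsoid** (`profile_gaussian3d`): the classical confocal
  focus $W = e^{-2(x^2+y^2)/r_0^2} e^{-2z^2/z_0^2}$, defaults
  $r_0 = 0.708$ µm, $\kappa = z_0/r_0 = 3$.
* **3D near field** (`profile_nifs3d`):
  $W = e^{-2(x^2+y^2)/r_0^2} e^{-z/z_0}$ for $z > 0$ and $0$ for $z < 0$
  (fluorophores cannot enter the waveguide), defaults $r_0 = 60$ nm,
  $z_0 = 12$ nm.  These are round ("~") values quoted for a
  40-nm-diameter wire; field-solver fits are not published, so results tied
  to the exact field shape are treated as approximate.
* **Annular rim profile** (`profile_annular`): within a few nanometres of
  the exit surface the lightning-rod effect concentrates intensity at the
  wire's rim, $W = e^{-(r-a_0)^2/b_0^2}$ with $a_0 = 20$ nm (wire radius)
  and $b_0 = 8$ nm.  It is the right profile for molecules confined to a
  membrane plane just above the exit surface.

A grid-sampled profile (`profile_grid`, trilinear interpolation, CSV
interchange) accepts externally computed intensity maps; the z-dependent
morphing between the annular and centred shapes is deliberately not modelled
as a single continuous field.

## Closed-form autocorrelation models

Each profile has a matching ACF model (all as `acf_*` functions):

* Conventional FCS, free 3D diffusion:
  $G = G_0 (1+\tau/\tau_D)^{-1} (1+\tau/\kappa^2\tau_D)^{-1/2}$ with
  $G_0 = 1/(V_\mathrm{eff} C)$, $V_\mathrm{eff} = \pi^{3/2} r_0^2 z_0$ and
  $\tau_D = r_0^2/4D$.
* 3D NIFS, diffusion in the half-space above a reflecting exit plane:
  $$G = \frac{1}{2 V_\mathrm{eff} C} \left(1+\frac{\tau}{\tau_D}\right)^{-1}
  \left[\sqrt{\frac{\tau}{\pi\tau_z}} +
  \Big(1-\frac{\tau}{2\tau_z}\Big)\,
  \mathrm{erfcx}\sqrt{\frac{\tau}{4\tau_z}}\right],$$
  with $V_\mathrm{eff} = \pi r_0^2 z_0$ and $\tau_z = z_0^2/4D$ — the same
  axial factor known from evanescent-wave (TIR) FCS.  `erfcx` is evaluated
  through the log-scale normal tail so it cannot overflow.
* 2D NIFS (membrane under the annular profile): no closed form exists for
  all lags; the model is piecewise,
  $$G = G_0 (1+\tau/\tau_D)^{-1/2} \quad (\tau \le \tau_\mathrm{crit}),
  \qquad
  G = G_0 \sqrt{4\pi\frac{\tau_C}{\tau}\frac{\tau_D}{\tau}}
  \left[1+\Big(\frac{\tau_C}{\tau}\Big)^2 +
  \tfrac14\Big(\frac{\tau_C}{\tau}\Big)^4\right] e^{-2\tau_C/\tau}
  \quad (\tau > \tau_\mathrm{crit}),$$
  with $\tau_D = b_0^2/2D$ (diffusion across the rim width, a 1D-Gaussian
  correlation decay) and $\tau_C = a_0^2/4D$ (diffusion around the
  annulus).  The long-time branch is the ring–ring correlation: its
  bracket is the series of the Bessel function $I_0(2\tau_C/\tau)$ arising
  from the exact angular integral, and the default switch point
  $\tau_\mathrm{crit}$ is the numerically located crossover of the two
  branches (`branch_crossover`), which falls at $8.29\,\tau_C$ for the rim
  geometry $\tau_D/\tau_C = 2b_0^2/a_0^2 = 0.32$.

Two conventions for the annular effective area circulate and differ by
exactly $\sqrt{2}$: $2\pi^{3/2}a_0 b_0$ equals the plain profile integral
$\int W\,dA$ ($1.78\times10^{-3}$ µm² at the default geometry), while
$(\int W)^2/\int W^2 = 2\sqrt{2}\,\pi^{3/2} a_0 b_0$
($2.52\times10^{-3}$ µm²) is the area whose inverse is the true zero-lag
amplitude.  `effective_volume(..., convention =)` exposes both and the
experiment reports print both; they are never silently reconciled.

### An independent numeric oracle

`acf_oracle()` evaluates the defining correlation integral
$\int\!\!\int W(\mathbf r) W(\mathbf r') P(\mathbf r'|\mathbf r,\tau)\,
dV\,dV' / (\int W\,dV)^2$ by quadrature, with the free Gaussian propagator
(3D and 2D) or its method-of-images reflected counterpart (half-space).
It shares no code with the closed forms and is used in the test suite to
validate them: the Gaussian-ellipsoid model is reproduced to better than
1% and the 3D NIFS model to better than 2% over four decades of lag; the
2D branches are approximations and agree with the oracle to <0.5% (short
branch, $\tau \lesssim 0.1\tau_D$), ~5% near the crossover and <1.5%
beyond $32\tau_C$.

Numerical choices that matter: all integrals run in dimensionless
coordinates (lengths in units of the profile scale) because quadrature
tolerances are effectively absolute and SI magnitudes of $10^{-15}$ would
defeat them; the double integrals are taken in rotated coordinates
$u = r - r'$, $v = r + r'$ so that the diffusion ridge along $r \approx r'$
aligns with a panel axis (domain constraints $r, r' \ge 0$ become the
triangle $v \ge |u|$, handled by the substitution $v = |u| + w$ with a
panel edge on the $u = 0$ kink); panels are doubled until two successive
Gauss–Legendre estimates agree to `rel_tol` ($10^{-4}$ by default), and
non-convergence is an error, not a warning.  The resolvable-lag floor is
$\sqrt{4D\tau} \gtrsim 0.05\times$ the profile scale; the zero-lag
amplitude is checked at $\tau \approx 10^{-3} \tau_D$ rather than at 0.

## The Monte Carlo engine

`run_simulation()` executes the classic three-stage scheme: (1) draw
initial positions uniformly over a rectangular box; (2) evolve Brownian
motion; (3) let each molecule emit photons according to the local
intensity, and bin counts per time step.

* **Dynamics.** Overdamped positional updates: each coordinate gains an
  independent Gaussian increment of variance $2D\,\Delta t$ per step.  At
  the 100 ns default step the solvent's viscous relaxation time
  ($a^2/\nu \sim$ ns for nanometre particles) is long past, so
  velocity-resolved schemes add nothing: the positional scheme is exactly
  diffusive at every step.
* **Boundaries.** Lateral faces are periodic.  For the 3D near field the
  exit plane $z = 0$ is a hard wall implemented as specular reflection
  ($z \to -z$), and the top face defaults to periodic re-injection (the
  box height is many decay lengths, so the choice is immaterial — a
  reflecting top is available and changes nothing measurable).
  Conventional FCS uses periodic faces everywhere.  2D mode holds
  molecules on the plane $z = 2.3$ nm above the exit surface.
* **Emission.** Per step and molecule, a photon is emitted with
  probability $b\,W(\mathbf r)$ (Bernoulli thinning; bin width equals the
  step).  Validity requires $b \le 0.1$, which the configuration enforces.
  `calibrate_brightness()` sets $b$ from the target count rate using the
  equilibrium-uniform average of $W$ sampled by Monte Carlo (a stage-1
  pilot): a short *dynamical* pilot is useless for nanoscopic profiles,
  where a 2-fL box holds ~0.03 molecules inside the near field at any
  instant and most short pilots see zero photons.
* **Count rates.** The conventional working point is ~100 kHz.  For the
  3D near-field geometry at the standard concentration the Bernoulli cap
  limits the attainable rate to ~34 kHz ($n\langle W\rangle \approx
  0.034$); experiment runs therefore target
  $\min(10^5, 0.95\times\text{max achievable})$ counts/s.  The 2D
  experiment, with even fewer excited molecules, is recalibrated upward
  for the same reason.
* **RNG and determinism.** The kernel uses its own xoshiro256++ generator
  with a 128-layer ziggurat normal sampler, seeded as
  `seed + run_index - 1` per run.  A configuration plus seed reproduces
  traces bit-identically, independent of R's RNG state; R's generator is
  too slow for the $10^{10}$ particle-steps a desk-scale experiment
  needs.  The RNG identity is recorded in trace metadata.

## Correlation estimation and its finite-sample offsets

`autocorrelate()` is a direct-summation estimator on a quasi-logarithmic
grid of integer-multiple-of-$\Delta t$ lags (default 12 per decade, up to a
tenth of the trace length), normalised by the squared mean of the full
trace; $\tau = 0$ is excluded (shot noise is not part of the diffusion
models).  Direct summation was chosen over a multi-tau cascade for
transparency; the compiled inner loop makes it cheap.  `average_curves()`
averages runs and records the per-lag sample standard deviation (n−1),
which normalises residuals and weights fits.

Two systematic offsets of this estimator are *exactly known* and matter at
desk scale:

1. **Finite trace duration.** Normalising by the same trace's mean biases
   the estimator low by $(2/T)\int_0^T (1-t/T)\,G(t)\,dt$ — about 3% of
   $G_0$ for the conventional geometry at $T = 1$ s, but tens of percent
   at $T = 0.1$ s.
2. **Closed box.** A simulation with a fixed number $N$ of molecules has
   anticorrelated occupancies (one molecule entering the spot leaves the
   rest of the box), contributing $-1/N$.

Left alone, these constant offsets masquerade as faster decay and bias
fitted diffusion times low by ~10–20% at tractable scales.
`fcs_fit(..., finite_size = list(T =, N =))` therefore subtracts the
offset implied by the fitted parameters, re-estimated in an outer
fixed-point loop (≤6 iterations, 2% tolerance).  The offset is held
constant within each least-squares pass on purpose: letting it vary with
the trial parameters inside the objective opens a spurious branch in
which amplitude, timescale and offset inflate together.  The correction
restores exact recovery on synthetic curves and unbiased recovery in
simulations; both terms vanish as $T$ and $N$ grow, so full-scale results
are unchanged.  `run_experiment()` applies it by default and prints the
offset used.

## Fitting

`fcs_fit()` is weighted nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`) on log-transformed parameters, which enforces positivity
without constraints; up to five restarts from jittered starts guard
against bad initial guesses (`initial_guess()` reads $G_0$ off the
smallest lag and $\tau_D$ off the half-decay lag).  Weights are $1/sd$
from the run-to-run scatter by default (lags with zero sd are dropped);
uniform weights are available.  Standard errors come from the weighted
Jacobian at the optimum and are approximate.  For the piecewise 2D model
the switch time is not free: an outer fixed-point loop (≤10 iterations,
1% tolerance) re-locates the branch crossover of the current parameters
and refits.

For the conventional experiment the oblateness is held at its optical
value ($\kappa = 3$) by default: over desk-scale lag ranges the axial
factor is nearly degenerate with $\tau_D$, and freeing $\kappa$ lets it
run away while $\tau_D$ compensates.  The near-field fits ($G_0, \tau_D,
\tau_z$) and ($G_0, \tau_D, \tau_C$) have no such degeneracy and fit all
parameters.

## The built-in experiments

`experiment_spec()` ships the three standard in-silico experiments
(conventional `fcs3d`; 3D near-field `nifs3d`; membrane `nifs2d`) with the
parameters listed above, at 1 particle/fL, 500/fL and 100/µm²
respectively.  Full scale is $10^7$ steps of 100 ns and 20 runs per
diffusion constant; `scale` shrinks steps and runs proportionally with
floors of $10^5$ steps and 4 runs, and `n_particles` may be reduced with
the box shrunk to preserve concentration.  The box is kept near-cubic:
squeezing the axial extent to buy lateral room truncates the Gaussian
focus and inflates the amplitude by >10%, whereas lateral truncation is
negligible beyond about four beam radii.

Problem sizes used by the shipped verification runs, chosen to keep the
known finite-size offsets small relative to the target tolerances while
remaining desk-sized: the conventional recovery uses 400 molecules in a
400-fL box, $10^7$ steps × 5 runs ($2\times10^{10}$ particle-steps, with
$T = 1$ s keeping the trace-duration offset at ~3% of $G_0$); the 3D
near-field recovery uses 250 molecules, $2\times10^6$ steps × 20 runs at
$D = 10^{-12}$ m²/s (with $\tau_z$ pinned to its geometric value
$z_0^2/4D$, exactly as $\kappa$ is pinned for the conventional fit — at
this scale the axial time is strongly anticorrelated with $\tau_D$ and
freeing it roughly doubles the $\tau_D$ error); the membrane recovery
uses 100 molecules, $10^6$ steps × 20 runs at the same $D$ (a 0.1 s trace
is then $10^3\,\tau_C$).

## What the simulations do and do not show

The generator emulates ideal-solution diffusion of identical, always-on
fluorophores under analytic illumination profiles.  Passing tests
demonstrate that the closed-form ACFs correctly describe their generating
processes and that the pipeline recovers known inputs — they do not
demonstrate robustness to photophysics (triplet blinking, bleaching,
saturation), detection optics, background, afterpulsing, polydispersity,
or the difference between the analytic profiles and a real waveguide's
field (edge effects make the true 3D profile non-Gaussian near the exit
surface, which is precisely why published fitted values at full scale sit
a few tens of percent from the analytic inputs).  Cross-correlation,
anomalous diffusion and multi-component mixtures are out of scope.

The piecewise 2D model is itself an approximation: near the branch
crossover it deviates from the exact ACF by up to ~10%, so recovered 2D
timescales carry correspondingly wider tolerances (the 40% band used in
the acceptance checks mirrors the deviations reported for full-scale
fits).
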