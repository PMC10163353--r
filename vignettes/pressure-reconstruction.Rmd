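---
title: "Reconstructing pressure around swimming fish from planar velocimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pressure around swimming fish from planar velocimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivpressure)
```

## The problem

A fish senses its hydrodynamic environment largely through pressure: the
lateral line responds to pressure differences along the body. Pressure
cannot be measured optically, but planar particle image velocimetry (PIV)
yields time-resolved 2D velocity fields around a swimming fish. The task is
to infer the instantaneous pressure field — and in particular the pressure
*on* the moving, deforming body surface — from those velocity measurements.

Classically this is done by integrating the momentum balance. In
non-dimensional variables (lengths by a characteristic length $L$, times by
$T$, velocities by $U$, pressure by $\rho U^2$) the 2D incompressible
momentum equations are

$$
\partial_t u + u\,\partial_x u + v\,\partial_y u
  = -\partial_x p + \tfrac{1}{Re}\nabla^2 u, \qquad
\partial_t v + u\,\partial_x v + v\,\partial_y v
  = -\partial_y p + \tfrac{1}{Re}\nabla^2 v .
$$

Two baseline routes are implemented here:

* **Pressure-Poisson** (`solve_poisson()`): take the divergence of the
  momentum balance and solve $\nabla^2 p = \nabla\cdot g$, where
  $g = -D\mathbf u/Dt + Re^{-1}\nabla^2\mathbf u$ is the momentum-derived
  pressure gradient.
* **Multi-directional integration** (`integrate_multidirectional()`), the
  omnidirectional scheme popularized for animal-locomotion PIV: line
  integrals of $g$ along straight rays from the domain boundary, aggregated
  per node by the median, with a zero-pressure anchor on the external
  boundaries. Rays terminate at the fluid–body interface, because PIV
  vectors next to the body are unreliable; the surface pressure must then be
  copied from the nearest valid grid node
  (`nearest_point_surface_pressure()`), an extrapolation whose error grows
  with the grid spacing.

Both baselines inherit the weaknesses of their boundary treatment and of
finite differencing on the measurement grid.

## The physics-informed network

The core of the package, `pinn()`, trains a fully connected coordinate
network $(x, y, t) \mapsto (u, v, p)$ whose loss combines

* a **data term**: mean squared mismatch to the measured velocity vectors;
* an **equation term**: the momentum residuals above, evaluated by *exact*
  differentiation of the network (the derivative channels are propagated
  analytically through every layer, no finite differences) at collocation
  points that need not coincide with measurement nodes;
* **boundary terms**: a non-penetration condition
  $\mathbf u\cdot\mathbf n = u_n$ on the body surface (the body kinematics
  enter the reconstruction as data), optional zero-pressure and
  inlet-velocity conditions on external edges;
* an **initial-condition term**, supported for completeness but disabled by
  default.

The default weights are 100 (data), 0 (initial), 100 (boundary), 1
(equation). The pressure appears only through its gradient unless a
pressure boundary condition is active, so in that configuration the network
pressure carries an arbitrary additive constant ("gauge"); every comparison
in the package first removes the gauge (`remove_gauge()`, `field_rmse()`),
and `predict_field()` reports which gauge its output carries.

Hidden layers use an affine map, the activation (sigmoid by default, tanh
optional) and a per-neuron trainable gain vector; the gain can be switched
off to obtain plain affine layers (`network_config(gain = FALSE)`). Inputs
are affinely normalized to $[-1, 1]^3$ over the training domain; that
normalization is part of the model and is chained through all reported
derivatives. Training is ADAM with minibatches: an epoch is one full pass
over the measured vectors; the equation and boundary batches are
independent uniform subsamples per iteration, capped at the configured
minibatch size. Two seeds (parameter initialization, sampling) make a run
bit-reproducible.

The reference configuration — 12 hidden layers of 120 sigmoid neurons,
minibatch 10 000, 1500 epochs — is the package default and is sized for
accelerator hardware and hours of training. The bundled desk presets
(`pinn_preset()`) are sized for minutes on one CPU: a 4 × 64 tanh network,
minibatch 1024, 2000 ADAM steps for the Taylor–Green benchmark, and a
4 × 48 tanh network for the swimmer surrogate. At desk scale tanh trains
markedly faster than sigmoid (sigmoid's non-centered activations need a
higher learning rate and more steps to escape the mean-predictor plateau);
the learning rate (default $10^{-2}$ for the presets, $10^{-3}$ for the
reference configuration, halved periodically) is exposed in
`training_config()`.

### Where the method's advantage comes from

The trained network is a smooth function of $(x, y, t)$: pressure can be
evaluated **exactly on the body contour** (`surface_pressure()`; the
reported extrapolation distance is identically zero) and on grids finer
than the measurements. The momentum residuals are always evaluated on the
finest available grid even when the measured vectors are coarse — when the
body kinematics are supplied, the contour points themselves are appended to
the collocation set so the pressure gradient is pinned right up to the
fluid–body interface. This is what makes the reconstruction insensitive to
the measurement resolution, while the baseline's nearest-node surface
extrapolation degrades as the grid coarsens.

## Synthetic ground truth

No deposited dataset accompanies the method, so the package generates its
own exactly solvable flows:

* `taylor_green_truth()`: the decaying Taylor–Green vortex on
  $[0, 2\pi]^2$, an exact unsteady Navier–Stokes solution with closed-form
  pressure (zero-mean gauge; the discrete spatial mean is pinned to zero,
  which only fixes the arbitrary constant).
* `potential_swimmer_truth()`: an unsteady potential-flow surrogate for the
  mid-plane slice around a carangiform swimmer. A uniform free stream is
  superposed with three dipoles buried along the body midline; the dipoles
  translate laterally with the prescribed undulation
  $\Delta y / L = A(x)\sin(kx - 2\pi f t + \varphi)$,
  $A(x) = a_0 + a_1 (x/L) + a_2 (x/L)^2$ with the mackerel-style
  coefficients $a_0 = 0.02$, $a_1 = -0.08$, $a_2 = 0.16$ and $k = 2\pi/L$.
  Because the field is harmonic, the viscous term vanishes identically and
  the unsteady Bernoulli relation
  $p = \tfrac12(U_\infty^2 - |\mathbf u|^2) - \partial_t\phi$ is the exact
  pressure at any Reynolds number. Grid nodes inside the body contour
  (midline ± half-width) are masked, exactly as PIV vectors inside a fish
  silhouette are removed.

Design choices for the surrogate that were genuinely open:

* **Body geometry.** The half-width profile
  $w(s) = 0.15\,\sin(\pi s)^{1/2}$ (in body lengths) is blunter and thicker
  than a real mackerel. It was chosen so that (a) the nose region carries a
  positive, stagnation-like head pressure (the normalizer of the surface
  error metric, about $0.25\,\rho U^2$ here), and (b) the contour passes no
  closer than about one maximum half-width to any singularity, so the
  near-surface pressure varies on scales ($\sim 0.15 L$) that a
  PIV-resolution grid and a desk-scale network can both resolve. A thin
  body with shallow singularities makes the surface pressure vary on the
  scale of the local half-width, which no method can recover from data at
  coarser spacing.
* **Contour vs. flow.** The contour is *not* a streamline of the dipole
  flow, so the kinematic normal velocity $u_n$ of the contour is not
  consistent with the surrogate's flow at the surface. Surrogate
  reconstructions therefore train with the data and equation terms (body
  condition off) and rely on direct on-contour evaluation; the
  non-penetration loss itself is exercised by unit tests and available for
  real data, where the kinematics and the flow are mutually consistent.
* **Continuity.** The package default leaves the divergence-free residual
  out of the equation term, the right choice for a 2D slice of a 3D flow
  where in-plane divergence need not vanish. The surrogate, however, is
  exactly 2D: the sweep drivers enable the continuity residual for it,
  because with sparse coarse measurements the two momentum residuals alone
  leave $(u, v, p)$ underdetermined.
* **Noise reference.** `add_noise()` scales white Gaussian noise by the
  maximum velocity magnitude of the clean series; the reference is
  configurable since no standard definition exists.

What the surrogate does *not* emulate: three-dimensional wake effects and
out-of-plane velocity (a known error source for all 2D methods near the
tail — the surface error metric excludes stations beyond $0.9 L$ for this
reason), boundary-layer vorticity (the surrogate is inviscid and
irrotational outside the body), and realistic fish thickness. Passing the
validation suite therefore demonstrates the machinery — losses, exact
derivatives, optimization, gauge handling, surface evaluation — under
controlled conditions, not field performance on real PIV data.

## The surface error metric

Surface accuracy is summarized by the relative global RMSE
(`relative_global_rmse()`): the root of a single global mean over retained
surface points and all time steps of the squared pressure error, divided by
the magnitude of the head pressure, in percent. Decisions that needed
fixing: the time average sits *inside* the root (one global mean, not a
mean of per-time RMSEs); the head pressure is operationalized as the true
nose-station surface pressure averaged over time; points with $x > 0.9L$
are excluded before any aggregation. When a reconstruction carries a
different gauge than the truth, the comparison aligns the two by matching
field means over the common valid nodes before the surface difference is
taken.

## Numerical choices

* Finite differences in the baselines are second order, with one-sided
  second-order stencils at domain edges and series endpoints; the gradient
  is flagged undefined wherever its stencil touches a masked node.
* The Poisson system excludes masked nodes; external edges use a reflected
  ghost with the momentum-derived normal gradient (or a zero Dirichlet
  pin), immersed interfaces a one-sided closure. The all-Neumann system is
  solved with a zero-mean Lagrange constraint, which also defines its
  gauge.
* The integrator's ray anchors default to the documented zero-pressure
  convention on all external boundaries. That convention carries an O(1),
  resolution-independent bias whenever the true boundary pressure is not
  zero, so discretization-order studies anchor the rays at known boundary
  values instead (`integration_options(boundary_values = ...)`);
  application runs keep the zero anchor.
* On-contour grid nodes count as body-interior when masking (vectors on
  the interface are as unreliable as interior ones); equidistant
  nearest-node ties resolve to the lowest column-major node index.
* Training aborts with a diagnostic on a non-finite loss; the sampling and
  initialization RNG streams are isolated from the caller's RNG state.
* Desk-scale problem sizes used throughout the validation suite: a
  $32\times 32\times 10$ Taylor–Green series (Re = 100) and a
  $76\times 31\times 11$ swimmer surrogate at $0.02L$ / $0.02T$; the sweep
  coarsens to $0.06L$ and $0.1L$. The sweep driver equalizes the ADAM-step
  budget across resolutions, since an epoch is defined as a pass over the
  measured vectors and coarser series would otherwise receive
  proportionally fewer updates.

## Known limitations

* The desk presets trade accuracy for minutes-scale runtimes; surface
  errors on the surrogate are tens of percent of the head pressure,
  dominated by the sharp near-surface pressure variation relative to the
  network capacity. The reference configuration narrows this gap at the
  cost of hours of training.
* A trained network is specific to its dataset; nothing transfers across
  flows, and each new velocity series requires retraining.
* The momentum residuals drop all out-of-plane products; strongly 3D
  regions (tail, wake) are reconstructed with larger error by every method
  implemented here.
* The integration baseline is a re-implementation from the published
  description of the omnidirectional scheme (ray count and aggregation are
  configurable); it is not a port of any released tool.
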