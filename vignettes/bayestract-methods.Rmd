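---
title: "Posterior-energy tractography with elastic shape priors: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posterior-energy tractography with elastic shape priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayestract)
```

# The estimation problem

Deterministic streamline tractography grows a fiber curve sequentially from
a seed by following the principal eigenvector of the local diffusion
tensor. That one-boundary strategy is fragile: at fiber crossings the local
principal direction is ambiguous, and a single wrong turn cannot be
undone. `bayestract` instead treats tractography as a two-boundary
estimation problem: a whole curve $\beta : [0,1] \to D = [0,1]^2$ with
fixed endpoints is evolved by gradient descent on a posterior energy

$$E_{total}(\beta) \;=\; \lambda_1 E_{data}(\beta) \;+\;
  \lambda_2 E_{prior}(\beta) \;+\; \lambda_3 E_{smooth}(\beta),$$

whose three terms are a diffusion-data likelihood, a statistical shape
prior learned from training fibers, and a length penalty. All three
gradients are available in closed form, so the optimization is a plain
(deterministic) descent rather than a stochastic search.

## The data term

For a 2D tensor field $M : D \to \mathrm{SPD}(2)$ the data energy is the
scale-invariant alignment functional

$$E_{data}(\beta) = \int_0^1 n_\beta(t)^\top M_{\beta(t)}^{-1}\,
  n_\beta(t)\, dt, \qquad n_\beta = \dot\beta / |\dot\beta|,$$

which is small where the tangent rides the dominant eigenvector of the
local tensor and — unlike geodesic formulations under the inverse-tensor
metric — does not conflate direction agreement with curve length: the
integrand depends on the tangent *direction* only, so rescaling the speed
of traversal leaves the value unchanged. Length is controlled separately by
$E_{smooth}(\beta) = \int_0^1 |\dot\beta|\,dt$, whose negative gradient is
the classical curve-shortening (heat) flow. An optional variant of the
data term with measure $|\dot\beta|\,dt$ (full reparameterization
invariance) is available behind the `reparam_invariant` flag of
`e_data_tensor()` and is off by default.

For HARDI data the per-voxel model is an orientation distribution function
$f_p$ on the unit circle, stored as a truncated even-order Fourier series
(default order $L = 8$; odd harmonics vanish identically, which *is*
antipodal symmetry, and $a_0 = 1/2\pi$ enforces unit mass). The data term
becomes $E_{data}(\beta) = \int_0^1 -f_{\beta(t)}(n_\beta(t))\,dt$, and
the Fourier representation makes the angular derivatives
$\partial f/\partial\theta$, $\partial^2 f/\partial\theta^2$ of its
gradient analytic.

## The shape prior

Fibers connecting a given pair of regions have consistent geometry across
subjects, so a statistical model of their *shape* is informative exactly
where the data are ambiguous (crossings, noise). Shapes are analyzed
elastically: a unit-length curve is represented by its square-root
velocity function (SRVF) $q = \dot\beta/\sqrt{|\dot\beta|}$, under which
the elastic metric is the flat $\mathbb{L}^2$ metric and
$\int |q|^2 dt = \mathrm{length} = 1$, so preshapes live on the unit
sphere of $\mathbb{L}^2([0,1],\mathbb{R}^2)$. A shape is the orbit of $q$
under rotations and orientation-preserving reparameterizations.

From training fibers the package computes a Karcher mean $[\mu]$ (standard
fixed-point iteration with step 0.5) and a tangent PCA of the shooting
vectors $v_i = \exp_{[\mu]}^{-1}([q_i])$: the top $m$ principal directions
$U_m$ with variances $S_m$, plus a tail scale $\delta$. The prior is a
truncated wrapped normal on the tangent space, and its negative
log-density exponent is the prior energy

$$E_{prior}(q) = \tfrac12 v^\top (U_m S_m^{-1} U_m^\top) v +
  \tfrac{1}{2\delta^2}\,\|v - U_m U_m^\top v\|^2,
  \qquad v = \exp_{[\mu]}^{-1}([q]),$$

truncated at the injectivity radius $\|v\| < \pi$. The normalizing
constant never enters the energy and is not computed. The gradient in the
tangent space is $w = A v$ with
$A = U_m S_m^{-1} U_m^\top + (I - U_m U_m^\top)/\delta^2$, parallel
transported along the connecting great circle to the current shape.

**Retained dimension and tail scale.** `tangent_pca()` keeps the smallest
$m$ explaining 95% of tangent variance, capped at 5. The singular values
of the tangent covariance are *variances*, so the dimensionally consistent
reading of "the tail must be tighter than every retained mode" is a
constraint on the tail variance: we set $\delta = 0.5\sqrt{S_{min}}$, i.e.
$\delta^2 = S_{min}/4$. Setting $\delta$ to a fraction of $S_{min}$ itself
(a variance, typically $10^{-3}$ here) would make the tail precision
$1/\delta^2 \sim 10^5$; at that stiffness, discretization-level alignment
residuals of order $10^{-4}$ dominate the energy, the prior gradient stops
being a reliable descent direction, and pure-prior evolutions stall. With
the variance-consistent rule the prior gradient passes descent checks on
random curves and pure-prior flows converge to the mean shape.

# Numerical design

## Discretization

Curves are $T$ ordered points on the uniform parameter $t_i = i/(T-1)$
(default $T = 100$). First and second derivatives use central differences
with second-order one-sided stencils at the ends; integrals use the
trapezoid rule; the same trapezoid weights define the $\mathbb{L}^2$ inner
product of the shape machinery, so sphere geometry (exponential map, log
map, parallel transport — all closed-form for the sphere) and PCA are
mutually consistent. Tensor and ODF fields are node-centered grids over
the unit square (node $(i,j)$ at $((i-\tfrac12)/G_1,(j-\tfrac12)/G_2)$),
interpolated entrywise bilinearly; interpolated tensors are eigenvalue
floored at $10^{-4}$ times the field's largest eigenvalue (bilinear
combinations of SPD matrices are SPD, so the floor is a safety net, not a
projection in regular use). Queries outside the node hull use constant
extension; evolution steps that leave the domain are clamped to the
boundary.

## Exact discrete gradients

The analytic gradients of the data and length terms are assembled in
"lemma form" $\partial g/\partial\beta - \tfrac{d}{dt}\,
\partial g/\partial\dot\beta$, with two implementation choices that matter
numerically. First, spatial field derivatives inside the gradient use the
exact derivative of the bilinear interpolant (the quantity the energy
actually sees), while `field_gradient_at()` separately exposes the cached
node-stencil gradient of $M$ and $M^{-1}$. Second, the outer time
derivative is applied as the exact adjoint of the stencil/trapezoid
scheme: the pointwise factors ($n^\top(\partial M^{-1}/\partial x_k)n$ and
$(2/|\dot\beta|)(M^{-1}n - (n^\top M^{-1}n)n)$ for the tensor term; the
analytic $\partial f/\partial\theta$ factors for the ODF term) are
analytic, and the $d/dt$ is the transposed difference operator. In the
continuum this is identical to the fully expanded product-rule expressions;
on the discretized problem it is the *exact* gradient of the implemented
energy, so central-finite-difference checks agree to $\sim 10^{-6}$
instead of the $10^{-2}$-level error the expanded form suffers from the
derivative kinks of piecewise-bilinear fields.

## Shape alignment

The reparameterization group is approximated by dynamic programming over
monotone lattice paths with coprime slope steps up to 4 (a compiled
kernel), alternated with Procrustes rotations. The lattice quantizes
slopes, so the DP solution is polished by projected gradient descent on
the warp values themselves, using the analytic functional gradient of the
matching cost (also compiled); this removes the staircase residual (orbit
distances drop from $\sim 3\times10^{-2}$ to below $10^{-2}$ for mild
warps). `align_shapes()` exposes three modes: `"dp"` (full search,
default for user-facing distances), `"refine"` (polish from the identity,
fast), and `"auto"` (fast path with DP fallback when a large residual
remains) used inside model fitting and tracking, where shapes are
concentrated. Severe warps with boundary slope 0 (for example
$\gamma(t)=t^2$) destroy sampling information at $T \approx 100$: the pure
warp round trip already leaves an orbit distance near 0.08, and the
aligner attains that floor rather than any fixed small tolerance.

## The tracker

`evolve()` iterates
$\beta \leftarrow \beta - \delta(\lambda_1\nabla E_{data} +
\lambda_2\nabla E_{prior} + \lambda_3\nabla E_{smooth})$ with the
endpoints fixed. Three specifics:

* **Optimizer.** The default is L-BFGS-B in epochs (`epoch_iter = 100`
  inner iterations) on the free curve points, with uniform arc-length
  resampling and prior re-alignment between epochs, both accepted only if
  the total energy does not increase — so the per-epoch energy trace is
  nonincreasing by construction. A plain adaptive-step gradient mode
  (`optimizer = "gradient"`: persistent halving on rejection, regrowth on
  acceptance) is retained as the reference first-order scheme. The
  quasi-Newton default is not cosmetic: the prior's Hessian spectrum spans
  roughly four orders of magnitude (tail modes act through the derivative
  operator of the SRVF), the stability-limited explicit step makes
  progress along the data valley negligible, and first-order runs stall at
  energies far above states that line searches along the straight path to
  the optimum show to be reachable by monotone descent.

* **Frozen prior alignment.** Re-solving the rotation/reparameterization
  alignment inside every energy evaluation makes $E_{prior}$ non-smooth at
  the $10^{-2}$ level (the optimizer's alignment path branches), which
  defeats monotone line searches. The tracker therefore freezes the
  alignment state within an epoch and evaluates the prior through it (an
  upper bound on the orbit-aligned energy, tight where the state was
  computed); the state is refreshed between epochs under the same
  no-increase rule. The tracker's prior gradient is the exact reverse-mode
  adjoint of this frozen-alignment energy. The exported
  `grad_e_prior_curve()` keeps the finite-difference construction (step
  the aligned SRVF against the transported gradient, reconstruct the curve
  with endpoint pinning and rigid re-registration, difference): it is the
  natural definition of a curve-space prior gradient and passes descent
  checks, but its conversion error on the stiffest tail modes is too large
  for backtracking line searches, which is why the tracker uses the exact
  adjoint internally.

* **Endpoint masking.** Endpoints never move. When the data term acts
  without the prior, the two neighbors on each side are also frozen: they
  couple to the pinned endpoint through the one-sided velocity stencil,
  and the data term can exploit that coupling to fold the curve near the
  ends (the fold is nearly free because the alignment integrand is even in
  the tangent). With the prior active, end-region roughness is penalized
  and those points must stay free so the prior can shape them; pure
  curvature flow cannot fold and also runs unmasked.

Stopping: relative total-energy change below `tol` (default $10^{-6}$)
over consecutive checks, or `max_iter`. A divergent evolution (non-finite
gradient) raises an error carrying the trajectory so far.

# The synthetic phantoms

`make_scene()` builds four deterministic-by-seed scenes: `crossing` (the
headline experiment), `kissing` (two bundles approaching within a grid
cell without touching), `noisy_patch` (a bundle plus a box of seeded
random SPD tensors), and `arc_bundle` (training fibers for the prior).
`scene_to_tensor_field()` rasterizes truth tangents into a
$20 \times 20$ grid of tensors
$a_{long}\,\overline{uu^\top} + a_{perp} I$ (defaults 1.0 / 0.1, isotropic
baseline $0.2 I$ in empty cells), Gaussian-smooths every entry
($\sigma = 0.75$ cells) and re-floors eigenvalues; the outer products are
splatted onto the four surrounding nodes with bilinear weights, so the
rasterized ridge centerline follows the true curve instead of the cell
lattice (plain cell assignment makes tracking accuracy depend on the
bundle's phase relative to the grid). `scene_to_odf_field()` builds
per-cell mixtures of antipodally symmetric von Mises-style lobes
$\propto \exp(\kappa\cos 2(\theta-\alpha))$ on the segment tangent angles
(default $\kappa = 8$, 10% uniform floor), smooths across the grid, and
projects on even Fourier harmonics with clipping/renormalization of
truncation ringing.

**Crossing-phantom geometry.** The reference experiment is pictorial, so
the package emulates its *regime* rather than its pixels, and the printed
distances themselves constrain the geometry: a no-prior mean distance in
the $10^{-3}$–$10^{-2}$ range requires truth fibers inside the data
term's capture basin and individually resolvable on a $20\times20$ grid,
and a with-prior distance another order lower requires per-fiber ridges.
The defaults are therefore five gentle arcs (height 0.04, i.e. under one
cell of bow) spaced 0.13 apart — more than two cells, staggered against
the grid period, and with apexes clearing the next chord by two smoothing
widths (when spacing minus height shrinks to one smoothing width, a
fiber's initialization line lies on its neighbor's apex plateau and
trackers are systematically captured). The crossing bundle is two vertical
lines through the domain: perpendicular crossings produce
direction-ambiguous mixture cells — the classical failure mode for
streamlining — whereas oblique crossings form a partially-compatible
"highway" that drags endpoint-pinned contours sideways; and the crossing
is kept compact because the mean-over-parameter data term starts rewarding
detours through cheap ridge segments once the mean integrand exceeds the
ridge level by about $\lambda_3 L/\lambda_1$. Per-seed variation enters
through whole-bundle placement jitter (±0.02) with only minimal curvature
jitter (±0.003): the prior is a model of the *same* connection, so the
truth's curvature should be in-family, while placement is
shape-irrelevant. Training bundles (`arc_bundle`) draw 30 arcs with
matching height statistics and small endpoint scatter.

**What passing these phantoms does and does not show.** The phantoms have
noise-free geometry, piecewise-smooth fields, and a prior trained on the
actual truth family; real dMRI adds measurement noise, partial-volume
mixing, 3D geometry, atlas/registration error in the training tracts, and
priors that only approximate the subject's anatomy. The experiments
demonstrate the mechanism — the shape prior rescues tracking where local
data are ambiguous — not clinical performance.

# The comparison experiment

`run_figure_experiment(seed)` is fully self-contained: it fits the prior
on a fresh training bundle, rasterizes the crossing phantom, runs (a) the
FACT-style streamline baseline seeded at the truth's left endpoints
(fixed-step Euler along principal eigenvectors, sign continuity, stopping
on boundary / 45° turning / anisotropy index below 0.15 — deliberately
first-order, so it exhibits the classical failure modes), (b) the
active contour without the prior ($\lambda = (0.8, 0, 0.1)$), and (c) the
full posterior ($\lambda = (0.8, 0.1, 0.1)$), then scores each bundle by
the mean nearest-truth $L^2$ distance after arc-length resampling
(`bundle_distance()`). Across seeds the ordering
$d_{withprior} < d_{noprior} < d_{streamline}$ is stable, with
$d_{withprior}$ of order $10^{-3}$, $d_{noprior}$ of order $10^{-2}$ and
$d_{streamline}$ of order $10^{-1}$ in domain units.

One caveat is worth stating precisely: under this metric, *any*
streamline failure that terminates away from the target region scores at
least about 0.2 — a track covering a fraction $c$ of the truth is
arc-length-stretched against the whole of it, and
$\int |truth(cs) - truth(s)|^2\,ds$ is large for $c \approx 0.5$
regardless of how faithfully the covered part was tracked. A streamline
distance in the $10^{-2}$ range is therefore not attainable by this
metric for tracks that genuinely fail to connect; the package reports the
honest value.

Problem sizes used throughout (tests and the acceptance script): curves of
$T = 100$ points, $20 \times 20$ grids, 30 training fibers, 5 truth
fibers, L-BFGS budgets of 10 epochs × 100 iterations; a full
single-seed experiment runs in well under a minute on one CPU and five
seeds in a few minutes.

# Known limitations

* 2D only: tensors are $2\times2$ and ODFs live on the circle; no 3D
  volumes, no spherical harmonics, no real-scanner tensor estimation.
* The dynamic-programming aligner cannot represent warps with boundary
  slope outside its lattice range; such orbit distances bottom out at the
  sampling-information floor rather than at zero.
* The prior energy evaluated through discrete alignment is only
  orbit-invariant up to the alignment residual, which the tail precision
  amplifies: rotations are recovered exactly, reparameterizations to a few
  percent of the energy.
* The mean-over-parameter data term can prefer detours through
  high-anisotropy regions when the curve must traverse expensive
  (ambiguous or isotropic) territory; the length term bounds but does not
  eliminate this, and the optional arc-length measure removes it at the
  price of re-coupling direction agreement with length.
* Closed curves, reflections, and endpoint (ROI-interior) relaxation are
  not supported; endpoints are exact points, fixed throughout.
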