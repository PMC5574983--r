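---
title: "Methods: multistability and phenotype switching in a two-gene circuit"
author: "phenoswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multistability and phenotype switching in a two-gene circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoswitch)
```

## The model

The package analyses a dimensionless two-gene circuit motivated by the
zeb1–cdh1 (ZEB1 / E-cadherin) axis of breast-cancer cells.  Gene 1 (`x1`,
the EMT driver) activates itself; gene 2 (`x2`, the epithelial gene)
activates itself and is repressed by gene 1:

$$\frac{dx_1}{dt} = a_1\frac{x_1^n}{\theta^n + x_1^n} + b_1 - k_1 x_1
  \equiv F_1(x_1),$$
$$\frac{dx_2}{dt} = a_2\frac{x_2^n}{\theta^n + x_2^n}
  + b_2\frac{\theta^n}{\theta^n + x_1^n} - k_2 x_2 \equiv F_2(x_1, x_2).$$

The activation and repression terms act additively ("or" logic): the
repression term is the unbound fraction of the promoter, so with `x1` high
gene 2 falls back on its self-activation alone.  All quantities are
dimensionless; there is no unit handling anywhere.  The constants default
to $k_1 = k_2 = 1$, $\theta = 0.5$, $n = 4$, $b_1 = 0.2$, $b_2 = 1$; the
two self-activation rates $a_1$ and $a_2$ are the biologically tunable
inputs ($a_1$ is the proxy for TGF-β signalling, $a_2$ for the
methylation state of the epithelial gene) and are the axes of the phase
diagram.  The Hill exponent is accepted as any real $> 0$ because the
multistability boundary is scanned continuously in $n$; powers are
computed as $e^{n\ln x}$ with $x = 0$ mapped to the limit 0.

Stable fixed points are labelled by where they sit relative to the Hill
threshold $\theta$, the model's only intrinsic concentration scale: high
`x1`/low `x2` is the basal state **B**, high/high the stem-like state
**S**, low/high the luminal state **L**.  All derived attractor
coordinates separate cleanly around $\theta = 0.5$.

```{r fixed-points}
p <- model_params(a1 = 0.8, a2 = 0.85)
find_fixed_points(p)
```

## Fixed points, scans, and the critical Hill coefficient

`F_1` does not depend on `x2`, so the system is a skew product and root
finding never needs a 2-D Newton iteration: the roots of `F_1` are
bracketed by a dense grid on `x1` (400 seeds per axis by default) and
polished by bisection; for each root `x0` the same is done for
`F_2(x0, ·)`.  Duplicates are merged at `1e-7` in max-norm and the output
is ordered by `(x1, x2)`, so results are deterministic.  The Jacobian is
lower triangular, hence the eigenvalues are its real diagonal entries;
a point is stable when both are negative and a saddle when they straddle
zero.  Eigenvalues within `1e-9` of zero trigger a warning ("unstable"),
which none of the package's reference regimes produce.  Every stable point
reported at the reference parameters is confirmed in the tests by forward
ODE integration of a perturbed start (an independent `deSolve` solve).

`phase_diagram()` and `bifurcation_scan()` re-solve the fixed points
pointwise over parameter grids; there is no continuation-style branch
tracking, which is adequate at the desk scales used here (a 151×151 phase
map takes a couple of minutes, the standard 131-point bifurcation sweep a
few seconds).  Decreasing $a_1$ at $a_2 = 0.8$ walks through the region
codes B → LB → LBS → LS → L with stable-point counts 1–2–3–2–1, the
model's account of how a transient pulse of TGF-β lets a motile basal cell
settle into the luminal state.

`critical_hill()` bisects the Hill exponent against a grid-scan
tristability test (any `(a1, a2)` cell with coexisting S, B and L).  Two
structural facts matter:

* S/B/L coexistence needs **two stable branches of the x1 subsystem**
  (L needs `x1 < θ`, B and S need `x1 > θ`).  The fold of
  $a_1 h(x_1) + b_1 - k_1 x_1$ disappears at the cusp
  $b_1/k_1 = \theta\,((n-1)/(n+1))^{(n+1)/n}$, so with the default
  $b_1 = 0.2$ no parameter choice is tristable below $n = 3.0194$.
  `critical_hill_cusp()` evaluates this closed form, and the test suite
  confirms it against a direct scan of the subsystem.  With $b_1 = 0.125$
  the same expression gives $n = 2.24$.
* near the cusp the bistable window in $a_1$ is **narrower than coarse
  grid spacings**, so the grid-scan detection threshold depends on the
  scan resolution: with the default 80×80 grid over $[0.05, 2]^2$ the
  bisection settles near $n = 3.46$, not at the cusp value.  The grid and
  ranges are exposed as arguments precisely because the detection, unlike
  the cusp bound, is resolution-limited.

The default bisection bracket `[2, 3]` therefore fails with an explicit
"does not straddle" error rather than returning a boundary value.

## Stochastic dynamics

The Langevin equations add independent Gaussian white noises of equal
intensity to both components,
$\langle\xi_i(t)\xi_i(s)\rangle = 2D\,\delta(t-s)$, representing the
combined intrinsic and extrinsic fluctuations of gene expression.
`simulate_sde()` uses Euler–Maruyama with default `dt = 1e-3`
(dimensionless time): the noise is additive and the drift smooth, so
higher-order schemes (Milstein) add nothing, and halving `dt` moves the
long-run occupancies by less than the replicate standard errors (checked
in the tests).  Concentrations are kept non-negative by reflection at the
origin (`x <- |x|`); the boundary treatment is a documented choice
(`boundary = "none"` disables it) since the density at the origin is
negligible at the noise levels studied.  All random numbers come from R's
RNG, so a seed makes every stochastic result bit-reproducible.

`estimate_occupancy()` assigns each post-burn-in sample to a basin by
deterministic relaxation — the sample is integrated with $D = 0$ until it
enters a small disk around one of the attractors — implemented as a
precomputed relaxation lookup grid so that assignment is
watershed-correct without ever constructing separatrices.  Euclidean
nearest-attractor assignment is available as a cheaper fallback.  The
defaults (8 replicates of 2000 time units with 200 burn-in, cycled across
starting attractors) resolve the occupancy trends at the reference
parameters with standard errors of about 0.01.

`first_passage_times()` samples passages from one attractor into a
max-norm capture disk of radius 0.05 around another (crossing the saddle
alone does not count); the radius is a documented knob and the reported
means shift by far less than a standard error under ±20% changes at the
noise levels studied.  Censored samples (`t_max`) are counted and a
warning is embedded when they exceed half the sample.

## The probability landscape

The stationary density of the 2-D Fokker–Planck equation
$$\partial_t P = -\partial_{x_1}(F_1 P) - \partial_{x_2}(F_2 P)
  + D(\partial^2_{x_1} + \partial^2_{x_2})P$$
is computed on a rectangular grid (default $[0,2]\times[0,2.5]$, 128×160
cells — comfortably beyond the invariant box
$[0,(a_1+b_1)/k_1]\times[0,(a_2+b_2)/k_2]$) with a conservative
finite-volume scheme.  Face fluxes use Scharfetter–Gummel exponential
fitting, $J = \frac{D}{h}[B(-w)P_L - B(w)P_R]$ with $w = vh/D$ and
$B(w) = w/(e^w-1)$, which is positivity-preserving, reduces to central
differencing for small cell Péclet numbers and to upwinding for large
ones, and is exact for locally linear potentials — important here because
advection dominates diffusion over most of the domain at $D = 0.02$.
Boundaries are no-flux, matching the reflecting convention of the
simulator.  Every column of the discrete operator sums to zero (discrete
mass conservation, tested to $10^{-10}$), so the stationary density is
the operator's null vector; it is found by one sparse direct solve with a
single row replaced by the normalization constraint, and the reported
residual is the stationary defect of the solution.  The effective
potential is $U = -\ln P$, with cells below $10^{-12}\max P$ masked
rather than mapped to huge finite values.

The same density can be estimated empirically: `histogram_landscape()`
bins supplied trajectories, and `sample_landscape()` streams an
arbitrarily long simulation through compiled code without materializing
it.  At the reference parameters and $D = 0.02$, three replicates of
$10^7$ Euler–Maruyama steps give a total-variation distance of about
0.02 from the Fokker–Planck solution — the package's strongest
cross-validation, since the two routes share no numerics.

Two caveats the landscape work makes explicit:

* at finite noise the modes of $P_{st}$ are shifted a few grid cells from
  the deterministic attractors (most visibly for the shallow L basin);
  the tests therefore require mode-to-attractor distances below 0.1
  rather than single-cell coincidence;
* basin masses saturate: `x2`-basin occupancy shifts steeply for
  $D \lesssim 0.05$ and then flattens, and the stem-like share even dips
  marginally (≈0.003) between $D = 0.07$ and $0.1$.  The qualitative
  trend — basal down, luminal and stem-like up — is a statement about the
  range, not about every increment, and the tests phrase it accordingly.

## One-dimensional switching theory

Because B and S share the same `x1` coordinate (the high stable root of
`F_1`), switching between them is well described by clamping
$x_1 = x_0$ and studying the 1-D gradient dynamics of `x2`.  For $n = 4$
the potential has the closed form implemented in `reduced_potential()`
(an arctangent/logarithm antiderivative of $-F_2$); for other exponents
the antiderivative is computed by adaptive quadrature.  The antiderivative
identity $U'(x_2) = -F_2(x_0, x_2)$ is verified to $10^{-8}$ at 1000
points in the tests — the strongest guard against transcription errors in
the closed form.

The exact mean first-passage time between the wells is the classical
double integral
$$\tau = \int_{y_1}^{y_2}\frac{dy}{D\,P_{st}(y)}
  \int_{0}^{y} P_{st}(k)\,dk, \qquad P_{st}(y)\propto e^{-U(y)/D},$$
evaluated by nested adaptive quadrature with the inner integrand rescaled
by $e^{(U(k)-U(y))/D}$ so no large exponentials are formed.  The textbook
lower limit $-\infty$ is replaced by the reflecting origin (the density
below 0 is negligible and concentrations are non-negative); the downhill
direction uses the mirrored form with the reflecting boundary above the
start.  The steepest-descent (Kramers) approximation
$$\tau = \frac{2\pi}{|U''(x_2^{st})\,U''(x_2^{u})|^{1/2}}
  \exp\!\Big[\frac{U(x_2^{u}) - U(x_2^{st})}{D}\Big]$$
is evaluated with the *deterministic* potential above.  One notational
point deserves care: recovering this formula from the exact integral via
steepest descent requires the potential in the exponent to be the
deterministic one (since $P_{st} \propto e^{-U/D}$), even though the
stationary-probability potential $-\ln P_{st}$ scales as $U/D$; the
package keeps the two objects distinct, and `barrier_heights()` accepts
either (the deterministic barriers are $D$-independent, the effective
ones are not).

```{r mfpt}
pot <- reduced_potential(p, stationary_x1(p, "high"))
barrier_heights(pot)
Dc <- find_noise_threshold(pot)
c(bisection = as.numeric(Dc), closed_form = attr(Dc, "closed_form"))
```

The threshold $D_c$ where $\tau_{BS} = \tau_{SB}$ is found by bisection;
for the Kramers method it also has the closed form
$D_c = (\Delta U_{u_1B} - \Delta U_{u_1S}) /
\tfrac12\ln(U''_B/U''_S)$, and the two agree to $10^{-6}$.  At the
reference parameters the barriers are
$\Delta U_{u_1B} = 0.0343$, $\Delta U_{u_1S} = 0.0112$ and
$D_c = 0.0828$: below it the stem-like-to-basal passage is faster, above
it the basal-to-stem-like one, so stronger fluctuations push the cell
toward the stem-like phenotype.

Consistency across methods is part of the test suite: the exact integral
agrees with Monte-Carlo passages of the clamped 1-D dynamics within three
standard errors at $D \in \{0.05, 0.08, 0.12\}$ (400 samples each), and
the integral-to-Kramers ratio approaches 1 from a 25% deviation as $D$
falls to 0.02.  The barriers here are shallow ($\Delta U/D \approx 1.7$
at $D = 0.02$), so the Kramers form is a structural approximation rather
than a numerically sharp one at physiological noise levels — which is why
the exact integral is always available.

A limitation the 1-D theory cannot escape: the full 2-D dynamics has an
additional exit channel from B through `x1` fluctuations (via the luminal
corridor) that the clamped reduction removes.  At $D = 0.02$ the 2-D
Monte-Carlo estimate gives $\tau_{BS} < \tau_{SB}$ — the opposite order
to the reduced theory — and, consistently, the 2-D stationary density
puts more mass on S than on B there.  Transitions involving L have no
closed-form reduction at all (no shared coordinate) and are served only
by the 2-D Monte-Carlo estimator.

## Problem sizes and defaults

The reference analyses use: 400 bracketing seeds per axis (root finding);
128×160 finite-volume cells; Euler–Maruyama `dt = 1e-3`; occupancy runs
of 8×2000 time units (200 burn-in); first-passage samples of 400;
histogram validation with 3×$10^7$ steps; an 80×80 `(a1, a2)` grid and
bisection width 0.02 for the critical Hill coefficient.  These sizes were
chosen so that every stochastic comparison is resolved at 2–3 standard
errors and every deterministic quantity is converged well beyond its
stated tolerance; all are arguments, not constants.

What the simulator does *not* emulate: discrete molecule numbers
(Gillespie dynamics), mRNA/protein two-stage kinetics, delays, additional
regulators (miR-200, SNAIL), or parameter fluctuations.  Passing tests
therefore validate the continuous Langevin model of this circuit, not the
full biology it abstracts.
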