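---
title: "Yield-stress arterial flow: model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield-stress arterial flow: model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbflow)
```

## The physical model

`hbflow` models steady, axisymmetric flow of blood through an arterial
segment whose wall departs from a straight tube in two ways: a slow linear
taper, and localised cosine-shaped abnormal segments — a *stenosis*
(narrowing, depth $\delta > 0$) or a *dilatation* (widening,
$\delta < 0$). Blood is treated as a Herschel–Bulkley fluid,

$$|\tau| = \tau_y + k\left(-\frac{\partial w}{\partial r}\right)^n,$$

which combines a yield stress $\tau_y$ (below it the material translates
as a rigid plug) with a power-law viscous response of index $n$ and
consistency $k$. Setting $\tau_y = 0$ gives a power-law fluid, $n = 1$ a
Bingham plastic, and both a Newtonian fluid; all four are reachable
through the named constructors `newtonian_fluid()`, `power_law_fluid()`,
`bingham_fluid()` and `hb_fluid()`. Whole blood at moderate shear rates
is well described by the shear-thinning case $n < 1$ with a small yield
stress.

All quantities are nondimensional: lengths in units of the normal lumen
radius $R_0$, stresses and the pressure gradient scaled by the
corresponding Newtonian reference flow. The flow rate $Q$ is the
volumetric rate *per* $\pi$, i.e. $Q = 2\int_0^R r\,w\,\mathrm{d}r$, so a
Newtonian tube with $q = 8$, $R = k = 1$ carries $Q = 1$.

### The lubrication (mild-stenosis) limit

The full two-dimensional momentum equations are not solved. For shallow,
slowly varying wall perturbations ($\delta/R_0 \ll 1$, radial length
scale much smaller than the axial one) the momentum balance reduces at
every axial station to that of locally fully developed tube flow: the
pressure is uniform over the cross-section and the local profile is the
exact Herschel–Bulkley pipe-flow solution at the local radius $R(z)$.
Everything the package computes follows from this local solution plus
one global constraint — the same flow rate $Q$ passes every station.

Two consequences worth keeping in mind:

* the axial velocity is everywhere nonnegative and the stream function
  is monotone in $r$, so genuinely two-dimensional features
  (recirculation eddies, trapped boluses, flow separation behind a steep
  stenosis) are outside the model by construction;
* accuracy degrades as $\delta$ grows or segments steepen; the default
  depth 0.2 over unit length is well inside the regime.

### Wall geometry

Within abnormal segment $i$, spanning $\alpha_i \le z \le \beta_i =
\alpha_i + l_i$,

$$R(z) = (1 - \zeta z)\left[1 - \frac{\delta_i}{2}\left(1 +
  \cos\frac{2\pi}{l_i}\Big(z - \alpha_i - \frac{l_i}{2}\Big)\right)\right],$$

and $R(z) = 1 - \zeta z$ elsewhere; $\zeta = \tan\phi$ is the taper
slope. The cosine factor vanishes at both segment ends, so the wall is
continuous everywhere, and reaches its extremum $(1-\zeta z)(1-\delta_i)$
at the midpoint. Segment positions accumulate left to right from
gap/length pairs ($\alpha_i = \sum_{j\le i}(d_j + l_j) - l_i$), which
makes overlap impossible by construction; the only rejected layout is a
segment extending past the tube end.

The **default demonstration geometry** (`default_geometry()`) is a tube
of length $L = 7$ with a stenosis of depth $0.2$ on $z \in [2,3]$ and a
dilatation of depth $0.2$ on $z \in [5,6]$, taper $\zeta = 0.01$. The
dilatation placement was a genuinely open choice: its midpoint at
$z = 5.5$ gives a crest radius of $0.945 \times 1.2 = 1.134$, which is
the configuration all reference midpoint values in the test suite are
computed at. The package expresses any placement; only the default is
fixed to this layout.

## Local solution and the pressure gradient

With $q = -\mathrm{d}p/\mathrm{d}z$ the local pressure gradient, the
shear stress is $\tau = rq/2$, so the plug occupies $r \le R_p =
2\tau_y/q$ and the wall shear stress is $\tau_w = Rq/2$ exactly,
independent of the constitutive law. Writing $m = (n+1)/n$, $s = R_p/R =
\tau_y/\tau_w$ and $A = \frac{n}{n+1}(q/2k)^{1/n}R^m$, the velocity is

$$w(r) = A\left[(1-s)^m - \left(\frac{r}{R} - s\right)^m\right]
  \quad (r \ge R_p),$$

constant at $w_p = A(1-s)^m$ in the plug. Integrating $2rw$ gives the
exact flow-rate relation

$$Q = \frac{nR^3}{3n+1}\left(\frac{qR}{2k}\right)^{1/n}(1-s)^{(n+1)/n}
  \left[1 + \frac{2n}{2n+1}s + \frac{2n^2}{(2n+1)(n+1)}s^2\right],$$

implemented in this $s$-form (rather than with $R_p/2R$-type terms) to
avoid cancellation at small $s$. Its $n = 1$ reduction is the
Buckingham–Reiner equation, which the tests use as an independent
cross-check.

### Newton–Raphson solution (`solve_pressure_gradient`)

Prescribing $Q$ makes the relation above an implicit equation for $q$.
It is solved in residual form, LHS $-$ RHS with
$\mathrm{LHS} = (3n+1)Qx^3/(nR^2)$, whose root is bracketed by a sign
change: the residual is positive just above the admissible lower bound
$x = 2\tau_y/R$ and negative for large $x$ (the RHS grows like
$x^{3+1/n}$). Numerical choices:

* **initial guess**: the first-order expansion $q_0 + q_1\tau_y$ (below),
  which is already within a few percent for physiological yield stresses;
* **damping**: any Newton step that would leave the admissible region
  $x > 2\tau_y/R$ is halved until feasible;
* **convergence**: both the relative step and the residual relative to
  the LHS must fall below `tol` ($10^{-12}$ by default, giving
  $\sim$10–12 significant digits); `max_iter` defaults to 100;
* **vectorisation**: all radii of an axial grid iterate simultaneously,
  so a whole-vessel solve is a handful of vectorised sweeps;
* $\tau_y = 0$ short-circuits to the closed form — the expansion's
  leading term is then exact.

There is no randomness anywhere in the package; identical inputs give
bit-identical outputs.

### Small-yield-stress expansion (`q_analytical`)

For $\tau_y/\tau_w \ll 1$ the pressure gradient admits the expansion

$$q_a = \underbrace{\frac{2k}{R^{3n+1}}\Big(\frac{(3n+1)Q}{n}\Big)^n}_{q_0}
 + \frac{2(3n+1)}{(2n+1)R}\,\tau_y
 + C(n)\,\frac{n^n R^{3n-1}}{2k\,((3n+1)Q)^n}\,\tau_y^2 .$$

The first two terms are exact perturbation results ($q_0$ is the
power-law closed form). The quadratic coefficient is *not* derived here:
a direct second-order perturbation of the flow-rate relation gives a
coefficient proportional to $n(n-1)$, which vanishes for Bingham fluids
and does not reproduce the behaviour of the exact root. The package
therefore treats $C(n)$ as a calibrated polynomial,

$$C(n) = \frac{42n^3 + 56n^2 + 26n + 4}{(2n+1)^4 (n+1)^2},
  \qquad C(0.8) \approx 0.5548,$$

validated against the Newton–Raphson root: at the default stenotic
configuration the relative deviation stays below 1.5% up to
$\tau_y = 2.4$, and below 6.5% at the dilatation crest (the expansion
degrades in wide sections because $\tau_w$ is smaller there, so
$\tau_y/\tau_w$ is larger). Because the coefficient is a calibration,
`q_analytical()` accepts any replacement through its `quad_coef`
argument, and `hb_quadratic_coef()` is exported so users can inspect or
modify it. The deviation bounds above are exactly what
`pressure_gradient_table()` computes and the test suite asserts.

## Axial assembly: profiles and flow resistance

`hb_flow()` evaluates $q(z)$, $\tau_w(z) = Rq/2$ and the cumulative flow
resistance

$$\lambda(z) = \int_0^z \frac{q(z')}{Q}\,\mathrm{d}z'$$

over the whole vessel and returns them as a classed model object with
`print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods.
`residuals()` reports the implicit-relation residual at every station
relative to its LHS — at solver tolerance for a `"numerical"` fit, and a
direct measure of truncation error for an `"analytical"` fit.

Quadrature: $q(z)$ is continuous but its derivative is kinked where
segments meet the taper line, so every integral is split at segment
boundaries and each smooth piece gets its own uniform composite-Simpson
grid. The default spacing `dz = 0.001` (7001 stations on the default
vessel) makes the quadrature error negligible against the modelling
error; the cumulative value at interior nodes uses the exact integral of
the per-pair fitted parabola, which coincides with composite Simpson at
pair boundaries. Analytical-mode resistance integrates the expansion
term by term, $a\int R^{-(3n+1)} + b\int R^{-1} + c\int R^{3n-1}$, over
the same split grids.

## Stream function

The Stokes stream function is the exact antiderivative of $rw$,
constructed so that $w = (1/r)\,\partial\psi/\partial r$, $\psi(0) = 0$
and continuity (of value and slope) holds at the plug boundary:

$$\psi = \frac{w_p r^2}{2} \;\; (r \le R_p), \qquad
\psi = \frac{w_p R_p^2}{2} + A\left[(1-s)^m\frac{r^2 - R_p^2}{2}
 - R^2\left(\frac{n\,u^{(3n+1)/n}}{3n+1} +
            \frac{s\,n\,u^{(2n+1)/n}}{2n+1}\right)\right]$$

with $u = r/R - s$. Mass conservation gives $\psi(R) = Q/2$ at *every*
station, which is the sharpest global invariant the tests check
($10^{-8}$ relative). `field_grid()` evaluates $w$ and $\psi$ on a
signed $r/R \in [-1, 1]$ grid for contour plots; the negative half is a
pure mirror, no asymmetry is modelled. Because $\psi$ is monotone in
$r$ here, streamline patterns show contours bending toward the axis
through a stenosis and away through a dilatation — closed recirculation
boluses cannot occur in this lubrication-limit field.

## Parameters at a glance

| parameter | meaning | default | notes |
|---|---|---|---|
| `n` | power-law index (–) | 0.8 | shear thinning; $n=1$ Bingham/Newtonian |
| `k` | consistency index (–) | 1.2 | nondimensional |
| `tau_y` | yield stress (–) | 0.1 | plug radius $2\tau_y/q$ |
| `Q` | flow rate per $\pi$ (–) | 1 | prescribed, constant along the tube |
| `zeta` | taper slope $\tan\phi$ | 0.01 | $>0$ converging |
| `delta` | segment depth (–) | $\pm 0.2$ | $<1$; negative = dilatation |
| `dz` | axial grid spacing | 0.001 | Simpson quadrature and profiles |
| `tol` | Newton tolerance | $10^{-12}$ | relative step and residual |

The defaults are the standard configuration every reference value in
the test suite is computed at: $n = 0.8$, $k = 1.2$, $Q = 1$,
$\zeta = 0.01$, depth-0.2 segments.

## Degenerate inputs and edge behaviour

* A state with $R_p \ge R$ (yield stress not exceeded at the wall) is an
  **error**, not $Q = 0$: with a prescribed positive flow rate such
  states cannot arise from a consistent solve, so they always indicate
  bad input.
* $\tau_y = 0$ bypasses the iteration entirely (closed form).
* An occluding stenosis ($\delta \ge 1$), a taper that closes the tube
  ($1 - \zeta L \le 0$), overlapping or out-of-range segments, and
  evaluation outside $[0, L]$ are all rejected at construction with the
  offending quantity named.
* Configuration files are parsed strictly: unknown keys are an error, so
  misspelt parameters cannot silently fall back to defaults.

## What the tests do and do not establish

The suite checks the implementation against independent routes: plain
bisection against Newton–Raphson, adaptive quadrature of $r\,w$ against
the closed-form flow rate, Buckingham–Reiner against the $n = 1$
reduction, finite differences of $\psi$ against $w$ and of $\lambda$
against $q/Q$, plus the conservation invariant $\psi(R) = Q/2$ and the
ordering properties (wall shear extremes at segment midpoints,
resistance increasing with stenosis depth and converging taper). Axial
fits in the tests use `dz` between 0.005 and 0.05 — coarser than the
default, chosen so the full suite runs in seconds; the quadrature
properties asserted are grid-robust. All of this validates the model's
internal consistency and its stated numerical targets; it does not
validate the lubrication approximation itself against resolved 2-D flow
or measured arterial data.
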