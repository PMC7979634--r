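---
title: "Designing Turing systems on prescribed parameter regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Turing systems on prescribed parameter regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(turingkit)
```

## The problem and the model

A two-species reaction–diffusion system

$$u_t = \nabla^2 u + f(u,v), \qquad v_t = D\,\nabla^2 v + g(u,v)$$

on a domain with zero-flux boundaries undergoes a Turing (diffusion-driven)
instability when a homogeneous steady state that is stable without
transport is destabilised by a band of finite-wavelength perturbations.
`turingkit` solves the *inverse* design problem: given a user-chosen scalar
level-set function $S(\mathbf p)$ over kinetic parameters
$\mathbf p$, construct polynomial kinetics whose Turing space is exactly
$\Omega = \{S(\mathbf p) > 0\}$, with additional control over the morphogen
phase relation, the 2D pattern type (spots versus stripes), the location of
the steady state, and spatial/temporal parameter heterogeneity.

With the convention $f_u > 0$, a Turing-capable Jacobian has either the
*pure* sign pattern $(+,-;+,-)$ (morphogen peaks aligned) or the *cross*
pattern $(+,+;-,-)$ (peaks anti-aligned). Rescaling time by $1/f_u$ and
length by $\sqrt{D_u/f_u}$ collapses the linearization onto three groups,
$F = |g_u| f_v / f_u^2$, $G = |g_v|/f_u$, $D = D_v/D_u$, and the classical
inequalities reduce to

* $F > G > 1$, equivalently $F' > G' > 0$ with $F' = F-1$, $G' = G-1$;
* $D > D_c = (\sqrt{F-G} + \sqrt F)^2$ (`criticalDiffusion`);
* the domain admits an unstable cosine mode: $k = n\pi/L$ must fall in the
  band $k_\pm^2 = \frac{(D-G) \pm \sqrt{(D-G)^2 - 4D(F-G)}}{2D}$
  (`wavenumberBand`), so the smallest patterning interval is
  $L_c = \pi/k_+$ (`minDomainLength`).

Choosing $F' = S(\mathbf p) + 1$ and $G' = 1$ makes the kinetic criterion
hold exactly on $\Omega$. The offset $\eta = 1$ in $F' = S + \eta$,
$G' = \eta$ is fixed rather than exposed: the solved constant coefficient of
$g$ equals $G = \eta + 1$, and positivity of that coefficient (hence
positivity of trajectories near the origin) would be lost for the
alternative assignment $G' = S$, which goes negative off-region.

## The kinetic families

All families come from solving $f(U,V) = g(U,V) = 0$ plus the prescribed
Jacobian on a fixed monomial ansatz; each constructor records its target
Jacobian, and `verifyKinetics` recomputes residuals and a 5-point-stencil
numerical Jacobian (exact for these polynomials up to rounding, which is
why the pass threshold can sit at $10^{-10}$).

* `buildCross(S)`: $f = -u + u^2 v$, $g = 2 + S v - (S+2) uv$, Jacobian
  $[[1, 1], [-(S+2), -2]]$ — determinant $S$, trace $-1$.
* `buildPure(S)`: $f = u^2 - uv$, $g = 2 - (S+4) v + (S+2) uv$ — same
  determinant and trace with the in-phase sign structure. A note on
  labels: the cross family's sign pattern is $(+,+;-,-)$ even though its
  $u$-equation coincides with the classic activator–depletion form often
  called "pure" in the literature; the package always classifies by the
  realised sign structure, which is what fixes the phase relation.
* `buildFromFG(F, G, signType)`: direct parameterisations such as the
  circular-region example $F = 2 - a^2$, $G = 1 + b^2$ (`circleRegion`).
* `buildPhaseSwitching(a, b)`:
  $f = -u + (4-a)u^2 + (a-3)u^2v$,
  $g = (b^2+1) + (3-a)uv + (a-4-b^2)v$, Jacobian
  $[[1, a-3], [-(a-3), -(b^2+1)]]$. On the two-branch region
  $(a-3)^2 - b^2 \ge 1$ (`hyperbolicRegion`) this is pure for $a<3$ and
  cross for $a>3$, so the phase flips between branches. At $a = 3$ the
  $u$-equation degenerates to $u^2 - u$ and blows up in finite time;
  construction is refused unless the saturation guard
  ($u^2 \mapsto u^2/(1+\varepsilon^2u^2)$, default off,
  $\varepsilon = 0.05$) or an explicit override is requested. The guard
  preserves the steady state and Jacobian only to $O(\varepsilon^2)$;
  `verifyKinetics` reports that drift rather than hiding it.
* `buildAtSteadyState(U, V, S)`: the cross construction re-solved about an
  arbitrary positive steady state, used for image-valued prepatterns where
  $U(x)$ encodes a picture. Positivity of trajectories when $V < U$ (the
  constant coefficient $a_1 = V-U$ goes negative) is *not* guaranteed;
  simulations monitor positivity instead of promising it.
* `withCubic(sys, C)`: subtracts $C (u-U)^3$ from $f$. The term has zero
  value and first derivative at the steady state, so every linear quantity
  is unchanged (tested to $10^{-13}$), but as $C$ grows the cubic
  nonlinearity overtakes the quadratic one and 2D patterns shift from
  spots to stripes/labyrinths. The subtracted sign keeps trajectories
  bounded; negative $C$ is rejected.

For $\alpha > 2$ the quadratic-order monomial generalises
($a_1 = \alpha-2$, $b_1 = 1-\alpha$, $c_1 = 1$ for cross), giving further
members of the family.

With $S = -1$ inside a prepattern region the local determinant is negative,
so the $k=0$ linearization there is a saddle; pinning an inner region to a
heterogeneous state in the prepattern recipes relies on nonlinear and
heterogeneous effects (a large cubic $C$, small effective diffusion) that
the linear theory does not cover, and the package makes no stability claim
for it.

## Suprema over regions and the recommended diffusion ratio

`supOverRegion` evaluates $S$, $F$, $D_c$ or $L_c$ on a dense grid over the
region's bounding box (default $401\times401$), masks the closed region
$\{S \ge 0\}$, and refines by repeatedly zooming a $41\times41$ grid onto
the incumbent maximiser. Nested scanning (rather than a fitted quadratic
step) was chosen because suprema of these quantities routinely sit on the
region or box boundary — the hyperbolic region's $D_c$ supremum
$17 + 12\sqrt2 \approx 33.97$ is attained at a corner — where local
quadratic models are ill-posed. The procedure is deterministic at fixed
resolution.

`recommendDiffusion` reports both the sharp bound
$\sup_{\bar\Omega} D_c$ and the simpler conservative rule $4\sup F$
(which always exceeds $D_c$ because
$(\sqrt{F-G}+\sqrt F)^2 < 4F$). On the circular region these evaluate to
$(1+\sqrt2)^2 \approx 5.8284$ and $8$; at $D = 8$ the minimum-domain
supremum is $4\pi/\sqrt{7+\sqrt{17}} \approx 3.7679$, reproduced by the 1D
experiment below.

## Numerical protocol

Space is discretised by the standard 3-point (1D) / 5-point (2D) Laplacian
with the second-order mirror closure; with trapezoid weights the discrete
diffusion operator conserves mass exactly, and its eigenvalues converge at
$O(h^2)$ to the dispersion relation — both are tested. Time integration
uses the sparse stiff BDF solver (`deSolve::lsodes` with the built-in
1D/2D stencil sparsity): diffusion is treated fully implicitly, the local
error is controlled at `rtol = 1e-5`, `atol = 1e-8` by default, and the
internal step is capped at `dtMax = 10`. A reaction-explicit splitting was
rejected during development because its stability bound on the reaction
part caps the step near $\Delta t \approx 2$ through the entire long
stopping tail, an order of magnitude more steps than the implicit BDF
needs.

The run protocol follows the design brief: initial conditions are uniform
i.i.d. perturbations of total width `icRange = 0.1` about the (possibly
heterogeneous) steady state — "range" is read as total spread, i.e.
$\pm 0.05$; the `icMode = "halfwidth"` switch gives the $\pm 0.1$ reading,
and classification outcomes are insensitive at these amplitudes — and a run
is converged when $\sup|\partial_t(u,v)| < 10^{-3}$ with $t \ge 10^4$,
subject to a hard cap `tMax = 5e4`. Because the sup-derivative of a BDF
solution carries a local-error noise floor amplified by the stiff diffusion
eigenvalues, the convergence check re-integrates 50 time units at
$10^{3}\times$ tighter tolerance (at most twice per run) before declaring
non-convergence. Blow-up (non-finite values, excursions beyond `1e6`, or a
stalled integrator) raises a typed error carrying the failure time; the
$a=3$ switching system exercises it. Scheduled parameters are compiled into
piecewise-constant epochs and the solver restarts at every switch, which
resolves the square-wave forcing exactly instead of relying on step-size
luck.

Default resolutions keep at least 8 nodes per predicted wavelength
$2\pi/k_{\max}$ (`patternWavelength`), with the reference experiments run
at 256 nodes (1D) and $128^2$ (2D $50\times50$); `refineCheck` reruns any
configuration at halved mesh size with the same coarse initial condition
interpolated onto the fine grid and compares classifications, which is the
grid-independence argument used throughout the test suite.

### The marginal G = 1 boundary

The circular-region example evaluated at $a = b = 0$ has $G = 1$: the
$k=0$ mode's trace is exactly zero, a linear centre. Simulations develop
the designed mode-1 pattern (amplitude $\approx 0.23$ for $L = 3.8$) but
retain a fraction-of-a-percent neutral oscillation of the spatial mean that
decays only through weak nonlinear damping, so the formal derivative
criterion does not fire within the time cap; the same marginality makes the
$b = 0$ rays of the polar sweep oscillate indefinitely. The package flags
these configurations as `marginal` in the Turing report and proceeds —
the final-state classification (patterned versus homogeneous, mode count,
phase) is insensitive to the residual oscillation. For the same reason the
region-fidelity sweep is classified at $t \approx 10^3$, after pattern
amplitudes ($\approx 3.5$) have saturated by several e-foldings of the
slowest relevant growth rate, while the domain-size bifurcation and the
phase-law and cubic experiments run the full $t \ge 10^4$ protocol.

## Pattern classification

The classifier is a declared convention validated on constructed inputs
(the underlying visual judgement has no published operational definition):

* amplitude = max − min; below `hetTol = 0.05` a field is homogeneous
  (pattern amplitudes here are $O(1)$, linear-decay residuals are far
  smaller);
* 1D mode count = sign changes of the mean-centred profile, so a
  half-cosine boundary peak counts as mode one (peak counting would not);
* 2D: threshold at the mean, label connected components
  (8-connectivity, `EBImage::bwlabel`), compute circularity $4\pi A/P^2$
  per component; median $\ge 0.6$ with no domain-spanning component gives
  spots, median $< 0.4$ (or a component longer than three wavelengths)
  gives stripes, otherwise mixed — the mixed label exists because
  oscillating stripe regimes intermittently degenerate into spots;
* phase = sign of the Pearson correlation of the mean-centred fields at
  threshold 0.5, indeterminate below it or for near-homogeneous fields;
* `classifyBySegment` repeats the 2D classification inside each prepattern
  segment, thresholding at the segment mean and clipping components at the
  segment boundary, with a low-confidence flag for segments smaller than
  four squared wavelengths.

The decision is invariant under positive affine rescaling of the field and
under grid rotation (tested), and circularity is computed from
boundary-pixel counts and clamped at 1.

## Heterogeneity and images

Spatial steps default to tanh smoothing of width one grid cell (a sharp but
smooth interface); square-wave schedules alternate two value sets every
half period starting from the "on" branch at $t = 0$, so a period of 6000
switches the parameters every 3000 time units. Grayscale PNG/PGM images
map to parameters by intensity thresholding (`imageToSegments`; labels run
0 = brightest to darkest, row 1 of the image sits at $y = L_y$) with
per-label parameter mappings (`segmentsToParams`; the shipped presets give
the spot/stripe/inverse mapping and the prepattern-preserving mapping), or
continuously by inverse intensity into the steady-state field
(`intensityToSteadyState`). Threshold choices for photographs are
unspecified upstream, so defaults are k-quantiles with user override, and
all image tests run on `makeFixtureImage` rasters generated in code — no
photograph assets ship with the package.

## What the synthetic experiments do and do not show

The generator-driven experiments reproduce the designed behaviour of the
families on idealised rectangles: instability exactly on $\Omega$, the
domain-size threshold, the phase law, and cubic pattern selection. They do
not probe curved or growing domains, non-polynomial kinetics, stochastic
low-copy-number effects, three or more species, or the dynamics outside
$\Omega$ beyond the guaranteed $k = 0$ instability for $S < 0$ — for
$S < 0$ the steady state is a saddle and trajectories leave it, either
toward a boundary equilibrium such as $(0, G/(G-F))$ (classified
homogeneous) or along the diverging tail (recorded as a blow-up) — which of
the two depends on the random initial draw, and neither is a pattern. The
solver flushes magnitudes below $10^{-150}$ to zero so that a species
decaying to extinction freezes cleanly, and aborts as soon as any field
exceeds the blow-up bound. Quantitative statements about real chemical or
biological systems additionally require the dimensional scales that the
nondimensionalisation absorbs.

## Problem sizes used by the shipped experiments

Analytic suprema scan $401^2$ grids with four zoom refinements. The 1D
bifurcation experiment uses 256 nodes at $L \in \{3.7, 3.8\}$, three seeds
each, capped at $t = 1.5\times10^4$ (the marginal case never formally
converges, as discussed). The phase-law and cubic experiments use
$128^2$ nodes on $50\times50$ domains with the full protocol; the polar
sweep uses $96^2$ and the shortened horizon justified above. These sizes
satisfy `refineCheck` and keep the complete suite within an ordinary
workstation coffee break.
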