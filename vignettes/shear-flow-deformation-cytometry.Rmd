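---
title: "Methods: shear flow deformation cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shear flow deformation cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `shearcyte`, the
assumptions behind them, the numerical choices, and the design decisions
made where the problem left room for judgment. It states no empirical
result beyond what the package's test suite and `scripts/acceptance.R`
themselves compute.

## 1. Measurement principle

A suspended cell is, at rest, a sphere of radius $r_0$. Pumped through a
long channel of square cross section in a viscous medium, it experiences
a local shear stress $\sigma(y)$ that grows from zero at the channel
center line to a maximum at the walls, and a local shear rate
$\dot\gamma(y)$ that makes it rotate internally (tank-treading) while
its deformed, ellipsoidal envelope stays stationary. Because the channel
is centimeters long, every analyzed cell has completed many rotations
before it is imaged: the shape is a *steady state*, and no transient
viscoelastic response function needs to be assumed. Five measurable
quantities determine the mechanics of each cell: the local stress, the
local shear rate, the local fluid viscosity, the cell's shape
$(a, b, \beta)$, and its tank-treading frequency.

## 2. Channel fluidics

**Stress field.** `shear_stress()` implements the classical series
solution for laminar uniaxial flow in a rectangular duct, summed over
the first 100 odd terms (indices $n = 1, 3, \dots, 199$; the sum is
defined over odd $n$ only). The series is evaluated with the hyperbolic
ratio $\sinh(n\pi y/H)/\cosh(n\pi W/2H)$ rewritten in log space because
both factors overflow `double` beyond $n \approx 140$. Increasing the
term count from 100 to 400 changes the stress near the wall by less
than 0.1%, which the test suite asserts. The field is linear in the
driving pressure and independent of the fluid viscosity; entrance and
exit effects are neglected (valid for $L \gg W$).

**Fluid rheology.** The suspension medium is shear thinning and modeled
by the Cross law $\eta(\dot\gamma) = \eta_0/(1 + (\tau\dot\gamma)^\delta)$
with zero-shear viscosity $\eta_0$ (Pa s), relaxation time $\tau$ (s)
and exponent $\delta \in [0, 1)$. `solve_shear_rate()` inverts
$\sigma = \eta(\dot\gamma)\dot\gamma$ by Newton–Raphson on
$0 = \sigma/\eta_0 - \dot\gamma + (\sigma/\eta_0)\tau^\delta\dot\gamma^\delta$,
starting just right of the residual's maximum
$\dot\gamma^* = (c\delta)^{1/(1-\delta)}$ (offset
$10^{-6}\,\sigma/\eta_0$), where the residual is concave and Newton
iterates converge monotonically; a bisection fallback guards the rare
non-convergent case. Tolerance is $10^{-12}$ relative, 100 iterations
maximum.

**Velocity profile.** `velocity_profile()` integrates the shear rate
from the no-slip wall with composite 5-point Gauss–Legendre panels
(at least 8 panels, at most one per 2.5 µm). The Newtonian special case
is checked against the closed-form double-series duct solution to 0.5%.

**Fitting the fluid from cell speeds.** `fit_fluid_rheology()` finds
$(\eta_0, \tau, \delta)$ by minimizing *relative* squared speed
residuals with a multi-start Nelder–Mead simplex on
$(\log\eta_0, \log\tau, \mathrm{logit}\,\delta)$. Relative weighting is
the statistically appropriate choice for multiplicative speed noise and
keeps the slow near-wall cells — which carry the shear-thinning
information — from being swamped by the fast center cells. Internally
the objective evaluates the profile once per parameter set on a
129-point cumulative quadrature grid and splines it to the sample
positions, which makes the fit fast enough for thousands of cells.

*Identifiability.* A single-pressure velocity profile constrains the
exponent $\delta$ and the viscosity curve $\eta(\dot\gamma)$ over the
shear rates actually present in the channel very well. The plateau
parameters $(\eta_0, \tau)$, by contrast, are extrapolations to
$\dot\gamma \to 0$: whenever $\tau\dot\gamma \gg 1$ over most of the
channel they are identified only through a thin region near the center
line and carry sampling variability of tens of percent, wandering along
a ridge of nearly constant $\eta_0/\tau^\delta$. The package therefore
tests the fitted *viscosity curve* rather than the plateau parameters on
simulated tables, and reports the fit's RMS velocity residual.

## 3. Cell detection

Images are z-score normalized, thresholded (default $z > 3$),
morphologically closed, hole-filled, and labelled (EBImage). An ellipse
is fitted to each component from its second central pixel moments
(semi-axes $2\sqrt{\lambda_i}$ of the covariance eigenvalues, with the
$1/12$ variance of a unit pixel added; orientation along the principal
eigenvector, folded to $(-90°, 90°]$, defined as 0 for near-circular
masks). Shape quality is controlled by two filters: solidity (pixel
count over convex-hull pixel count, computed via Pick's theorem on the
hull of pixel centers) at a default minimum of 0.95, and agreement of
the contour length with the fitted ellipse perimeter (Ramanujan
approximation) within 10%. These two thresholds are engineering
defaults — they reject cell doublets and ragged segmentations in
rendered data — and are exposed in the pipeline configuration. A third
filter excludes cells closer than one equivalent radius
$r_\mathrm{eq} = \sqrt{ab}$ to the channel center, where the stress is
non-monotonic across the cell body and deformations are too small to
invert reliably.

Tracking is greedy nearest-neighbor linking between consecutive frames
in a weighted $(x_\mathrm{pred}, y, a, b)$ space (weights 1, 4, 2, 2),
gated by $|\Delta y| < 5$ µm; the per-track speed is the mean
frame-to-frame $x$ displacement times the frame rate. The acquisition
constraint $fr > v_\mathrm{max}/(0.5\,\mathrm{ROI}_x)$ (each cell must
be caught in at least two consecutive frames) is checked and reported as
a warning, not an error.

## 4. Viscoelastic inversion

**Normalization.** Only $a$ and $b$ are observable; incompressibility
fixes $\tilde a\tilde b\tilde c = 1$. The package takes the vorticity
axis as undeformed ($\tilde c = 1$), hence
$\tilde a = \sqrt{a/b}$, $\tilde b = \sqrt{b/a}$, $r_0 = \sqrt{ab}$.
This is the natural convention for planar shear of an incompressible
sphere; if the true $c$-axis deformation were substantial, the shape
integrals at large strain would shift accordingly (a known limitation).

**Shape integrals.** The ellipsoid integrals
$g_i'' = \int_0^\infty \lambda\,d\lambda/((\cdot)(\cdot)\Delta')$ and
$g_3' = \int_0^\infty d\lambda/((\tilde a^2+\lambda)(\tilde b^2+\lambda)\Delta')$
with $\Delta' = \sqrt{(\tilde a^2+\lambda)(\tilde b^2+\lambda)(\tilde c^2+\lambda)}$
are evaluated by adaptive quadrature (`stats::integrate`, relative
tolerance $10^{-11}$). For a sphere each $g''$ equals $4/15$ and
$g_3' = 2/5$, hence $I = 1$ and $K = 4/25$ — closed forms the test suite
verifies to $10^{-6}$. Because the integrals depend only on the axis
ratio when $\tilde c = 1$, they are tabulated on 400 log-spaced ratios
in $[1, 20]$ with monotone cubic (`monoH.FC`) interpolation; the table
agrees with direct quadrature to better than 0.1% and falls back to
quadrature outside its range.

**Storage modulus.** $\epsilon = (\tilde a^2 - \tilde b^2)/(2I)$ and
$G' = \tfrac52\,\sigma\sin(2\beta)/\epsilon$. Records with
$\epsilon \le 0$ or $\sin 2\beta \le 0$ are flagged invalid (`NA`), not
raised as errors, and excluded from population statistics.

**Loss modulus.** The alignment angle of a tank-treading viscoelastic
sphere obeys

$$\cos 2\beta \;=\; A\,
\frac{1 + \tfrac25 x\,Q}{1 + \tfrac25 x\,P},
\qquad
A = \frac{\tilde a^2-\tilde b^2}{\tilde a^2+\tilde b^2},\quad
P = \frac1K\Big(\frac{\tilde a^2+\tilde b^2}{2\tilde a\tilde b}\Big)^2,\quad
Q = \frac1K\Big(\frac{\tilde a^2-\tilde b^2}{2\tilde a\tilde b}\Big)^2,$$

which is linear in the viscous contrast $x = (\eta - G''/\omega_d)/\eta$
and solved in closed form (branch-free):
$x = (\cos 2\beta - A)\,/\,(\tfrac25(AQ - P\cos 2\beta))$,
$G'' = \omega_d\,\eta\,(1-x)$. Here $\omega_d$ is the *kinematic*
deformation frequency of the internal circulation,
$\omega_d = \dot\gamma\,2\tilde a\tilde b/(\tilde a^2+\tilde b^2)$
(`deformation_frequency()`), i.e. twice the Jeffery rotation rate of the
shape; for a sphere $\omega_d = \dot\gamma = 2\cdot(\dot\gamma/2)$,
identical to twice the Einstein tank-treading rate, so the convention
coincides with $2\omega_{tt}$ at low shear rates.

Two properties fix this form. First, the limits are physical: a purely
elastic cell ($G'' = 0$, $x = 1$) sits at $\beta \to 45°$ for small
strain, and cells whose internal viscous stress exceeds the fluid's
($x$ increasingly negative) elongate and align toward the flow
direction, reaching $\beta \approx 15\text{–}35°$ at strains near 1 —
the behavior actually observed in such experiments. Second, the inverse
is well conditioned: with the shear-rate-based $\omega_d$ the
dimensionless contrast stays of order one even near the walls, so a
realistic orientation noise of a fraction of a degree propagates to a
$G''$ error of order 20%, not a sign flip. Writing the same relation
with the *measured* (empirically lagged) rotation rate in place of the
kinematic one pushes $G''/(\omega\eta)$ to $\sim$10 near the walls, a
regime in which the relation admits no flow-aligned steady state at all
and the inversion becomes numerically meaningless — so the kinematic
frequency is the only self-consistent reading. The *reporting* frequency
of the extracted moduli remains $\omega = 2\cdot 2\pi f_{tt}$ with the
measured (or predicted) tank-treading frequency, since that is the rate
at which the material is actually cycled.

## 5. Tank treading

`measure_tanktreading()` computes dense optical flow between consecutive
cell crops, maps each interior pixel to its ellipse-corrected radius
$\tilde r$ (radial position divided by the ellipse radius at that polar
angle), and regresses the ellipse-normalized tangential speed through
the origin against $\tilde r$ for $\tilde r < 0.7$; under rigid rotation
the normalized speed equals $\omega_{tt}\tilde r$, so the slope *is*
$\omega_{tt}$ in rad/s. The through-origin form is chosen precisely for
this identity. Pixels near the boundary are excluded to avoid edge
artefacts; results with fewer than 10 usable pixels or $R^2 < 0.2$ are
discarded and the caller falls back to the master relationship
$\omega_{tt}(\dot\gamma) = (\dot\gamma/2)/(1+(0.113\dot\gamma)^{0.45})$
(labelled `method = "predicted"`). The relationship approaches the
Einstein limit $\omega_{tt}/\dot\gamma = 1/2$ for small shear rates and
holds for tank-treading cells in viscous media; tumbling regimes (e.g.
red blood cells at low shear rates) are out of scope.

The flow backend is an iterative dense Lucas–Kanade estimator (central
differences, per-pixel 2×2 normal equations over a square window, three
warp refinements with bilinear resampling) behind a pluggable contract:
two patches in, per-pixel displacement out. Two choices matter. Crops
are high-pass filtered (subtraction of a $\sigma = 5$ px Gaussian blur)
before flow, so the estimator responds to the rotating internal texture
rather than the static cell-body shading. And the integration window is
deliberately small (7×7): on rendered rigid rotations, larger windows
oversmooth the rotational field near the texture boundary and bias the
fitted rate upward by up to 20%, while the 7×7 window recovers a
10 rad/s rotation to better than 1% — the property the test suite
asserts at its 5% tolerance. Rotation direction (upper vs lower half of
the channel) is recorded but only the magnitude is used.

## 6. Power-law scaling and the population mode

Cells follow structural-damping (soft glassy) rheology,
$\tilde G(\omega) = k\,(i\omega/\omega_0)^\alpha\,\Gamma(1-\alpha)$,
optionally plus a Newtonian term $i\omega\mu$, with the stiffness $k$
referenced to $\omega_0 = 2\pi$ rad/s (1 Hz). At a single frequency
(with $\mu = 0$) the unique inversion is
$\alpha = (2/\pi)\arctan(G''/G')$ and
$k = G'/((\omega/\omega_0)^\alpha\Gamma(1-\alpha)\cos(\pi\alpha/2))$;
`complex_modulus()` and `scale_to_reference()` are exact mutual inverses
and the suite checks the round trip to $10^{-10}$. The per-cell scaling
ignores $\mu$; the global fit with a common $\mu$
(`fit_population_powerlaw()`, joint log-residuals of both components) is
provided for calibration-bead style datasets spanning a frequency range.

The population summary is the mode of the 2-D Gaussian KDE of
$(\log_{10} k, \alpha)$ — $k$ is log-normal across cells, $\alpha$
normal, and stiffer cells tend to be less fluid, so the joint mode is a
robust single descriptor. Bandwidths follow Scott's rule for two
dimensions (kernel s.d. $\hat\sigma_i n^{-1/6}$ per axis with a robust
$\hat\sigma$), the standard rule-of-thumb for 2-D Gaussian KDEs; the
201×201 grid argmax is refined by Nelder–Mead ascent on the exact KDE.
The mode of a 2000-cell KDE is itself a statistic with sampling noise of
order the bandwidth (roughly 10% in $k$ for a spread of 0.35 decades),
which the tests account for by checking single draws loosely and the
seed-average tightly.

## 7. The forward simulator

`simulate_cytometry()` inverts the entire analysis: it draws a
population with known $(k, \alpha, r_0)$ — log-normal $k$ (default mode
100 Pa, spread 0.35 decades), normal $\alpha$ (0.35 ± 0.05) with a
−0.05 per-decade stiffness–fluidity coupling, radii 8 ± 1 µm, positions
uniform across the channel minus one radius at each wall — and solves
the steady-state shape of every cell by outer root bracketing on the
normalized major axis: at each trial $\tilde a$ the alignment angle
follows in closed form from the loss-modulus relation and the strain
relation's residual is driven to zero (60-point log grid bracketing plus
`uniroot` to $10^{-12}$). Cells with no admissible steady shape
(extremely soft cells near the wall) are counted and skipped. The
emitted table follows the pipeline CSV contract exactly, with the
alignment angle's physical sign flip between channel halves and a
camera-alignment offset (default 2 µm) that the pipeline must recover by
centerline fitting.

The default measurement noise emulates the round-trip accuracy of the
package's own render → segment → ellipse-fit path at 0.345 µm/px
(measured: about 0.02 µm on the axes and 0.1° on the orientation;
defaults 0.05 µm, 0.1 µm position, 0.2° with a margin), plus 1% speed
and 2% tank-treading error. The default fluid (η₀ = 4 Pa s, τ = 0.1 s,
δ = 0.55) represents a 2%-alginate-like medium: its zero-shear viscosity
sits between measured 1.5% and 2.5% alginate plateaus and it yields a
center-line speed of 17.6 mm/s at 200 kPa, consistent with operating
practice of keeping flow below about 20 mm/s so cells are trackable at
500 Hz.

The renderer (`render_frames()`) draws shaded ellipses with seeded,
Gaussian-blurred speckle texture that rotates rigidly at the tabulated
tank-treading rate while the cell advects at its tabulated speed. It is
deliberately simple: no bright-field optics (defocus rings, diffraction),
no cell-to-cell hydrodynamic interaction, no migration across
streamlines, no sigmoidal shape modes, and homogeneous texture
statistics. Passing the closed-loop tests therefore demonstrates the
*internal consistency* of the analysis chain at realistic noise levels,
not robustness to the full variability of real bright-field data.

## 8. Problem sizes and budgets

The test suite validates the closed loop on 2000 simulated cells
(detection-table path, deterministic given the seed), the fluid fit on
500 tracks with 2% speed noise, and optical-flow rotation on six
81×81 px crops; the whole suite runs in under a minute on one CPU. The
shape-integral lookup table (1600 adaptive quadratures) is built lazily
once per session (~0.4 s) and cached.

## 9. Known limitations

* Each cell is probed at a single frequency set by its channel position;
  frequency dependence is a population-level statement.
* Near the channel center, cells are nearly round and β is ill-defined;
  such records are excluded by the one-radius rule, and cells just
  outside it still carry the noisiest moduli.
* The measured moduli are effective secant values: real cells
  stress-stiffen and occasionally deform into non-ellipsoidal shapes,
  which the ellipse fit cannot represent.
* $(\eta_0, \tau)$ of the fluid are extrapolations when the channel
  only samples the power-law regime of the Cross model (Section 2).
* The $\tilde c = 1$ normalization is untestable from 2-D images; a
  genuinely triaxial deformation would shift the shape-integral table at
  large strain.
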