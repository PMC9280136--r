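---
title: "Methods: triple decomposition, valve model and phase detection"
author: "triflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple decomposition, valve model and phase detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triflow)
```

This vignette documents the models implemented in `triflow`, the
numerical conventions behind them, the design choices that were
genuinely open, and what the synthetic fixtures do and do not emulate.

## 1. Triple decomposition of the velocity gradient

The velocity gradient `(∇u)ij = ∂ui/∂xj` (s⁻¹) describes the local
linearization of a flow.  Its classical *double decomposition* into the
symmetric strain-rate tensor `S` and the skew spin tensor `Ω`
(`double_decompose()`) leaves shear unaccounted for: a plane shear flow
contributes equally to both parts.  The *triple decomposition* instead
writes

\[ \nabla u = Q\,\big((\nabla u)_{EL} + (\nabla u)_{RR} + (\nabla u)_{SH}\big)\,Q^T \]

with `Q` orthogonal, separating irrotational strain (EL), rigid-body
rotation (RR) and pure shear (SH).  The frame is obtained from the real
Schur factorization `∇u = Q T Qᵀ` (`schur_standardized()`): the
quasi-triangular `T` decomposes additively into its diagonal, its
normal skew part and its strictly-upper non-normal remainder, which
carries all the shear.  Magnitudes are Frobenius norms
(`triple_decompose()`, batch form `triple_magnitudes()`).

A real 3×3 tensor always admits a real Schur form, but the form is not
unique.  For deterministic output the package fixes these conventions:

* **Block ordering.**  When a complex-conjugate eigenvalue pair exists
  (local rotation present), the 1×1 block with the real eigenvalue `λ`
  is reordered to position (1,1) and the 2×2 block to the lower right.
  The reordering uses the invariant subspace of `λ` and a Householder
  similarity, so it is exact up to roundoff.
* **Block standardization.**  The 2×2 block is rotated (Givens) to have
  equal diagonal entries `α`; the complex pair is then
  `α ± i\sqrt{-βγ}` with `β = T[2,3]`, `γ = T[3,2]`, `βγ < 0`.
* **Off-diagonal swap.**  If `|β| < |γ|`, the similarity that permutes
  the second and third coordinates swaps `β ↔ γ` (and `ε ↔ ζ`).  The
  shear part of the block is then `β + γ`; in the degenerate rigid-body
  case `|β| = |γ|` the sign conventions make `β + γ = 0` exactly.
* **Sign.**  Column signs of `Q` are flipped so `γ ≥ 0`.

None of these choices affects the three magnitudes (they are invariant
under any orthogonal change of the input frame, which the test suite
verifies to 1e-9 relative over seeded random tensors); they only pin
down which of the equivalent Schur forms is reported.  When all
eigenvalues are real the factorization is used as returned (any
eigenvalue ordering gives the same shear magnitude,
`‖SH‖² = ‖∇u‖_F² − Σλᵢ²`), rotation is exactly zero, and the diagonal
need not be equal.  Classification real-vs-complex is taken from the
factorization's own block structure — no imaginary-part threshold is
introduced, so near-degenerate tensors fall into the all-real branch
with zero rotation rather than being nudged by an arbitrary tolerance.

The trace is *not* forced to zero: discrete gradients of incompressible
fields are never exactly divergence-free, and the residual divergence
lands in the strain part where it belongs.

Non-finite entries raise an error immediately rather than propagating.

The factorization itself is delegated to LAPACK (`dgees` via
RcppArmadillo) — the same backward-stable kernel used by every serious
numerical environment — and the standardization above is implemented in
the package's compiled code, applied per tensor.  A batched kernel
decomposes a 64³ field in well under a second.

The von Mises-like scalar shear stress (`sss()`) is computed from the
shear-rate tensor `γ̇ij = (∇u)ij + (∇u)ji` *without* the viscosity
factor, keeping its units (s⁻¹) commensurate with the decomposition
magnitudes.  Its purpose here is comparative: `sss == sh_mag` for
single-plane shear, `sss == 0` for rigid rotation, but
`sss = √28 ≈ 5.29` for the pure-strain tensor `diag(1, 2, −3)` whose
shear magnitude is exactly zero — the strain contamination that makes
SSS a biased stand-in for shear in platelet-activation models.

## 2. Gridded fields

`grid_velocity_field()` holds a 3-component velocity on a uniform
rectilinear grid with optional boolean domain mask.  Gradients
(`compute_gradient()`) use second-order central differences at interior
nodes.  Two boundary policies apply:

* **Unmasked grids**: one-sided second-order differences at the grid
  boundary planes, so linear fields are differentiated exactly
  everywhere.
* **Masked grids**: a node is defined only when its full 6-point central
  stencil lies inside the mask.  There is deliberately *no* one-sided
  fallback toward walls: near-wall shear is exactly the quantity of
  interest, and silently dropping to a biased stencil there would
  corrupt it.  Undefined nodes carry `NA` (never zero — zeros would
  poison volume averages) and are excluded from all statistics.

`decompose_field()` maps the batched decomposition over all defined
nodes.  `spatial_average()` is a volume-weighted mean: node weights are
the product of spacings, halved on grid boundary planes (trapezoid
quadrature), mirroring an integral over the domain divided by its
volume.  `extract_structures()` binarizes one modality at a strict
threshold and labels connected components with 26-connectivity (the
choice is recorded in the output's attributes; a fixed convention keeps
runs comparable).  `time_series()` assembles per-frame averages.

All modality magnitudes are homogeneous of degree one in the velocity
amplitude, which the tests exploit as an exact invariant.

## 3. Mitral valve orifice model

The orifice is planar: two half ellipses sharing the long
(intercommissural) axis `2l`, with anterior short axis `saa` and
posterior short axis `sap` (defaults 12.8, 8.1 and 11.6 mm).  Opening
and closing are temporal scalings of the two short axes with knots at
the six cardiac landmarks; the default schedule runs from diastole
start (0.420 s, scales 0.40/−0.57, closed) through E-wave peak
(0.525 s, 1.00/1.00), the diastasis plateau (0.644–0.711 s, 0.50/0.70),
A-wave peak (0.779 s, 0.85/0.85) and diastole end (0.830 s, closed).
The open area is `(π/2)·l·max(0, saa_scale·saa + sap_scale·sap)`;
negative sums mean the projected leaflet edges overlap past the
coaptation line, i.e. a closed valve, represented by the area clamp and
the point-in-orifice indicator only — no explicit leaflet-contact
geometry is modelled.

**Interpolation.**  Scalings between knots use monotone piecewise-cubic
Hermite interpolation (`pracma::pchip`, Fritsch–Carlson-type tangents
that vanish at local extrema and across plateaus).  This was a genuine
design fork: free-tangent (Catmull–Rom/FMM) splines overshoot the
physical maximum scaling of 1.0 after the E-wave knot, while the
monotone scheme cannot.  With it, the model reproduces its two
reference areas: 3.96 cm² at E-wave peak and 2.55 cm² at mid diastole
(against 2.54 printed for the source valve, within 1%).  Note that R's
`splinefun(method = "monoH.FC")` variant does *not* zero its tangents
at local extrema and misses the mid-diastole value by ~2%; the
MATLAB-style `pchip` tangents are the ones that reproduce it.

**Mid diastole** is interpreted as the temporal midpoint of diastole,
`t = (0.420 + 0.830)/2 = 0.625` s — the only reading consistent with
the reference area, since the diastasis plateau itself evaluates to
2.45 cm².

**Clip (edge-to-edge repair) variant.**  A clip centred at `s·l` along
the long axis with width `w` splits the orifice into two sub-openings,
each again two half ellipses, with semi-long axes taken directly from
the unclipped segments: `a₁ = (l(1+s) − w/2)/2`,
`a₂ = (l(1−s) − w/2)/2`.  Within each sub-opening the anterior/posterior
short-axis ratio equals the untreated `saa/sap`, and short axes scale
with their opening's long axis, leaving a single multiplier `k`:
`b_a,i = k·aᵢ·saa/l`, `b_p,i = k·aᵢ·sap/l`.  `k` is fixed by conserving
the total leaflet free-edge length at E-wave peak — the sum of the four
half-ellipse arcs equals the untreated orifice's two arcs.  Arc lengths
use adaptive quadrature of the exact integrand (relative tolerance
1e-10) and `k` is bracketed on `[1, k_max]` and solved to 1e-10.
"Edge length" means the curved leaflet edges only, excluding the
straight long-axis chord and the clip itself; this choice is isolated
in one internal function.

Two limits validate the construction analytically: a zero-width centred
clip gives `k = 1` exactly and two half-scale copies of the untreated
orifice (arc length is homogeneous of degree 1), hence exactly half the
untreated area at every time (area is homogeneous of degree 2); and the
geometry is mirror-symmetric under `s → −s`.

**A limitation worth knowing:** total clipped area is *not* monotone in
clip width.  Edge conservation makes narrower openings relatively
taller (`k` grows with width), and the quadratic area gain from taller
leaflets initially outweighs the loss of long axis — the area rises by
up to ~2.5% over widths 0–4 mm before decreasing.  This is a real
property of the edge-conserving model, verified against the scaling
argument `area ∝ k(w)·(a₁² + a₂²)`, not a numerical artifact; intuition
that "wider clip ⇒ smaller opening" only holds beyond ~4 mm.

The clip width is a required model parameter (default 5 mm, the arm
span of common edge-to-edge devices): the published double-orifice
areas are not reachable without one, and no width is stated for the
source device, so reported clipped areas should be read as
width-calibratable.

`jet_reynolds_number()` estimates `Re = ρUD/μ` with `D` the diameter of
the circle matching the orifice area; blood defaults `ρ = 1060` kg/m³,
`μ = 0.0027` Pa·s.  With a 1.86 m/s E-wave jet through 4.0 cm² this
gives `Re ≈ 1.6×10⁴`.

## 4. Cardiac phase detection

`fit_volume_spline()` fits a cubic smoothing spline to sampled LV
volumes.  The smoothing default is the generalized cross-validation
choice of `stats::smooth.spline` — reproducible and explicit, since no
canonical value exists; it can be overridden by a fixed `lambda`, and
`smoothing = 0` switches to an interpolating cubic spline (FMM end
conditions, exact for cubic polynomials).

`detect_phases()` reads six landmarks off `dV/dt`, excluding the
isovolumetric phases from the model:

* The **E-wave peak** anchors everything: it is the global maximum of
  `dV/dt` after end systole (the E wave is by definition the dominant
  filling wave).
* **Diastole start** is the negative-to-positive zero crossing of
  `dV/dt` nearest *before* the E peak.  The simpler rule "first
  crossing after the global volume minimum" is equivalent on clean
  data but fragile under noise: the fitted volume minimum can drift
  past the true transition into the region where `dV/dt` is already
  positive, making that rule latch onto a spurious later dip.
  Anchoring on the dominant wave avoids this failure mode.
* The **A-wave peak** is the most prominent later maximum: a candidate
  qualifies only if the `dV/dt` valley between the E peak and the
  candidate falls below half the candidate's height.  A genuine atrial
  wave is separated from the E wave by the deep diastasis trough;
  noise-induced twins of the E peak are not.  If no candidate survives
  (no atrial kick, or heavy smoothing) the result is returned partial,
  with the missing landmarks flagged rather than guessed.
* **Diastasis** bounds are the two original acquisition frame times
  bracketing the `dV/dt` minimum between the peaks, and **diastole
  end** is the last frame time.

Zero crossings and extrema are refined to 1e-6 s by bisection/golden
search.  Detection is equivariant under time translation and volume
scaling.

## 5. Synthetic fixtures

`make_field()` generates the canonical local flow structures on cubic
grids (default 64³ over a 4 cm cube, roughly ventricular scale), each
with its closed-form gradient for oracle testing: uniform shear
(Couette, default 100 s⁻¹), solid-body rotation (50 s⁻¹), trace-free
extensional strain, a Lamb–Oseen vortex (core radius 5 mm, circulation
chosen for a ~100 s⁻¹ core rotation rate), a round jet with tanh shear
layer (1 m/s through radius 10 mm, layer thickness 2 mm — an idealized
transmitral jet), and pointwise superpositions.  On the jet axis the
closed-form gradient is taken as the flat-profile limit; the true
radial derivative there is `O(exp(−2R/δ))`, below 10⁻⁴ of the layer
shear for the defaults.

`make_volume_curve()` builds a one-beat LV volume trace whose rate
`dV/dt` is a sum of three Gaussian waves: ejection, E and A.  The wave
centres and the E-wave width are calibrated by a damped fixed-point
iteration (to 1e-9 s) so that the analytic curve places the
systole-diastole zero crossing, both filling-wave maxima and the
diastasis trough *exactly* at the requested times, while the amplitudes
are solved linearly so the curve starts at EDV, reaches exactly
`EDV·(1−EF)` at diastole start and returns exactly to EDV at diastole
end.  Defaults mirror the study subject (EDV 117 ml, EF 64%, 25 frames,
landmark times of the default schedule, E/A peak ratio 2).  A smooth
(C∞) rate curve was chosen over compact-support raised-cosine bumps
deliberately: echo-derived volumes are effectively band-limited, and
piecewise bumps carry curvature jumps at the peaks and a corner at the
crossing that bias spline-based landmark detection by several
milliseconds at 25 frames per beat — a generator artifact, not a
detector property.  Gaussian sampling noise (standard deviation given
as a fraction of EDV) is applied with a mandatory seed; no fixture
touches the global RNG state.

**What the fixtures do not emulate:** patient-specific chamber
geometry, deforming meshes, turbulent break-down of the inflow jets, or
measurement artifacts beyond additive Gaussian noise.  Passing tests on
these fixtures demonstrates that the algebra, discretization and
detection logic are correct on fields whose ground truth is known
exactly — not that a clinical CFD pipeline built on them is validated.

## 6. Problem sizes and numerical tolerances

The shipped tests and the acceptance script use grids of 17³–65³ nodes
(three refinements, ~275k nodes at the finest), 10⁴ random tensors for
the exactness and frame-invariance sweeps, and 100 synthetic volume
curves at noise levels spread over 0–2% of EDV — sizes chosen so the
full suite runs in about a minute on one core while the convergence
orders are already within 3% of their asymptotic value of 2.
Convergence is measured in volume-averaged absolute error: max-norm
convergence degrades to first order on rings where the eigenvalue type
of the gradient changes (the decomposition is continuous but not
Lipschitz there), which is a property of the decomposition, not of the
discretization.  Key tolerances: Schur reconstruction 1e-10 relative
(achieved ~5e-15), orthogonal-frame invariance 1e-9, ellipse arcs and
the edge-conservation root 1e-10, landmark refinement 1e-6 s.
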