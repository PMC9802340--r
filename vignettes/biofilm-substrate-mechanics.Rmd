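---
title: "Measuring colony spreading and substrate traction on soft gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring colony spreading and substrate traction on soft gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmtfm)
```

## The measurement problem

Bacterial colonies growing on a soft elastic substrate do two things at
once: their front advances across the surface, and the colony exerts
tangential forces that deform the gel underneath. `biofilmtfm` implements
both measurement arms as one tested pipeline:

1. **Front velocimetry.** Bright-field time-lapse frames are segmented,
   the colony boundary is fit to circular arcs, and the radial advance of
   the front between arcs separated by a fixed time increment gives the
   expansion velocity in mm/hour.
2. **Traction force microscopy (TFM).** Fluorescent tracer beads embedded
   in the gel are tracked by particle image velocimetry (PIV); after stage
   drift is removed, the tangential surface stress is reconstructed from
   the displacement field by regularized inversion of the elastic
   half-space (Boussinesq) operator, and the surface shear strain follows
   from the constitutive identity $\tau = G'\varepsilon$.

Raw laboratory imagery for studies of this kind is rarely deposited, so
the package ships a first-class synthetic generator that renders colony
and bead stacks from known ground truth. Every analysis claim in the test
suite is checked against that truth.

## Synthetic study conditions

The generator defaults encode the imaging conditions typical of this
assay: frames every 10 minutes, a front speed of 5 µm/min (0.3 mm/hour,
the saturation scale of front speeds on stiff elastic gels), 4.8 µm
tracer beads, and displacement structure consisting of a slow inward
contractile motion toward the colony center, transient ~20 µm "hot spot"
pulses near the expanding edge, and rigid stage drift. Pixel size
(2 µm/px) and field of view (512 px colony frames, 256 px bead frames)
are generator choices — documented here, not inferred from any particular
microscope.

What the generator deliberately does **not** emulate: colony biology (the
front law is prescribed, not emergent), axial bead motion, bead turnover
or bleaching, illumination gradients, and gel viscoelasticity. A green
test suite therefore demonstrates that the estimators recover what they
claim under controlled conditions; it does not certify performance on
pathological real-world imagery.

Time semantics of the displacement model are a design choice the sources
of this assay leave open: the contractile and drift terms accrue linearly
with frame index (frame 0 is the unstressed reference), and hot spots are
boxcar events with a fixed per-event direction, by default the unit
vector from the contractile center to the event center. The contractile
profile $u_r(r) = -f\,A\,(r/L)\,e^{(1-(r/L)^2)/2}$ at frame $f$ peaks at
exactly $fA$ µm at radius $L$, which keeps amplitude checks exact.

## Boundary detection and arc velocimetry

Manual supervision of boundary tracing is replaced by a deterministic
chain: contrast normalization, Gaussian smoothing (σ = 1 px),
between-class-variance (Otsu) thresholding, largest connected component,
morphological closing (radius 3 px), then subpixel contour extraction of
the smoothed intensity at the threshold level. Supplying the previous
frame's boundary as a prior reproduces the supervised preference for
temporal continuity: the candidate contour nearest the prior wins.
Because the rendered colony edge is a one-pixel intensity ramp, the
contour is meaningful at the subpixel level; on noiseless disks the
detected boundary sits within 0.05 px of the true circle.

Arcs are fit by the algebraic (Kåsa) least-squares circle refined by
geometric minimization of the radial misfit — exact on noiseless data,
including short arcs, and stable under isotropic point noise. Velocity is
the mean radial distance from the earlier arc to the later arc along rays
cast **from the earlier arc's center** across its angular span (50 rays
by default), divided by the time increment. Anchoring rays at the earlier
center when consecutive centers differ is a documented convention of this
package; with 20 µm center offsets it agrees with a dense ray oracle to
0.5%. Velocities are computed on non-overlapping 20-minute increments and
stamped at the interval midpoint, which is unbiased when growth is linear
in time. Four imaging windows placed on the colony periphery are tracked
independently; the per-colony curve is their mean with SEM.

## PIV: displacement estimation

Interrogation windows (32 px, 50% overlap by default; both
config-exposed) are cross-correlated via the FFT after mean removal. The
estimator is multi-pass: the integer displacement from a first pass
offsets the current-frame window (circular indexing at frame edges) and
the correlation is repeated until the residual integer vanishes, so the
final peak is symmetric about the true subpixel residual — this makes
integer shifts exact to machine precision. The subpixel residual comes
from three-point Gaussian interpolation per axis against a local ring
baseline (radius 3–5 px around the peak), with a parabolic fallback where
a logarithm is undefined. Because the interpolation bias is antisymmetric
in the residual and largest near half-pixel displacements, residuals in
(0.25, 0.75) px are re-estimated from the neighboring integer offset and
the two estimates averaged, cancelling the bias; this brings uniform
subpixel displacements to ~0.02–0.05 px RMS.

Vector validation is threefold: a minimum window intensity variance
(signal-free windows are masked, never fabricated), a peak-to-second-peak
quality ratio (default 1.5, second peak sought outside the primary peak's
support), and the normalized median test across the vector grid
(threshold 2, noise floor 0.1 px), which masks vectors whose correlation
peak was won by clutter in sparse windows.

`accumulate_series()` implements both reference conventions:
`"first_frame"` correlates every frame directly against frame 0 (the
accumulated field — no integration of instantaneous fields is performed),
and `"previous_frame"` correlates consecutive pairs (the instantaneous
field). Stage drift is estimated as the **spatial mean** displacement
over a user-specified stress-free rectangle far from the colony — the
minimal deterministic reading of subtracting the stress-free region's
field — and recorded in the result so corrections are auditable. Drift
estimation is best run with large windows (64 px) since rigid motion
needs no spatial resolution.

## Divergence analysis

$\nabla\cdot u = \partial u_x/\partial x + \partial u_y/\partial y$ is
computed by second-order central differences on interior grid nodes and
one-sided differences at edges (flagged `boundary`). Displacements and
grid coordinates are both in µm, so the divergence is unitless. The wave
diagnostic azimuthally averages the divergence as a function of signed
distance from the colony edge; on a synthetic annulus of prescribed
magnitude 0.015 locked to a moving edge, the profile peak recovers the
magnitude within 5% and tracks the edge within one grid spacing.

## Traction reconstruction

The forward model is the tangential elastic half-space surface response:
in the Fourier domain $\hat u(k) = \hat G(k)\,\hat\tau(k)$ with

$$\hat G(k) = \frac{1}{G'k^3}
\begin{pmatrix} (1-\nu)k^2 + \nu k_y^2 & -\nu k_x k_y \\
                -\nu k_x k_y & (1-\nu)k^2 + \nu k_x^2 \end{pmatrix},$$

the classical Fourier-transform traction microscopy operator. The
half-space idealization is justified because gel thickness (~1 mm) vastly
exceeds both the observed displacements (µm scale) and the PIV grid
spacing; a zero-padding factor is exposed for callers who want to
approximate free-space boundary conditions (used internally for far-field
decay checks), while the default treats the grid as periodic so the
forward operator is exactly invertible and doubles as the oracle in
round-trip tests. Tractions are assumed tangential; the Poisson ratio
defaults to 0.5 (incompressible gel) and is config-exposed, with
$E = 2G'(1+\nu)$ where a Young's modulus is needed.

Two numerical facts matter for interpretation. First, the $k = 0$ mode of
$\hat G$ vanishes: the spatial mean of the traction over the field of
view is unresolvable from displacement data (physically, colony tractions
balance internally, and drift correction removes the mean displacement
anyway), so reconstructions are mean-free and validation patches should
be force-balanced. Second, the Tikhonov parameter of
$\min_\tau \|\hat G\tau - u\|^2 + \lambda^2\|\tau\|^2$ is expressed
relative to the squared operator norm of $\hat G$; since
$\hat G \propto 1/G'$, this makes the reconstructed stress **exactly**
proportional to $G'$ at fixed displacement — the testable core of any
soft-versus-stiff substrate comparison. With `reg = "lcurve"` the
parameter is chosen at the corner of the L-curve (maximum Menger
curvature of log residual norm versus log solution norm over a 30-point
sweep), computed on the data at hand and logged in the result.

"Accumulated stress" is the reconstruction of the first-frame-referenced
displacement field; "instantaneous stress" that of the consecutive-frame
field. Stress summaries report quartiles, whiskers (min/max by default or
Tukey 1.5 IQR — the convention is config-exposed because published
box plots rarely state it), and the mean of $|\tau|$ per timepoint.
Strain is $\varepsilon = \tau/G'$ exactly; the choice of which stress
statistic to convert is left to the caller.

## Problem sizes and runtime

The test suite and the acceptance script run on 512 px colony frames
(7 frames), 256 px bead frames (2–4 frames), and 48–64 node traction
grids. These sizes were chosen so that each property is measured with
comfortable statistics while an end-to-end run completes in seconds on a
single CPU; all estimators are resolution-independent, and the pipeline
accepts arbitrarily larger stacks.

## Known limitations

* Boundary detection assumes a single dominant intensity-contrasted
  colony per window; merging colonies or strongly textured interiors
  would need the prior-snapping option and careful window placement.
* The PIV estimator measures in-plane motion only; axial bead motion is
  out of scope.
* The periodic traction operator wraps long-range displacement tails;
  fields whose sources approach the frame edge should use the padding
  option and expect the unresolved mean.
* Agar-like viscoelastic substrates violate the elastic constitutive
  assumption throughout; the package deliberately refuses no inputs on
  this basis, so the user must know their gel is elastic.
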