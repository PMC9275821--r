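---
title: "Methods: covariant kinematics, shear and cell statistics on folding tubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covariant kinematics, shear and cell statistics on folding tubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, discrete operators and design decisions
behind `tubekin`, in the spirit of a statistical-methods appendix. Nothing
here states a result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The kinematic model

A thin epithelial tube deforming in 3D carries a velocity field
`v = v∥ + v_n n̂` (tangential part plus normal part; we orient normals
*inward*, toward the lumen, so the mean curvature of a cylinder is
positive, `H = 1/(2R)`, and `v_n > 0` means constriction). The induced
metric `g_ij` evolves as

```
∂t g_ij = ∇_i v_j + ∇_j v_i − 2 v_n b_ij,
```

with `b_ij` the second fundamental form. Taking the trace and assuming the
tissue is incompressible (material area density constant) yields the
package's central identity,

```
2 H v_n = ∇ · v∥,
```

whose residual `∇·v∥ − 2Hv_n` equals the local relative area growth rate
`d log A / dt`. A shrinking sphere `R(t)` makes this concrete:
`∇·v∥ = 0`, `v_n = −Ṙ`, residual `2Ṙ/R` — exactly the logarithmic area
rate. On a tube, incompressibility couples a localized constriction
(`v_n > 0` where `H > 0`) to in-plane flow that converges
circumferentially and extends axially: convergent extension via
constriction.

Assumptions: the surface is a topological cylinder (or closed surface)
represented as an oriented triangle mesh; consecutive timepoints share
vertex identity (Lagrangian correspondence), so velocities are finite
differences of vertex positions; the chart `(s, φ)` labels material
points, `s` in micrometres from the anterior end, `φ` periodic. Units are
micrometres and minutes throughout (seconds for calcium frames).

## Discrete operators

**Mean curvature.** Cotangent Laplace–Beltrami applied to the vertex
positions, divided by Meyer's mixed (Voronoi-safe) vertex areas and
projected on the inward vertex normal (`ΔX = 2H n̂`). The mixed area is
what makes the estimate pointwise-accurate at irregular vertices
(icosphere poles); barycentric areas leave an O(1) error there. On
structured cylinder meshes the formula is exact to machine precision; on
icospheres the error falls well below 1% from subdivision level 2. The
one-ring stencil is incomplete on boundary vertices; those values are
replaced by the mean over adjacent interior vertices rather than
extrapolated.

**Covariant divergence.** The tangential field is flattened to a discrete
1-form on edges (midpoint sampling) and the codifferential is taken with
cotangent dual/primal edge-length weights, divided by barycentric vertex
areas. Two properties motivated this choice over a finite-element weak
form: a uniform axial stretch of a cylinder returns the stretch rate
exactly, and the discrete divergence theorem holds *identically* (to
roundoff) on any vertex subset — the area-weighted divergence sum over a
chart sub-rectangle telescopes to the 1-form flux through its cut edges.
The tests assert both.

**Velocity centering.** Velocities are forward differences
`(X(t+dt) − X(t))/dt`, but all geometry entering the incompressibility
test (normals, curvature, divergence, patch areas) is evaluated on the
midpoint surface `(X(t)+X(t+dt))/2`. This centers the discrete fields in
time and reduces the step error from O(dt) to O(dt²); with 1-minute steps
it is what keeps patch residuals at the 1e−3/min level.

**Patch averaging and pooling.** Fields are averaged area-weighted over a
rectangular grid of material-chart bins, 20 × 16 = 320 patches by
default. The correlation between `2Hv_n` and `∇·v∥` pools all (patch,
timepoint) samples with patch-area weights; an unweighted option exists
because the pooling rule for such correlations is a genuine free choice —
weighting by area gives every piece of tissue equal say, which we consider
the defensible default.

**Metric-rate validation.** `metric_rate_check()` evaluates both sides of
the `∂t g_ij` identity semi-analytically on parametric sequences (closed
form radius profile, dense finite differences along the material
coordinate) and is a validation tool only; no general discrete shape
operator is implemented, because the production pipeline needs only the
traced identity.

## The synthetic constricting tube

The generator is kinematic, not mechanical: it prescribes the unique
axisymmetric, area-preserving Lagrangian flow for a radius profile

```
r(z, t) = R0 − Σ_j d_j(t) exp(−(z − c_j)² / 2w_j²),
```

solving for marker axial positions by inverting the cumulative area
integral `∫ r sqrt(1 + r_z²) dz` by quadrature (4096-point trapezoid,
inverted by monotone interpolation), with the anterior end anchored and
the tube extending posteriorly. Defaults are the study conditions used
throughout: `R0 = 30` µm, `L0 = 200` µm, one constriction of width 15 µm
whose depth ramps linearly to `0.6 R0` over 30 one-minute steps, on a
128 × 64 mesh. The depth waveform of real constrictions is not prescribed
by data, so the ramp is configurable. Closed forms for `H`, `v_n` and
`∇·v∥ = 2Hv_n` at every marker provide the oracle fields.

**What is conserved discretely.** After the continuum inversion, marker
positions are refined ring by ring (`uniroot`, tolerance 1e−13) so that
every quadrilateral band cell of the mesh keeps its initial *discrete*
area exactly (drift ~1e−13). The two triangles inside one band cell,
however, split the cell's area in proportion to the two ring
circumferences — a ratio fixed by the radius profile that no Lagrangian
marker placement (axial shift or azimuthal twist, both area-preserving
shears at the triangle level) can rebalance. Individual triangle areas
therefore carry an O(Δs · ∂r/∂z / r) sampling asymmetry, a few percent at
default resolution, decaying linearly under refinement; the tests pin the
quad-cell conservation at machine precision and the monotone decay of the
split asymmetry. Patch-level and cell-level area statistics are
insensitive to the split because the two triangle families interleave.

**Failure modes.** A constriction depth at or above `R0` is rejected at
specification time; a neck collapsing below 5% of `R0`, or a
non-invertible area integral, aborts with the offending timestep named.

## Shear in the material frame

The material chart fixes labels at the onset of constriction (`t0`,
configurable; the first timepoint by default). The longitudinal
coordinate is rescaled to `ζ(s) = ∫ sqrt(g_ss/g_φφ) ds` — computed from
per-face induced metrics, bin-averaged along `s` and integrated with
linear extension to the chart ends — which makes the reference pullback
conformal for near-axisymmetric shapes (residual `|μ(t0)|` is reported
and required below 0.05; it is ~1e−14 on generated tubes). Deformation at
later times is measured *relative* to the stored per-face reference
metric via its Cholesky transform, so `μ(t0) = 0` holds exactly
face-by-face and `μ` inherits invariance under rigid motions and global
scaling. A harmonic flattening (`harmonic_cylinder_chart()`: Dirichlet
solve for `s`, harmonic angle with a 2π period across a shortest cut path
for `φ`) builds charts for meshes that arrive without one; it is a
standard, well-conditioned isotropy reference, chosen deliberately over
Ricci-flow uniformization.

Circumferential averaging of `μ` is done on the complex value, so
opposite orientations cancel and a uniform axial stretch shows a single
phase; a magnitude-average option is exposed because plain "averaging" of
a complex anisotropy is ambiguous. `K = (1+|μ|)/(1−|μ|)` is checked
against the singular-value ratio of the per-triangle map to 1e−8.

## Cell-scale measurements

Polygons arrive in chart coordinates, are unwrapped across the φ seam,
densified (one interpolated point per edge by default, so cells large
relative to the surface curvature still follow it), embedded by
barycentric interpolation over the chart triangulation, and projected on
the tangent plane at the centroid's face, with the frame from
Gram–Schmidt of the chart directions (ŝ first, right-handed with the
inward normal). The second-moment-of-area tensor gives `a/b = sqrt(I1/I2)`
(second moments of an ellipse scale as a³b and ab³, hence the square
root) and the orientation θ of the major axis from ŝ.

**Cell areas** are measured as the area of the cell's footprint on the
piecewise-linear surface: the chart polygon is clipped against every
overlapping mesh face (Sutherland–Hodgman) and the chart overlap weighted
by the face's 3D/chart Jacobian. This is exact under the surface map; a
naive fan triangulation of the embedded boundary overestimates areas by
tens of percent once a cell wraps a strongly curved neck, which is why
the package does not use it.

**Statistics.** Means of `a/b` and θ are area-weighted exactly as the
printed estimators (θ via the two-argument arctangent of the weighted
vector sum). Orientation is an axial quantity, so a doubled-angle variant
is provided; the printed non-axial form remains the default for
comparability, and the two differ in edge cases (±60° averages to 0
non-axially but to ±90° axially — the tests document this). Bootstrap
standard errors follow the variance-extrapolation recipe: subsample
means with replacement at 50 sizes in (N/4, N], fit `σ²(n) = a/n + b`,
evaluate at `n = N`; it agrees with the plain N-out-of-N bootstrap within
10% on i.i.d. data and scales as `1/sqrt(N)`.

**T1 events.** Adjacency series per cell pair; pairs adjacent at every
timepoint are discarded; states persisting for `debounce` timepoints or
fewer (default 1) revert to the surrounding state, replacing the manual
visual screening of segmentation flicker with a reproducible rule. Each
remaining change is one event; its axis is the centroid–centroid
direction in a locally conformal patch, folded to (−90°, 90°], and the
AP/DV orientation bias is an exact two-sided binomial test at a 45°
threshold.

**Group comparisons.** Per-timepoint two-sample z-scores (unequal
variance) are combined across timepoints with Stouffer's method
(`Z_comb = ΣZ/√T`) for the "sustained difference" p-value; the combining
rule is an interpretation, chosen for its transparency, and the per-time
table is always returned so any other combination can be applied.

## Calcium quantification

`δI = |I1−I2| + |I2−I3| + |I1−I3|` per frame triplet (frames 9–10 s
apart, one triplet per ~90 s composite). For i.i.d. Gaussian pixel noise
of SD σ the noise floor is `E[δI] = 6σ/√π` — each pairwise difference is
N(0, 2σ²) and expectations add regardless of correlation; the tests pin
this against a Monte-Carlo oracle. Feature extraction is a Gaussian blur
(σ = 2 px) followed by a *white* top-hat (disc radius 15 px) — bright
transients on a dark background; black-hat would target dark features and
is not what a fluorescence transient is. Neither parameter is dictated by
the data, so both are arguments. Images are padded by edge replication
before filtering (EBImage's greyscale morphology also assumes intensities
in [0, 1], so the input is rescaled around the filter). Two blobs closer
than the top-hat radius merge; this is documented behavior, not a defect.
Activity profiles sum the cleaned signal along the circumferential image
axis; per-embryo normalization maps the background window (45–50 µm from
the putative constriction site) to 0 and the maximum to 1, cancelling
affine intensity rescalings of the raw movie; kymographs align embryos on
supplied constriction-onset times (onset detection is out of scope — it
comes from a separate bright-field observation).

## Comparison statistics

`Z = (mean_a − mean_b)/sqrt(s_a²/n_a + s_b²/n_b)` with sample SDs
(n − 1 denominator); `p = ½ erfc(−Z/√2)`, the lower normal tail — the
erfc argument must carry √2, not 2, for `Z = −1.64` to give p = 0.05;
`SE = sqrt(p̂(1−p̂)/N)` for the three-fold success frequency. Degenerate
inputs are explicit: zero pooled variance with unequal means returns
signed infinity rather than NaN.

## The generator as a stand-in for recordings

The synthetic module emulates the *structure* the analysis assumes:
exact area preservation, circumferential cell elongation with jitter,
tethered nuclei pairs whose relative drift acts along the initial
separation direction (so the prescribed rate is the separation growth
rate by construction), Poisson-timed Gaussian pulses, Bernoulli fold
outcomes with partial phenotypes drawn mostly at 1–2 folds. It does not
emulate: segmentation errors and over/under-splitting, PIV noise and
advection error, anisotropic optical scattering, tissue-intrinsic area
growth (the real organ grows ~30% in area; the generated flow is exactly
area-preserving so the incompressibility test has a clean null), cell
divisions or real intercalation dynamics, or any force balance. Passing
tests therefore certify the measurement chain, not biological inference
on real recordings.

## Problem sizes and determinism

Default analyses run at 128 × 64 mesh resolution with 30 one-minute
timepoints (the acceptance script's regime), ~600 cells, 81 nuclei pairs
and 64 × 128 px movies — sizes at which every pipeline stage completes in
seconds to half a minute on one CPU and discretization errors sit well
below the quantities of interest (patch residuals ~1e−3/min against
signals of ~1e−2/min). All generators take explicit integer seeds and are
byte-reproducible; analysis stages are deterministic.

## Known limitations

- The harmonic chart requires a clean topological cylinder; no mesh
  repair is attempted beyond validation, and cotangent weights on very
  poor-quality triangulations can degrade the Laplace solves.
- Boundary rings inherit neighbor-averaged curvature/divergence values;
  quantities within one patch of the tube ends are less accurate.
- The Beltrami pipeline measures metric anisotropy only; decomposing
  shear into cell-shape versus rearrangement contributions is out of
  scope (the comparison is done at summary level via
  `cellshape_vs_tissue_shear()`).
- `b_ij` is never estimated from discrete data; the metric-rate identity
  is validated on parametric surfaces only.
- The T1 axis uses the orthonormal tangent frame at the quartet centroid
  as the "locally conformal patch"; for strongly sheared charts the two
  differ at second order in the patch size.
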