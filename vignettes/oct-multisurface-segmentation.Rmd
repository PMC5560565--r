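---
title: "Constrained multi-surface segmentation of mouse retinal OCT: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained multi-surface segmentation of mouse retinal OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spectral-domain OCT of the mouse retina produces volumes of roughly
1000 A-scans x 100 B-scans x 2048 depth voxels (a 1.4 x 1.4 x 1.6 mm field,
0.78 um axial sampling). Longitudinal studies of photoreceptor degeneration
need the positions of up to ten retinal surfaces in every volume, and manual
tracing at that scale is impractical: raters differ from themselves by about
1.3 um and from each other by 1.6-2.2 um on repeat tracings. `octseg`
segments all surfaces automatically, quantifies eight layer thicknesses in
the standard four-quadrant annulus, and runs the group comparisons used in
light-damage (LD) studies, where the outer retina thins dramatically and the
outer nuclear layer (ONL) may disappear entirely.

## The optimization model

Each surface is a function `z = S(b, x)` assigning one axial position to
every column of the volume. A configuration of `n` surfaces is feasible
when

* `|S(b, x) - S(b, x+1)| <= smooth_x` (lateral smoothness),
* `|S(b, x) - S(b+1, x)| <= smooth_b` (inter-B-scan smoothness, deliberately
  looser because whole B-scans shift axially with breathing motion),
* `min_sep <= S_lower - S_upper <= max_sep` for adjacent surface pairs.

Given per-surface cost volumes `c_s(b, x, z)` (lower = more boundary-like),
the segmentation is the exact global minimizer of
`sum_s sum_{b,x} c_s(b, x, S_s(b, x))` over all feasible configurations.
The solver encodes the problem as a minimum closure graph: node
`(s, b, x, z)` is "on" iff `S_s(b, x) >= z`, node weights are the axial
cost differences `c(z) - c(z-1)`, and each constraint becomes an
infinite-capacity arc. One minimum s-t cut (igraph's push-relabel max-flow)
solves all surfaces of a stage simultaneously and exactly.

**Tie-breaking.** The feasible optima of this problem form a lattice, so a
unique pointwise-minimal optimum (every surface as shallow as possible)
exists. The solver returns it by taking the source side reachable in the
residual network, and the exhaustive oracle (`brute_force_segment`) returns
the meet of all enumerated optima — the identical rule, which is what makes
the oracle-equivalence tests exact rather than cost-only.

## Costs

The coarse stage uses signed axial derivatives of Gaussian-smoothed
intensity, negated per edge polarity and shifted to be non-negative. The
main stages use a random forest per stage and mode (healthy and LD scans
never share classifiers): voxels within one voxel of a traced surface are
labelled with that surface, all other voxels of the traced B-scans are
background, classes are balanced by subsampling, and costs are `1 - P`
(bounded and monotone; `-log P` was rejected because vanishing
probabilities would produce infinite costs). The feature recipe is raw
intensity; smoothed intensity at sigma 1, 2, 4 voxels axially (half
laterally); signed axial derivatives at sigma 1 and 2 in both polarities;
signed distance to the coarse ILM; relative depth inside the ROI; and
normalized lateral position. The cited feature design is not published in
detail, so this recipe is this package's own declared choice, sized for
half-resolution working volumes.

## The three-stage pipeline

1. Downsample by 2 laterally and axially (B-scan count unchanged).
2. Localize a region of interest at a further 4x downsampling by solving a
   two-surface problem (ILM and the deepest strong bright-to-dark
   transition) with gradient costs and a minimum separation of half the
   nominal retinal thickness — that large separation is what makes the
   coarse stage immune to the stronger photoreceptor edges.
3. Solve three constrained stages: the RNFGC-complex bounds; the remaining
   inner surfaces (in LD mode only the INL bounds, since the lower OPL
   boundary is unreliable there); the outer surfaces (in LD mode only the
   ONL top and Bruch's membrane).
4. Rescale to native resolution (lateral linear interpolation, axial
   multiplication).

**Stage anchoring.** Restricting each stage only to "at or below the
previous stage" proved insufficient: with gradient costs, stage 1 happily
locks onto the brighter EZ/RPE edge pair, which satisfies the same pairwise
separation. Every stage surface is therefore bounded to its expected
separation range from an anchor — the coarse ILM estimate for stage 1 (with
the ROI margin as slack), the previous stage's lowest surface afterwards
(with a 2-voxel guard band). The ranges derive from nominal layer
thicknesses +/- 50%; in LD mode ablatable bands contribute zero to the
lower bounds.

**Constraint values.** `smooth_x = 2`, `smooth_b = 6` working voxels, and
separations from the nominal thicknesses, all exposed in `seg_config()`.
These are fixed expected parameters in the spirit of the original design;
the original empirical values are unpublished, so these are this package's
own defaults, chosen against the phantom's geometry (4 um undulation,
1.5-voxel B-scan jitter, 40 um ONH depression).

**Vanishing layers.** In LD mode the ONL-to-BM minimum separation is zero.
Two further mechanisms implement "the ONL top collapses onto BM where no
layer is visible": a mild linear separation prior (0.05 cost units per
voxel of ONL thickness) that settles ties where the two boundaries are the
same image edge, and a visibility snap — after the stage solve, columns
whose separation is at most 3 working voxels (~4.7 um, below the resolution
of the cost model) collapse exactly. Separations that small cannot be
distinguished from estimation noise of two classifiers looking at one edge;
a real day-6 ONL (~26 um, 17 working voxels) is an order of magnitude above
the threshold. A global prior alone cannot do this job: any strength that
closes the noise gaps also erases the real residual ONL.

## The phantom

`generate_phantom()` is the package's test bed, standing in for scans that
are not publicly deposited. It renders a piecewise-layered axial
reflectivity profile with the mouse contrast ordering (hyperreflective
RNFL, EZ and RPE; hyporeflective INL and ONL) using linear partial-volume
mixing, then applies, in order: a smooth low-frequency topography (4 um),
an ONH depression at the volume centre where all surfaces converge (radius
0.15 mm, matching the excluded analysis disc), regional LD ablation scaling
the ONL and photoreceptor bands by `1 - severity`, vessel shadows
attenuating all intensity below the lower RNFGC boundary, a per-B-scan
axial motion shift (sd 1.5 voxels), unit-mean gamma speckle (shape 60,
emulating 10-frame averaging) and additive Gaussian noise (sd 0.02).

Healthy nominal thicknesses (RNFGC 12, IPL 39, INL 25, OPL 14, ONL 53,
IS 14, EZ 8, OS 10, RPE 15 um) reproduce the control-cohort layer
magnitudes (IR 76, OR 114, TRT 190 um); the LD mode thickens the INL to
32 um and removes 74% of the outer bands by default, matching day-6
magnitudes. Reflectivity values are free parameters of the phantom — the
scanner's intensity statistics are not published — chosen only to respect
the contrast ordering.

What the phantom does **not** emulate: the scanner's point-spread function
and depth-dependent attenuation, curved vessel trees, frame-averaging
artifacts, eye tilt, and any real texture inside layers. Passing tests on
the phantom therefore demonstrate the correctness and robustness of the
optimization and learning machinery under controlled, realistic geometry
and noise — not clinical-grade accuracy on real scans.

Simulated raters place control points every `spacing_px` columns at the
true surface plus `N(bias, sd^2)` um noise and join them with a natural
cubic spline (the package also supports exact-cubic and linear rules).
`sd = 1 um` reproduces the observed intra-rater repeat magnitude
(`2*sd/sqrt(pi) ~ 1.13 um`); a "trace-around" option displaces control
points upward inside vessel shadows, a behaviour real raters exhibit on the
lower RNFGC boundary.

## Validation metrics and statistics

Unsigned border position error is `mean|S_a - S_b| * 0.78 um` over the
annulus between the 0.3 mm and 1.2 mm diameter circles (boundary pixels
included on both circles — a deterministic rule where convention is
unstated), with per-slice means aggregated as mean +/- SD across slices in
the variability tables; per-column pooling is available in
`border_error()`. Where a rater did not trace the ONL top, BM substitutes
for it in the automated comparison.

Thickness analysis covers eight layers (RNFGC, IPL, INL, RNFGC+IPL, IR,
ONL, OR, TRT). The OR lower bound is BM in both modes — the published
summary values satisfy IR + OR = TRT only under that reading, and it makes
the identity exact by construction here. Quadrants split the annulus on the
+/- 45 degree diagonals; the superior-at-top labelling is configurable
because scan orientation conventions differ. Group comparisons use paired
t-tests at alpha = 0.01 with no multiplicity correction, pairing by eye
index, reproducing the published analysis convention; an unpaired option
exists because pairing of independent animals is a reporting convention,
not a design necessity. Cohort simulation draws one Gaussian per eye per
layer per day from the bundled reference table; quadrant-level deviations
default to zero because the table carries no quadrant information.

## Numerical choices and degenerate inputs

* Costs must be finite; infeasible constraint systems are rejected before
  graph construction by interval propagation along the surface chain.
* Downsampling is block-mean; non-divisible trailing columns are cropped
  with a warning. Surfaces rescale axially by pure multiplication (the
  half-voxel phase of block averaging is absorbed by the error budget;
  sub-voxel refinement at native resolution is out of scope).
* Persistence uses a package-internal float TIFF codec (uncompressed,
  little-endian, `SampleFormat = IEEEFP`): volumes at 64-bit so intensities
  round-trip bit-exactly, surfaces at 32-bit. The mainstream R TIFF
  bindings store normalized integers and cannot represent these values.
* Identical paired cohorts make the t statistic 0/0; the comparison
  returns p = 1 with a warning instead of erroring.
* Problem sizes in the test suite: unit tests run 8-12 B-scan phantoms
  (64 x 448 voxels); end-to-end checks run 25 x 128 x 512 phantoms, the
  scale at which a stage graph has ~0.5-1.5 million nodes and solves in
  tens of seconds.

## Known limitations

* Surfaces are reported at integer working-resolution positions rescaled to
  native; no sub-voxel refinement pass exists.
* The ONH region is bridged, not segmented: inside the 0.15 mm disc the
  true surfaces converge faster than the smoothness constraints allow. All
  analyses mask this disc, matching the published protocol.
* The visibility snap zeroes any real ONL remnant thinner than ~5 um; at
  that thickness the layer is below the cost model's resolution anyway.
* Cross-stage consistency is enforced by per-column clipping after each
  stage; within-stage constraints are exact, but a pathological cost field
  could make a later stage touch its clip bound.
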