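---
title: "Measuring erratic and blood vessel-guided migration of astrocyte progenitors"
author: "AstroMigrate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring erratic and blood vessel-guided migration of astrocyte progenitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In the late embryonic cortex, astrocyte progenitors generated in the
ventricular zone disperse through the intermediate zone and cortical plate
before differentiating into protoplasmic astrocytes of the gray matter.
Time-lapse imaging of organotypic slices shows two characteristic modes:
*erratic migration* — fast, weakly persistent movement with frequent
direction changes but a net tendency toward the pial surface — and
*blood vessel-guided migration*, in which cells attach to cortical
capillaries, crawl along them (the vasculature runs predominantly radially
in the cortical plate), and detach again. Radially migrating neurons serve
as the contrast class: slower, strongly directed along the radial axis.
Perturbations of vessel attachment shift cells away from vessels and
deplete astrocytes from the superficial cortical plate.

AstroMigrate implements the measurements behind those statements as a
tested pipeline: trajectory statistics, vessel-proximity and on/off-vessel
classification, cortical depth distributions, a statistical reporting
layer, and a synthetic-data generator that emulates the imaging inputs so
that every stage can be verified without any external dataset.

## Coordinate and sign conventions

One fixed convention is used everywhere, because the hemisphere-dependent
sign rules are the easiest place to hide a bug:

* Physical coordinates are right-handed, in micrometres. `+y` is the
  radial direction toward the pial surface, `x` the mediolateral in-slice
  axis, `z` the imaging depth.
* Arrays are indexed `(Z, Y, X)`, 1-based in R; voxel `i` covers the
  half-open interval `[(i-1)*v, i*v)` along its axis and has its centre at
  `(i-0.5)*v`. The mapping round-trips within half a voxel (tested).
* In-plane directions are measured from `+x`, counter-clockwise positive,
  in degrees; all angle outputs are wrapped to `(-180, 180]` and the wrap
  is idempotent.
* Directional changes are `wrap(dir[i+1] - dir[i])`, with the sign negated
  for left-hemisphere tracks, so a positive value carries the same
  anatomical meaning in both hemispheres. The direction-subtraction
  convention in the field is not standardized; this concrete rule is the
  package's documented choice, exercised by the wrap-around example
  (170&deg; followed by -170&deg; gives +20).
* Angles to the radial axis are signed with lateral positive and medial
  negative. Lateral is `+x` in the right hemisphere and `-x` in the left,
  so a purely lateral step is +90&deg; in either hemisphere and flipping
  the hemisphere is an exact sign involution (property-tested).

## Trajectory statistics

`frameSteps()` emits one step per consecutive sample pair with the
midpoint time, displacement, speed (`displacement / dt`, exactly) and
in-plane direction. Design choices:

* **2D directions, dual-mode speeds.** The emulated acquisition merges
  about ten focal planes (~50 µm) before tracing, so directions and
  turning angles are computed in the slice plane only; speeds use the full
  3D displacement when `z` is present, and the in-plane speed is reported
  alongside.
* **Strict thresholds.** The speed gate (default 10 µm/h), motility
  displacement (20 µm within the first 24 h) and detection size filter
  (6000 µm³) are all strict inequalities ("more than", "over", "larger
  than"). A frame at exactly 10 µm/h is *not* gated.
* **Gated frames only.** Angular statistics use gated steps; consecutive
  gated steps are differenced directly, with intervening sub-gate frames
  skipped rather than interpolated. Zero-displacement steps carry no
  direction and are excluded from angular statistics.
* The radial axis is supplied per field as a `CorticalFrame` (in curved
  cortex it was determined per cell by eye in the source workflows; a
  per-field configured axis is the reproducible stand-in).

`polarSummary()` reports the net in-plane displacement of a track in polar
form (distance, signed direction from the radial axis); a closed loop has
distance 0 and an undefined, flagged direction.

## Vessel association

`buildVesselMask()` thresholds the vessel channel (voxels at or above the
threshold), removes 26-connected components below a configurable size, and
derives (a) the *surface*: occupied voxels with at least one empty
6-neighbour, and (b) a medial-axis curve *skeleton* by ordered topological
thinning (simple-point tests under the standard 26/6 foreground/background
connectivity pair, peeling in erosion-depth order, followed by pruning of
discretization spurs down the erosion-depth gradient). The skeleton is
kept for QC only; all distances are computed to the surface, matching the
"center to surface" convention of a voxelized reconstruction.

* **Distances** are Euclidean, in physical µm, from each centroid to the
  nearest surface-voxel centre; anisotropic voxel sizes are honoured, and
  centroids inside the occupancy get distance 0. No sub-voxel surface
  interpolation is attempted; geometric assertions therefore carry a
  half-voxel-diagonal tolerance.
* **Edge exclusion** flags (never deletes) cells within 15 µm of either Z
  face or within 20 µm of any XY border, because their true nearest vessel
  may lie outside the imaged volume; the Z rule takes precedence when both
  apply. Input and output cardinalities are always equal.
* **Association** is the fraction of included cells strictly closer than
  5 µm to the surface, with a 2.5 µm-bin histogram for peak inspection.
  The reference population is a uniform nuclei cloud restricted to the
  central Z window whose margins equal the Z exclusion.
* **On/off classification**: with the default contact tolerance of 0 a
  frame is "on" iff its position falls inside the mask occupancy (the
  pixel-overlap reading of "fused" signals); the tolerance is exposed
  because signal fusion in rendered imagery is a heuristic, not a distance
  rule. Contiguous on-periods come back as a run-length segmentation.
* **Persistence**: tracks with a contiguous on-period of at least 5 h are
  selected and their maximum distance from the start position over the
  whole observation is reported; others return `NA` (not selected).
* **Off/on ratios** count only tracks traceable at least 10 h; a whole
  track is called "on" when the majority of its labelled frames are on
  (ties count as off). The majority rule is a package choice — the source
  workflows separate trajectories by signal fusion without stating a
  per-track aggregation — and its threshold is deliberately simple; a
  field with zero on-tracks yields a flagged `NA`, never infinity.

## Cortical depth distributions

`detectDoublePositive()` operationalizes co-labelling as the voxelwise
product of two channels (double precision; a saturated product widens,
never wraps), thresholded and segmented by 26-connectivity; a component
must contain a local intensity maximum of the product and have physical
volume strictly above the size filter. The product threshold has no
universal default — it depends on the rendering amplitudes — and is a
required parameter. Synthetic cells are rendered as isotropic Gaussians
whose half-maximum isosurface encloses the requested volume, so
thresholding the product at `(amplitude/2)^2` recovers the designed volume
analytically and the 6000 µm³ filter is testable exactly.

`relativeDepth()` projects centroids onto the inward normal (minus the
radial axis) and maps them affinely so the upper (pial-side)
cortical-plate border is 0 and the lower border 1; out-of-range cells are
flagged and excluded from binning. Borders are straight lines per field;
curved-border polylines are out of scope. `binDistribution()` uses
`nBins` equal-width bins (default 4; configurable because different
analyses bin differently), bin 1 most superficial, internal edges
half-open toward the deeper bin (depth 0.25 with four bins falls in bin
2) and the last bin closed; counts always sum to the number of in-range
depths. Both the continuous depths (violin-style display data) and the
binned counts are produced from the same values.

`compareBinFractions()` performs per-bin group comparisons with the
*brain* as the unit of analysis (per-brain bin fractions), Dunnett
many-to-one against a control by default or Tukey all-pairs; groups with
a single brain are rejected for inference and reported descriptively
(mean ± SD).

## Statistical layer

`runTest()` exposes Welch and Student t (selection guided, never silently
applied, by the two-sided F-test `varianceGate()` at alpha 0.05),
Mann-Whitney (exact when sample sizes allow and no ties; normal
approximation with continuity correction otherwise), Dunnett, Tukey-Kramer
and Kruskal-Wallis-gated Dunn post hoc tests, all two-sided, each report
carrying its unit of analysis. Group inference defaults to per-brain
units; distribution displays use per-cell or per-frame units.

Numerical choices worth knowing:

* **Dunnett** adjusted p-values are computed from the defining
  equicorrelated multivariate-t integral
  (correlations `lambda_j * lambda_k`,
  `lambda_j = sqrt(n_j / (n_j + n_0))`) by deterministic nested adaptive
  quadrature — no random quasi-Monte Carlo, so results are reproducible to
  ~1e-8 and the two-group case reduces exactly to the pooled t test
  (tested). No multivariate-t package is required.
* **Dunn**'s z uses the tie-corrected rank variance and a
  Bonferroni-family adjustment over the comparison set; the adjustment
  name is recorded in the report because the field's tools do not agree on
  one.
* **Descriptives** follow the box-plot convention with whiskers at exactly
  1.5 × IQR below/above the quartiles, plus mean, SD, SEM, median and
  quartiles. Stars map strictly at 0.05/0.01/0.001/0.0001.

## The synthetic world

The generator states one concrete world and keeps it; every default is a
field-plausible value chosen once.

| parameter | default | why |
|---|---|---|
| duration, frame interval | 24 h, 0.25 h | within the emulated 10-30 min acquisition range |
| field | 256 × 256 × 64 µm | a confocal field with ~50-60 optical sections at 1 µm |
| erratic speed | lognormal, mean 30, SD 12 µm/h | fast mode, clearly above the 10 µm/h gate |
| erratic turning SD | 60&deg; | no measured dispersion exists for erratic cells; this is a calibration choice producing "almost random" yet connected paths, flagged as such |
| erratic drift | +5 µm/h along +y | the surface-ward tendency, added as a constant velocity component; inflates realized mean speed by < 1% |
| radial speed | lognormal, mean 12, SD 5 µm/h; turning SD 10&deg; | slower, strongly directed |
| vessel-guided speed | 20 µm/h; attach 0.5/frame within 5 µm; detach 0.02/frame | produces realistic attach/detach episodes within 24 h |
| vessels | 70 segments, radius 2 µm, length ~U(30, 50) µm, 70% within 30&deg; of radial | a sparse capillary bed (~0.9% volume fraction) with the radial predominance of the cortical plate |
| nuclei | 1000 uniform points | the non-selected DAPI reference |
| rasterization | 1 µm isotropic voxels, amplitude 100, noise SD 1 | two-channel stacks in (Z, Y, X) |

Radially biased segment orientations are drawn uniformly inside the
30&deg; cone with the bias probability and uniformly outside it otherwise,
so the radial fraction is exactly binomial. Capsules are inset by one
radius so the whole tube — and any cell riding it — stays inside the
imaged field. Vessel-guided agents ride at half a radius from the segment
axis: within one radius by construction, and far enough inside the capsule
that voxelized contact classification at 1 µm voxels agrees with the
ground-truth flags exactly rather than flickering at the surface.

**What the generator does not emulate** — and hence what a green test does
not establish: vessel growth and angiogenesis (the observed
vessel-bridging behaviour is descriptive only), point-spread-function and
photobleaching realism, cell divisions within tracks, curved cortical
geometry, and motion blur. Tests against this world validate the
*measurement* code, not biological claims.

## Degenerate inputs and tie-breaks

* Zero requested segments: a valid empty network with volume fraction 0.
  An empty thresholded mask is valid but flagged, and distances against it
  are an explicit error.
* Duplicate track timestamps are rejected naming the offending index; a
  track with fewer than two gated directed steps yields an empty (not
  erroneous) directional-change list.
* Exactly-at-threshold values: speed gate, motility displacement,
  association distance and size filter are strict; minimum on-vessel hours
  and traceability hours are inclusive ("at least"); bin edges go to the
  deeper bin; off/on majority ties count as off.
* Both-groups-zero variance makes the F gate return "equal" by convention,
  flagged.

## Pipeline and reproducibility

`runPipeline()` chains simulate → track-stats → vessel-dist → classify →
distribution → report, accepts stage subsets when upstream outputs exist,
fails fast naming any missing dependency, and writes a manifest with the
resolved configuration, seed, per-stage timings and MD5 hashes of every
output; deterministic stages reproduce their hashes when re-run with the
same seed. All randomness flows from one master seed through per-generator
sub-streams. Configurations travel as JSON with snake_case keys and
unknown keys rejected. Being an R package, the pipeline's interface is
this function plus the exported building blocks; the stage names mirror
what a shell tool would expose as subcommands.

## Known limitations

* Distances are to surface-voxel centres; at coarse voxels this biases
  distances upward by up to half a voxel diagonal.
* The thinning skeleton is quality-control output; it is pruned
  heuristically and not guaranteed minimal, and it is skipped by default
  in the full-field pipeline for speed.
* Automatic tracking (detection-to-linking) is out of scope: tracks are
  inputs, via the CSV dialect or TrackMate-style XML with physical units.
* Lineage splits are not modelled; each track is one cell.
* The TIFF layer covers the uncompressed little-endian grayscale baseline
  (8/16-bit unsigned, 32-bit float) — sufficient for interchange with
  common scientific writers, not a general TIFF implementation.
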