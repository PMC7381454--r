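---
title: "Tracking a hexagonal-grid pursuit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a hexagonal-grid pursuit: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexpursuit)
```

`hexpursuit` extracts beat-indexed predator–prey trajectories from overhead
video of a pursuit played on a hexagonal-grid board, and analyzes the
resulting distance data. This vignette explains the geometry, each pipeline
stage and its tunable parameters, what the synthetic renderer does and does
not emulate, and the design decisions taken where the problem was genuinely
open.

## The board and its lattice

The board is a 94 × 61 cm rectangle ruled with *flat-topped* hexagons of
circumradius (cell "size") 1.5 cm. A flat-top hexagon of size $s$ has
width $w = 2s$ and height $h = \sqrt{3}\,s$; for $s = 1.5$ cm that is
3 cm × 2.598 cm. The cell *centers* form a triangular lattice: every
neighbor pair — vertical or diagonal — is separated by exactly $h$. This
uniform spacing is what makes both the consistency repair and the px/cm
calibration well-posed.

Cells carry axial indices $(q, r)$: column $q$ advances $3w/4$ rightward,
odd columns are shifted up by $h/2$. A cell belongs to the grid iff its
center lies strictly inside the board rectangle; the lattice anchor is the
cell whose center sits at $(w/2,\,h/2)$ from the board's lower-left corner.
Physical coordinates are cm, origin lower-left, y up; pixel coordinates are
0-based, origin top-left, y down. The map between them is the axis-aligned
affine $x_{px} = o_x + s_{px/cm}\,x_{cm}$, $y_{px} = o_y - s_{px/cm}\,y_{cm}$
(the camera is assumed perpendicular to the board, so no rotation or
perspective terms; see Limitations).

Nearest-cell lookup is an exhaustive scan over cell centers. Exact
distance ties — which arise only for points on cell-boundary midlines —
are broken toward the smallest $(r, q)$ lexicographically. The rule is
arbitrary but fixed, which keeps trajectory formation deterministic.

## Grid detection

`detect_grid_centers()` recovers the cell centers from an image of the
board without supervision:

1. **Canny edges.** Gaussian blur (σ = 1), Sobel gradients, non-maximum
   suppression, hysteresis with thresholds 0.1/0.3 of the gradient range
   (configurable). On a line-ruled board every hexagon edge produces a thin
   double edge.
2. **Closed-boundary tracing.** The connected regions of the *complement*
   of the edge map that do not touch the image border are exactly the
   areas enclosed by traced boundaries — one per hexagon interior. Regions
   smaller than `min_region_px` (20 px), regions filling less than half
   their bounding box (the slivers between double edges), and area
   outliers (outside 0.4–1.8 × the median, e.g. several interiors merged
   through a gap) are discarded.
3. **Centroids.** Each surviving region's pixel centroid estimates its
   cell center. A boundary's "common intersection point" is ill-defined
   for a traced pixel boundary; the centroid is the natural estimator and
   is unbiased for a symmetric hexagon.
4. **Consistency check and repair** (`validate_and_repair`). A center is
   accepted if at least two other centers sit at the expected lattice
   spacing within a relative tolerance (default ±15 %). Rejected centers
   are replaced by the nearest vacant site of the ideal triangular lattice
   least-squares-fitted to the accepted centers, and flagged. The check is
   defined on neighbor-center spacing, which is exact for this lattice at
   any orientation of the corner labels; the traditional corner-bearing
   list is retained in `grid_detector_config()$corner_angles` as a
   diagnostic field only, because corner bearings of a flat-top hexagon
   (0°, 60°, …) do not form a 45°-family and a spacing criterion is the
   geometrically well-defined version of the same idea.
5. **Matching and calibration.** The lattice spacing is refined by a
   least-squares fit of detections to integer lattice indices; the
   translation is chosen by anchoring a central detection to each nearby
   grid cell and keeping the candidate with the most (then tightest)
   matches — robust to missing and spurious detections, where a centroid
   alignment is not. Cells with no detection within 0.35 spacing get their
   affine-implied position, flagged as repaired. The scale of the final
   least-squares affine fit is the px/cm calibration.

## Marker detection

Two independent per-frame detectors, run in parallel by `track_trial()`:

**Prey (bright red point).** A pixel is "red" iff
$R - \max(G, B) > 60/255$: plain red-channel separation also fires on the
white board, so a dominance margin is required. A 3 × 3 median filter
removes isolated speckles (for a binary mask the median is exactly a
majority vote, computed as a box sum). A circular Hough transform over
radii 3–10 px then votes from the mask's edge pixels; the strongest
accumulator peak — votes normalized by circumference so no radius is
favored — gives the center, refined to sub-pixel by a vote-weighted
centroid around the peak. Detection is declared missing below a minimum
vote count (6).

**Predator (black dot).** The frame is binarized with foreground = darker
than 0.25 of the dynamic range. Otsu's method is available
(`binarize_method = "otsu"`) but is not the default: on a board covered in
grey rule lines Otsu splits paper from lines and floods the foreground
with the entire lattice web, whereas a near-black marker is far darker
than any rule line, so a fixed dark threshold isolates it cleanly.
Components with fewer than ten pixels are removed (8-connected labelling),
a morphological close (disk of diameter 5 px) consolidates the dot, and
the center is the minimum enclosing circle of the largest surviving
component.

Frames where a marker is not found keep the last detected position and are
flagged `missing`; leading gaps are backfilled from the first detection.
This hold-last policy is the simplest defensible choice for markers that
move at most one cell per beat.

## Beats, snapping, and the distance metric

At 50 fps and 70 bpm there are $50 \cdot 60 / 70 = 42.857$ frames per
beat — deliberately non-integer. Beat $k$ is sampled at the *nearest*
frame to $k \cdot 42.857$, bounding the timing error by half a frame
(10 ms). The number of beats in a window of $F$ frames is
$\lfloor (F-1)/42.857 \rfloor + 1$, and the renderer sizes a trial of $B$
beats as $\lceil (B-1) \cdot 42.857 \rceil + 1$ frames so that sampling
recovers exactly $B$ beats.

Sampled pixel positions are converted to cm through the calibration and
snapped to the nearest cell center. The per-beat predator–prey distance is
the Euclidean distance between the *snapped* centers, in cm; the trial
statistic is its mean. Snapped distances are the default because grid
association is part of the measurement model (both agents genuinely occupy
cells); `distance_series(use_raw = TRUE)` computes raw-position distances
for sensitivity analysis. Trajectories of unequal length are truncated to
the common beat range with a warning.

## Movement patterns

All three generators emit one cell per sequence step with consecutive
cells identical or lattice-adjacent — the metronome constraint.

* **Predictable**: the ideal path advances one cell width per beat
  rightward with $y(t) = y_0 + A \sin(2\pi f t)$, $f = 0.19$ Hz,
  $A = 7.5$ cm (2.5 hexagon widths), beat $k$ at $t = k \cdot 60/70$ s.
  The path is densely sampled (s/20 steps), snapped to cells, and bridged
  by greedy neighbor steps wherever quantization skips a cell — the
  straight-line "imitation" of a sinusoid that a hexagonal lattice
  permits. Phase starts at 0 at the start cell. Note the lattice cannot
  sustain a full cell width (3 cm) of horizontal progress per *lattice*
  step (max 2.25 cm), so one sinusoid period spans more sequence steps
  than ideal beats; quantization-aware comparisons should measure the
  period from the emitted path.
* **Random**: a seeded walk to uniformly drawn lattice neighbors;
  off-board moves are excluded and leftward moves are resampled with
  probability `drift_bias` (0.5), which produces the left-to-right trial
  structure without forbidding retreat.
* **Semi-random**: alternating segments that follow the predictable
  reference path and segments of the drifting random walk, segment lengths
  geometric with mean `segment_mean` (default 6 beats). The construction
  interpolates between the two defined extremes with a single parameter:
  as `segment_mean → Inf` (sinusoid first) it *is* the predictable
  pattern, and at `segment_mean = 1` it is random-dominated.

A checkable proxy for "varying predictability": the predictable pattern's
autocorrelation at one (path-measured) period exceeds the random
pattern's, averaged over seeds — asserted in the test suite.

## The synthetic renderer

`trial_renderer()` draws the board (white 245/255, hexagon outlines at
0.55 grey), the prey as a (230, 30, 30) disk of radius 6 px and the
predator as a (20, 20, 20) disk of radius 5 px, at a default 10 px/cm in a
1280 × 720 frame — the recording conditions being emulated. Two noise
processes are modelled: a linear illumination gradient (default ±10 %
left-to-right; the mild nonuniformity of an ambient-lit room) and
per-frame single-pixel bright-red speckles (default 20; stray laser
reflections, chosen red so they actually stress the prey detector's
median filter). Agents move by *linear interpolation* between consecutive
beat centers, which is harsher on the per-frame detector than the discrete
hops of the physical game and therefore conservative. Ground truth records
every frame's true centers and every beat's true cell; long trials are
rendered frame-by-frame through a closure so nothing holds thousands of
frames in memory.

What the renderer does **not** emulate: laser bloom and specular physics,
perspective or lens distortion, motion blur, camera sensor noise, hands
and bodies over the board. Passing round-trip tests therefore demonstrate
the pipeline's correctness under controlled optics, not robustness to
every artifact of real footage.

## Statistics

For an $n \times k$ subjects × conditions matrix, `rm_anova()` partitions
$SS_{total}$ into subjects, conditions, and error;
$F = MS_{cond}/MS_{err}$ with $(k-1)$ and $(k-1)(n-1)$ degrees of freedom,
both deflated by the Greenhouse–Geisser
$\hat\varepsilon = \mathrm{tr}(S^*)^2 / \big[(k-1)\sum_{ij} S^{*2}_{ij}\big]$
computed from the double-centered condition covariance $S^*$ ($\hat\varepsilon = 1$
exactly at $k = 2$, where sphericity is vacuous). Both
$\eta^2 = SS_{cond}/SS_{total}$ and
$\eta^2_p = SS_{cond}/(SS_{cond}+SS_{err})$ are reported, because a bare
"η²" in a repeated-measures report is ambiguous between the two.
`paired_comparisons()` runs two-sided paired t-tests with
$d = \bar{x}_{diff}/s_{diff}$ and a Bonferroni multiplier equal to the
number of comparisons actually requested. Zero difference variance flags
$d$ undefined rather than fabricating a value.

The layer is validated two ways: exact agreement (within $10^{-8}$) with
independent oracles (`stats::aov` with an `Error(subj/cond)` stratum for
F, an eigenvalue-form ε, `stats::t.test` for the pairwise tests), and
parameter recovery — a planted shift of the U condition by 3
*within-subject* SDs must be detected at α = 0.001 with all paired
d > 1.5 in ≥ 95 % of 200 replicates. "Within-subject SD" is taken as the
SD of a within-subject condition difference, the noise scale on which the
paired d is defined; under that convention the planted effect is d = 3
and the recovery bound is comfortably stable, whereas measuring the shift
in per-condition SDs would plant d ≈ 2.1 and leave the 1.5 threshold
within sampling noise of $\hat d$ at n = 20.

## Numerical choices and problem sizes

* Tolerances: lattice-spacing acceptance ±15 %; detection-to-cell matching
  0.35 spacing; geometric identities asserted at $10^{-9}$ relative.
* Exact nearest-cell ties snap within $10^{-12}$ relative squared
  distance before the lexicographic tie-break, so midpoint queries are not
  at the mercy of floating-point noise.
* The test suite and acceptance script keep the vision workloads at sizes
  chosen to exercise every stage end-to-end: the 68-beat trajectory-count
  trial runs on the full 94 × 61 board rendered at 4 px/cm (2873 frames);
  round-trip cell-recovery runs on a 30 × 20 cm board at 8 px/cm over 10
  seeds of 5-beat trials; grid-detection accuracy runs at the full
  1280 × 720 / 10 px/cm scale. Marker radii keep their pixel defaults
  across scales, so markers remain a little smaller than a cell.

## Known limitations

* No homography or lens-distortion correction: the calibration is a
  single scale plus translation and assumes a perpendicular camera, as in
  the emulated recording geometry.
* The consistency repair assumes the grid is axis-aligned in the image
  (again the perpendicular-camera assumption); a rotated board would need
  a rotation term in the lattice fit.
* The detectors are per-frame; there is no appearance model, Kalman
  smoothing, or multi-object data association. Occlusions longer than a
  beat simply hold position.
* The semi-random construction is one reasonable parameterization of
  "between predictable and random"; real printed semi-random trajectories
  from such experiments are instances of a class this generator emulates,
  not reproduces.
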