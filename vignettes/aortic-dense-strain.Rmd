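---
title: "Regional aortic wall strain from cine DENSE CMR: models and methods"
author: "aortadense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional aortic wall strain from cine DENSE CMR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortadense)
```

## The measurement problem

Cine DENSE (Displacement ENcoding with Stimulated Echoes) CMR stores the
in-plane displacement of tissue in the *phase* of each voxel: a voxel that
has moved by $d_i$ mm along axis $i$ since the encoding instant carries phase
$\varphi_i = 2\pi k_e d_i$, where $k_e$ is the encoding frequency in
cycles/mm (0.17–0.25 cyc/mm for the aortic protocols this package targets).
Acquired phase is only observable wrapped into $(-\pi, \pi]$. From a cine
series of magnitude and x/y-phase stacks, plus manually drawn luminal and
adventitial wall contours, the package reconstructs the motion of the aortic
wall over the cardiac cycle and summarizes it as a 16-sector circumferential
Green strain map and derived indices. The target vessel is thin (1–2 mm in
vivo), moves a few millimetres per beat, and deforms heterogeneously around
its circumference — which is exactly the signal of interest.

## Pipeline

`dense_strain()` chains the following stages; each is exported and
individually testable.

1. **Wall mask.** Contours are rasterized by the even-odd rule: a voxel
   belongs to the wall when its center is inside the adventitial polygon and
   outside the luminal one (`wall_mask()`).
2. **Phase unwrapping** (`unwrap_phase()`, `unwrap_series()`). Quality-guided
   flood fill restricted to the wall mask, one phase channel at a time, with
   the magnitude image as the quality map: the region grows by always
   admitting the highest-magnitude frontier voxel and adding the multiple of
   $2\pi$ that keeps the jump to its admitting neighbor below $\pi$.
   Disconnected mask components are unwrapped independently (with a
   warning). Spatial unwrapping leaves one global multiple of $2\pi$ per
   component undetermined; `unwrap_series()` resolves it by temporal
   continuity — frame 1 is anchored at a median phase of zero (displacement
   is zero at the encoding instant immediately after the ECG trigger), and
   each later frame takes the offset that brings its median phase closest
   to the previous frame's. This is valid whenever the wall moves less than
   half an encoding period ($1/2k_e$ mm, 2 mm at 0.25 cyc/mm) between
   successive 32 ms frames, which holds with a wide margin for aortic
   motion.
3. **Decoding** (`decode_displacement()`): $d_i = \varphi_i / (2\pi k_e)$.
4. **Spatial smoothing** (`spatial_smooth()`): each wall voxel's
   displacement is replaced by the unweighted mean over wall voxels within a
   Chebyshev radius of 1 voxel-space (2 at the infrarenal aorta, where the
   in vivo protocol required heavier smoothing); voxels outside the wall
   never enter the average.
5. **Forward tracking** (`track_forward()`). Every frame-$t$ entry is
   back-projected to its implied reference origin (observed position minus
   displacement). For each reference wall voxel the three nearest origins
   are found and its forward displacement $u_t$ is their
   inverse-distance-weighted mean; an origin coinciding with the voxel
   within $10^{-9}$ mm is used alone. The reference configuration is frame
   1, so $u_1 \equiv 0$.
6. **Temporal smoothing** (`temporal_smooth_positions()`): a centered
   moving average (default window 3 frames) of the tracked positions,
   truncated at the series edges rather than padded — fabricating
   pre-trigger samples would bias $u$ near frame 1 — then re-anchored so
   $u_1 = 0$ exactly. The upstream description of position time-smoothing
   does not pin down the operator; the moving average is the minimal
   smoother consistent with it, and the window is exposed so its effect is
   auditable.
7. **Sector elements and Green strain** (`build_sector_elements()`,
   `green_strain_element()`). The wall is divided into 16 equal angular
   sectors about the reference wall centroid (mean of the frame-1 mid-wall
   contour). Within a sector, voxels are pooled into four quadrants
   (inner/outer wall half × clockwise/counterclockwise arc half); each
   quadrant's mean reference position and mean trajectory become one node
   of a bilinear quadrilateral element. With shape functions $N_a$ on
   normalized coordinates $(\xi, \eta) \in [-1, 1]^2$, the referential
   displacement gradient at the element center is
   $H = (\sum_a u_a \otimes \nabla N_a) J^{-1}$ and the Green strain
   $E = \tfrac12 (H + H^T + H^T H)$, which is exactly zero under rigid
   motion. The gradient is taken with respect to *reference* coordinates
   (the referential/Green convention); the output records this.
8. **Cylindrical rotation** (`rotate_to_cylindrical()`). The local wall
   tangent at a sector is the central difference of the two adjacent
   sector element centers in the reference configuration; $E$ is rotated so
   that $E_{\theta\theta}$ is the circumferential component. The full
   tensor ($E_{rr}$, $E_{r\theta}$, $E_{\theta\theta}$) is retained, but
   only the circumferential component feeds the reported metrics.
9. **Assembly and time-smoothing** (`assemble_sector_map()`). Sector 1 is
   the first sector counterclockwise from the aorto-vertebral interface
   (AVI); an AVI exactly on a sector boundary starts numbering at the next
   counterclockwise sector. Scans with fewer than 12 of 16 valid sectors
   are rejected (mirroring in vivo exclusion of poor-signal scans); invalid
   sectors carry `NA` and downstream metrics use valid sectors only,
   recording `n_valid`. Each sector's strain series is smoothed by an
   ordinary least-squares fifth-order polynomial in frame index — refused
   below 7 frames, where the fit would interpolate noise.
10. **Metrics** (`select_systole()`, `compute_ncs()`,
    `heterogeneity_index()`, `mean_displacement_angle()`,
    `diastolic_geometry()`, `align_daa_map()`), described next.

## Summary indices

* **Local systole.** At the infrarenal (IAA) and mid-descending (DTA)
  aorta: the frame with the largest cross-sectional mean circumferential
  strain (earliest frame on ties). At the distal arch (DAA), where single
  sectors may peak in local diastole: the mean peak frame of the first six
  sectors that peak after the onset of local systole, rounded half-up.
  "Onset" is not defined quantitatively upstream; it is operationalized
  here as the first frame at which the mean strain exceeds 10% of its
  eventual maximum (`systole_threshold`, configurable and logged).
* **NCS.** Sector strain divided by the cross-sectional mean at local
  systole; mean NCS is exactly 1 by construction. *Maximum* NCS searches
  all frames, not only systole, since the extreme can occur in local
  diastole.
* **Heterogeneity index.** Sample standard deviation ($n-1$; $n = 16$ is
  small, and the sample convention is used consistently here and in the
  reproducibility CoV) of the 16 sector strains at systole divided by
  their mean. Zero for homogeneous deformation; invariant under strain
  rescaling.
* **Mean displacement angle.** Angle of the mean wall displacement at
  systole, zero pointing left-lateral, positive counterclockwise
  (anterior) in the axial anatomical view, degrees in $(-180, 180]$.
* **Geometry.** Diastolic diameter = mean of the frame-1 mid-wall
  contour's x- and y-extents (cm); relative aortic size = diameter / body
  surface area (cm/m²).
* **DAA alignment.** Because distal-arch cross-sections are
  patient-specific obliques, a fitted map may be rotated by at most ±1
  sector to maximize Pearson correlation with a caller-supplied reference
  map (ties prefer no rotation). The reference is an explicit argument: a
  library cannot presume a cohort to align within.

## Reproducibility metrics

`compare_maps()` compares two NCS maps of the same scan: mean absolute
sector difference, and a coefficient of variation defined as the sample SD
of the non-absolute differences divided by the mean NCS — fixed at 1 by the
normalization, not recomputed. The same metrics are recomputed over the two
largest local maxima and two smallest local minima of the circular
16-vector (strict inequality against both neighbors; a plateau counts once
at its lowest sector index), pairing each extremum with the nearest
same-type extremum of the other map by circular distance. Whether pairing
should match by rank or proximity is not specified upstream; proximity is
implemented, and maps with fewer than two extrema of a type use what
exists, recording the pair count. CoV ratings: good ≤ 0.20, fair 0.21–0.30,
poor > 0.30. `compare_three_way()` averages two pairwise reports for the
reader-2-versus-two-analyses design.

## The synthetic phantom

Without public DENSE acquisitions, validation rests on
`render_dense_series()`: an annulus whose motion is analytic, so every
stage has exact ground truth. The deformation is

$$x(X, t) = c + b(t) + \lambda(\Theta, t)(X - c), \qquad
\lambda = 1 + A\,p(t)\,\frac{1 + h\cos(\Theta - \Theta_{peak})}{1 + h},$$

a bulk translation plus an angle-dependent radial stretch. This family was
chosen because its circumferential Green strain has the closed form
$(\lambda^2 - 1)/2$ in the homogeneous case and a cheap finite-difference
oracle (`true_sector_strain()`, central differences at step ≤ 0.01 mm at
each sector's mid-wall point) otherwise. The inverse map is closed-form
(the deformation preserves rays from the moving center), so rendering
assigns each observed voxel the exact displacement of the material point
occupying it.

Defaults are the package's study conditions, fixed once: 18 frames at
32 ms; raised-cosine systolic profile peaking (exactly 1) at frame 8;
$k_e = 0.25$ cyc/mm; stretch amplitude $A = 0.10$, giving a peak mean
circumferential strain of 0.105 — the scale seen in vivo; bulk translation
$(1.0, -0.5)$ mm, which pushes the peak phase excursion just past $\pi$ so
that unwrapping is genuinely exercised; phase noise SD 0.05 rad (no in
vivo phase-noise figure is available upstream, so this free parameter is
reported with every acceptance run); wall radii 8/12 mm on a 1.0 mm, 48×48
grid. The 4 mm wall is deliberately thicker than the 1–2 mm in vivo wall:
it guarantees the ≥ 2-voxel wall thickness the method requires with margin,
so tests probe the estimator rather than the segmentation limit. Noise is
injected in phase (radians), not displacement, because that is where
acquisition noise lives; the magnitude image gets its own additive noise.
Contours are the analytically deformed circles at 128 vertices per frame,
so sector-assignment error from the polygonal approximation is far below
one sector. A displacement excursion beyond one encoding period
($|d| > 1/k_e$) is flagged `double_wrapped`: such motion is unrecoverable
by single-cycle unwrapping, mirroring in vivo exclusions for inadequate
encoding frequency.

What the phantom does *not* emulate: stimulated-echo signal decay, spiral
k-space readout and its artifacts, through-plane motion, fat signal, and
segmentation error (contours are exact). Passing tests therefore show the
*post-processing* recovers known kinematics from realistic phase data; they
do not certify performance against acquisition artifacts or imperfect
manual segmentation.

## Conventions

Image coordinates are mm, origin at the image corner, x rightward
(patient-left in standard transverse display), y downward (posterior).
All sector and angle arithmetic uses the *anatomical angle*: zero
left-lateral, increasing counterclockwise in the axial view (anterior up),
i.e. `atan2(-dy, dx)` in image coordinates. Sectors are half-open arcs
closed on their counterclockwise edge; a point exactly on a boundary
belongs to the clockwise sector — the same convention that sends an AVI on
a boundary to the next counterclockwise sector. Wrapped phase lives in
$(-\pi, \pi]$ with the boundary mapped to $+\pi$; one fixed convention
makes encode/decode tests bit-exact. Oblique distal-arch planes are
treated in their own in-plane frame with the AVI supplied as an angle
(defined in vivo from the anterior tip of the nearest in-plane vertebra).

## Numerical behavior and known limitations

* **Tracking interpolation bias.** The three-nearest inverse-distance
  interpolation is exact for constant fields and for origins coinciding
  with the query (the exact-hit rule), but it does not reproduce general
  affine fields: the weighted centroid of the three neighbors need not be
  the query point. On the phantom this produces a quasi-periodic strain
  bias that grows with stretch amplitude: with 1.0 mm voxels the sector
  strain matches the finite-difference oracle within 0.005 at $A = 0.10$
  (uniform case) and within about 0.01–0.012 at $A = 0.15$. The element
  machinery itself is exact to ~1e-13 on analytically tracked
  trajectories, so this interpolation is the accuracy floor of the
  pipeline; it is the specified estimator, not an implementation artifact.
* **Peak attenuation.** The window-3 moving average and the degree-5
  polynomial fit attenuate the systolic strain peak by about 0.003 and
  0.001 respectively at $A = 0.10$. Noise-free validation runs therefore
  use `temporal_window = 1` (noise reduction has no purpose without
  noise) while keeping the polynomial smoothing, which is part of the
  strain pipeline proper.
* **Degenerate inputs.** Rigid-body-only motion yields near-zero mean
  strain and `compute_ncs()` refuses to normalize (the index is
  undefined); zero mean displacement flags the angle undefined rather
  than erroring; constant maps make the DAA alignment correlation
  undefined and return zero rotation with a flag; elements with a
  singular or ill-conditioned reference Jacobian (condition number >
  1e6) are flagged invalid rather than propagating garbage.
* **Ties.** Equal systolic maxima take the earliest frame; equal
  alignment correlations prefer rotation 0, then −1; equidistant
  neighbor origins in tracking resolve by entry scan order — all
  deterministic.
* **Problem sizes.** The test suite and the acceptance script run the
  phantom at 48×48 voxels × 18 frames (≈ 250 wall voxels per frame),
   which the package's own validation shows is enough to separate the
  heterogeneity signal from phase noise; a full pipeline fit takes on
  the order of a second on one core, and the complete validation suite a
  few minutes.
* **Not in scope.** Pulse-sequence simulation, automated segmentation,
  group statistics across subjects, and reporting of radial/shear strain
  as deliverable metrics (the full tensor is computed and retained, but
  thin-wall radial components are not reliable enough to report).
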