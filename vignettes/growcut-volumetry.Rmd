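---
title: "GrowCut segmentation and tumor volumetry: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GrowCut segmentation and tumor volumetry: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growcutvol)
```

## The automaton

GrowCut treats segmentation as bacterial competition on the voxel grid. Each
voxel carries a label $l_p$ and a strength $\theta_p \in [0,1]$; scribbled
voxels start with their class and $\theta = 1$, everything else unlabeled at
$\theta = 0$. In each synchronous iteration a voxel $p$ is conquered by the
neighbor $q$ maximizing the attack force

$$a(q \to p) = g\!\left(|c_p - c_q|\right)\,\theta_q, \qquad
  g(x) = 1 - \frac{x}{\mathrm{max\_diff}},$$

whenever that force *strictly* exceeds $\theta_p$; conquest copies the
attacker's label and sets $\theta_p$ to the attack force. Because $g \le 1$,
attack forces never exceed the attacker's own strength, every change strictly
increases $\theta_p$, and $\theta$ is bounded by 1 — together these guarantee
termination. Seeds can never be conquered (no force exceeds 1 strictly), so
scribbles are immutable by construction rather than by special-casing.

Assumptions worth stating: the model is purely intensity-driven (no shape or
texture prior), it presumes the foreground is *locally* distinguishable from
background along any path connecting the two scribble classes, and it is
sensitive to where the scribbles are placed — it is a semi-automatic method,
not an automatic one.

### Choices the automaton literature leaves open

* **Similarity kernel.** The linear $g(x) = 1 - x/\mathrm{max\_diff}$ is the
  classical choice and the one used here: bounded in $[0,1]$, maximal for
  identical intensities, zero at the largest observed neighbor contrast.
* **Normalizer** (`max_diff_policy`). Default `"neighbors"`: the maximum
  absolute intensity difference over all neighbor pairs *inside the ROI*.
  This adapts the kernel to local contrast; a global intensity range
  (`"range"`) is available but dilutes $g$ when the ROI is much flatter than
  the full image. A constant region (`max_diff = 0`) degenerates to
  $g \equiv 1$, i.e. pure strength propagation.
* **Update discipline.** Synchronous, double-buffered: all reads come from
  the previous iteration. Parallel implementations of this automaton are
  often asynchronous and traversal-dependent; we instead fix determinism as
  a contract — two runs on identical inputs are bit-identical, and the test
  suite enforces it.
* **Tie-breaking.** Among equal-force attackers the first offset in a fixed
  neighbor order wins (first axis varying fastest, $-1$ before $+1$; see
  `neighbor_offsets`). Strict inequality (">" not "≥") prevents label
  oscillation between equally strong fronts.
* **Neighborhood.** 26-connectivity (3D Moore) by default — the classical
  GrowCut neighborhood; 6-connectivity is available via `growcut_params()`.

### Speed-ups and their soundness

`growcut()` applies three optimizations; each is an identity on the result,
and `growcut_reference()` — a deliberately naive full-grid, no-bookkeeping,
on-the-fly reimplementation — is kept in the package as the oracle that the
optimized engine must match voxel for voxel (property-tested on randomized
instances).

1. **ROI restriction.** The automaton runs inside the axis-aligned bounding
   box of all scribbled voxels plus `roi_margin` (default 5 voxels). A
   bounding box is used rather than a rasterized convex hull: it is a
   superset of the hull, so it can never exclude a labeled voxel, and hull
   rasterization buys no correctness. Labels cannot leak outside the box;
   voxels there remain 0.
2. **Precomputed similarity weights.** $g$ is evaluated once per neighbor
   offset before iterating; since the identical expression would be
   evaluated on the fly, results are bit-identical.
3. **Saturation/activity tracking.** A voxel with $\theta = 1$ can never
   change again; a voxel none of whose neighbors changed last iteration
   cannot see a stronger attack than before. Both are skipped; global
   termination is detected when the changed count reaches zero.
   `max_iterations` (default 500) is a guard only — normal exit is
   convergence, typically after a few tens of iterations at clinical sizes.

## Post-editing

Automatic results are cleaned with an ordered sequence of binary operations:
dilation and erosion (cross or full-cube structuring element per the step's
connectivity, radius realized by iteration) and island removal (connected
components below `min_size`, or everything but the largest component,
removed). The default pipeline is keep-largest island removal only;
dilation/erosion are opt-in, since appropriate radii are inherently
case-dependent. Ties for the largest component are broken by scan order
(smallest linear index), which makes batch runs reproducible.

## Volumetry and evaluation

Physical volume is voxel count times voxel volume (product of the three
spacings, mm³); study summaries convert to cm³. Agreement is the Dice
coefficient $2|A \cap B| / (|A| + |B|)$, reported in percent in the tables.
Two conventions are fixed here because the standard definitions are silent:
Dice of two empty masks is 1 (identity semantics), and all spreads are
*sample* standard deviations ($n-1$) — the form under which the bundled
ten-case study records reproduce their published summary row exactly
(81.97 ± 3.39 % DSC; 6.37 ± 3.96 vs 6.47 ± 4.14 cm³).

The geometric models (`geometric_volume()`) are included for comparison with
quick diameter-based clinical practice: spherical $\pi d^3/6$, ellipsoid
$\pi abc/6$, mean-radius $\tfrac43 \pi \bar r^3$, and the caliper formula
$a b^2/2$. The ellipsoid and caliper forms are the standard ones from the
respective measurement traditions. `macdonald_area()` implements the
bidimensional size measure — largest in-plane diameter times the largest
extent perpendicular to it — by brute force over boundary voxel centers
(projection extrema are attained on the convex hull, so the boundary
suffices); the slicing plane is caller-chosen, axial by clinical convention.
A single-voxel mask degenerates to one voxel extent per diameter, a
documented convention rather than a claim. Response is the inclusive
$\ge 50\,\%$ area reduction.

## The phantom: what it emulates, and what it does not

`make_phantom()` builds a homogeneously contrast-enhancing ellipsoid (the
intensity profile typical of pituitary adenomas on contrast T1) in a darker
background, plus i.i.d. Gaussian noise; `make_scribbles()` emulates the
interactive initialization by eroding the truth (the painted "area inside")
and placing a dilated shell outside it (the "stroke outside"). Choices:

* **Inside test on voxel centers**, strictly inside the ellipsoid — this
  makes lattice-point counting an exact oracle for the ground-truth volume.
* **Size presets** `small`/`medium`/`large` (≈ 0.78, 6.36, 15.27 cm³) span
  the tumor-volume range of clinical pituitary adenoma series, so the tests
  exercise the same scale regime as practice.
* **Default intensities** 120 vs 20 with `noise_sigma = 10`, i.e. noise at
  10 % of the intensity gap — an easy but not trivial contrast-to-noise
  regime for an enhancing lesion.
* **Gaussian, not Rician, noise**: the recovery properties tested are
  threshold-based and tolerant, and the simpler model keeps the generator
  transparent. Reproducibility is bit-exact for identical parameters and
  seed, and the generator never disturbs the caller's RNG stream.

What the phantom does *not* emulate: partial-volume effects at the tumor rim,
bias fields, anatomical neighbors of similar intensity (vessels, normal
gland), and operator variability in scribble placement. Passing the phantom
recovery tests therefore shows the engine and pipeline are correct and
robust at realistic contrast — it does not certify clinical accuracy, which
in practice is dominated by precisely the factors above and by post-editing.

## Data model and I/O conventions

Voxel coordinates are 1-based R array indices in (i, j, k) order — the native
convention of R and of the R imaging packages this builds on — converted to
mm only inside volumetry. Orientation/direction matrices in NRRD or NIfTI
headers are carried through I/O untouched but ignored by computation; nothing
in the method depends on patient orientation. Label 1 means tumor and 2
background everywhere, with binary masks derived as `labels == 1`; this fixes
an ambiguity that multi-label files otherwise leave open. Label maps are
written with an integer on-disk type in both formats so round trips are
lossless; the NRRD writer/reader is a minimal NRRD0004 implementation (raw,
gzip and ascii encodings, axis-aligned space directions) — the format of the
ecosystem this workflow comes from.

## Problem sizes used by the tests

The test-suite and acceptance-script sizes were chosen as the smallest
instances that still exercise every mechanism: 12³ grids with random
scribbles for engine-vs-oracle equivalence (50 instances; the naive oracle is
deliberately slow), 64³ default phantoms across 10 noise seeds for recovery,
and hand-simulable 1×1×5 / 1×1×6 lines for the update rule itself, whose
converged labelings were derived by brute-force simulation of the rule before
being frozen into the tests.

## Known limitations

Two-class use is the tested regime: the engine accepts more labels, but all
guarantees and tests target foreground/background. No GPU or multithreaded
execution; no DICOM series input; no resampling or registration — volumes
being compared must share a grid. The reference engine is quadratic-ish in
practice (all voxels, every iteration) and is meant for small oracle grids,
not clinical volumes.
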