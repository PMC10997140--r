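---
title: "Mapping CSv-adjacent streamlines onto major white matter tracts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping CSv-adjacent streamlines onto major white matter tracts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csvtracts)
```

## The analysis this package implements

The cingulate sulcus visual area (CSv) is a small, bilateral, functionally
defined region in the posterior mid-cingulate sulcus that responds
selectively to optic flow consistent with self-motion. A natural anatomical
question is which major white matter tracts carry its connections. The
analysis chain implemented here answers a phantom-testable version of that
question:

1. **Candidate streamlines** from whole-brain tractography, pooled across
   several tracking-parameter settings (ensemble tractography), are
   **filtered** with a linear fascicle evaluation (LiFE) style model:
   every candidate receives a non-negative weight by how much it helps
   predict the measured diffusion signal, and zero-weight candidates are
   discarded.
2. **CSv streamlines** are selected from the filtered set: any streamline
   with an endpoint within 3 mm of a CSv voxel centre, per hemisphere.
3. Each CSv streamline is **assigned to one of seven tracts** — SLF I, II,
   III, the cingulum, the callosal fibres, the arcuate fasciculus (AF) and
   the corticospinal tract (CST) — by Boolean waypoint-ROI rules: a
   streamline belongs to a tract if it passes through *all* of that
   tract's waypoint ROIs (two ROIs for the CST, one for each other
   tract); otherwise it is `UNCATEGORISED`.
4. Per subject and hemisphere, the **proportion** of CSv streamlines in
   each tract is computed; across subjects each tract × hemisphere cell
   gets a **two-sided one-sample t-test against zero**, with significance
   declared at a Bonferroni-corrected level (0.05/7, reported as 0.007).

Because the original per-subject imaging data are not deposited, every
stage is exercised end-to-end on synthetic phantoms with known ground
truth; the phantom generator is first-class, tested code.

## The phantom and its forward model

`phantom_spec()` defines a scene on a voxel grid (default 41×41×41 voxels
of 2 mm, centred on the world origin so that left/right map to
negative/positive world *x*). Seven geometrically separated tube bundles
stand in for the tracts: stacked anterior–posterior SLF branches, a
cingulum adjacent to the CSv blob, a left–right callosal bundle crossing
the mid-sagittal plane, an inferior–superior AF stand-in, and an
inferior–superior CST with the two-ROI topology. Each bundle realises
`n_streamlines` (default 100) polylines: the centreline translated by a
random in-disc offset (radius 3 mm) plus small smooth jitter (0.15 mm
s.d.). A configurable fraction (default 30%) of each bundle's streamlines
is rerouted after its last ROI station to terminate inside a 2.5 mm
capture ball around the CSv blob's central voxel — safely inside the 3 mm
selection distance — so the set of "CSv streamlines" is known exactly by
construction. Generation fails if any two bundles' waypoint ROIs come
within two voxel widths of each other, and an audit (`check = TRUE`)
verifies every truth streamline crosses all of its own ROIs and no other
bundle's.

The diffusion signal follows a multi-stick voxel model,

$$S(\mathbf g, b) = S_0\Big(\textstyle\sum_k f_k\,
  e^{-b\,d_{ax}(\mathbf g\cdot\mathbf t_k)^2} + f_{iso}\,e^{-b\,d_{iso}}\Big),$$

with axial (stick) diffusivity $d_{ax} = 1.0\times10^{-3}$ mm²/s and
free-water diffusivity $d_{iso} = 3.0\times10^{-3}$ mm²/s — typical
literature values, both configurable. The orientation field is built from
the *realised* truth streamlines: every node (1 mm resampling) deposits a
stick with its local tangent in the voxel it falls in, and stick volume
fractions scale with per-voxel node counts (fibre density ∝ summed path
length), normalised so the densest voxel reaches $1 - f_{iso,wm}$
(default 0.8). Free water fills the remainder of every voxel, so
fractions always sum to 1. Two properties follow by construction: every
white-matter voxel is traversed by at least one generating streamline,
and the noiseless signal is *exactly* the stick forward model of the
generating set — which is what makes exact LiFE recovery a meaningful
test (below). Noise is Rician, $|S + n_1 + i\,n_2|$ with
$n_{1,2}\sim N(0, S_0/\mathrm{SNR})$, matching magnitude MR images; a
Gaussian option exists for analytic tests, and $\mathrm{SNR}=\infty$
gives the exact forward model. The default acquisition scheme mirrors the
study design: 64 gradient directions (a deterministic spherical Fibonacci
set) at b = 1000 s/mm² plus six b = 0 volumes.

Candidate sets emulate pooled probabilistic tractography at desk scale
(thousands rather than millions): jittered copies of truth streamlines
(interior jitter 0.2 mm s.d. by default; endpoints exact so CSv proximity
is preserved) plus spurious distractors — smooth random walks (2 mm
steps, direction perturbed by 0.35 s.d. per step, reflected at the grid
border) whose local orientations are decorrelated from the bundle field.
Each candidate carries one of four provenance tags named after the four
tracking angle thresholds (5.7, 11.5, 23.1, 47.2 degrees), and all
candidates respect the 4–250 mm length bounds.

### What the phantom does not emulate

No cortical folding or grey matter, no fibre fanning or bottlenecks
beyond per-voxel multi-stick crossings, no registration to a template
space, no eddy/motion artefacts, and waypoint ROIs are clean axis-aligned
boxes rather than hand-drawn anatomical slabs. Passing tests therefore
demonstrate the correctness of the *logic* — selection arithmetic, rule
evaluation, solver behaviour, statistics — not robustness to anatomical
ambiguity, which on real data is absorbed by manual ROI placement.

## Stage-by-stage numerical choices

**Coordinates.** Voxel indices are 0-based; the voxel centre of index
$(i,j,k)$ sits at `affine %*% c(i,j,k,1)` in world RAS mm. All internal
computation is in world mm; the TCK and TRK dialect conventions
(including TRK's half-voxel "voxmm" offset) are resolved only at the I/O
boundary, and round trips are lossless to single precision. Per-streamline
metadata travel in a plain-text sidecar table keyed by streamline index,
which keeps them diffable and dialect-independent.

**Tensor fit.** Ordinary (unweighted) log-linear least squares of
$\ln(S/S_0) = -b\,\mathbf g^\top D \mathbf g$, with $S_0$ the mean b = 0
signal and non-positive signals clamped to $10^{-6} S_0$ before the log.
OLS was chosen over iterated weighted variants because it is
deterministic, exact on noiseless single-tensor signal (property-tested
over random SPD tensors), and sufficient for the map's descriptive role.
The PDD colour map uses the standard convention — red left–right, green
anterior–posterior, blue superior–inferior, intensity FA — and is
antipodally symmetric by construction.

**LiFE filter.** The design matrix has one row per (white-matter voxel,
gradient direction) pair and one column per candidate. Candidates are
resampled at half the voxel size (a step that cannot skip a voxel on the
lattice); each traversed voxel contributes the demeaned stick profile of
the local segment orientation, summed over nodes. The target is the
measured diffusion-weighted signal demeaned per voxel across directions,
which cancels direction-independent (isotropic) signal on both sides.
The non-negative least-squares problem is solved by cyclic coordinate
descent on the normal equations (compiled code): each coordinate update
is the exact one-dimensional minimiser, so the objective is
non-increasing — an invariant the tests assert — and iteration stops when
the KKT residual falls below `tol` (default 1e-10) relative to the
problem scale. Any solver meeting the KKT condition would be acceptable;
coordinate descent was chosen because it produces exact zeros at the
boundary and scales comfortably to the desk-scale problems here. The
culling threshold interprets "did not contribute" as numerically zero
weight: candidates with weight above $10^{-8}\times$ the maximum weight
are kept.

The LiFE recovery test runs in the exactly-representable regime: a
noiseless phantom whose 100 truth streamlines all enter the candidate set
unjittered, plus 100 distractors. There the signal is exactly explainable
and the filter zeroes every distractor while keeping every true
streamline. With jittered candidates the cull rate degrades gracefully —
the solver mops up the jitter residual with tiny distractor weights —
while the distractor *weight share* stays below 5%, which is the
invariant the realistic-regime test asserts.

**Selection.** "Within 3 mm" is read as inclusive (≤) and measured from
either endpoint to the nearest CSv voxel centre — the simplest verifiable
rule; at 2 mm voxels the centre-versus-boundary difference is up to one
half-diagonal and the threshold is configurable. A streamline qualifying
at both hemisphere masks is assigned to the nearer, ties to the left
(deterministic tie-break). Selection is validated against a brute-force
endpoint × voxel double loop and is monotone in the threshold.

**Classification.** `passes_roi()` performs exact segment–voxel-box
intersection by walking each segment through the half-integer lattice
planes of continuous index space. This is the default because it is
exactly the geometric predicate the waypoint rule describes; a sampled
mode (step = half voxel size) is provided and agrees away from
corner-clipping configurations. Assignment is exclusive by default with
precedence CST > AF > callosal > cingulum > SLF I > SLF II > SLF III,
chosen so that the partition invariant (counts sum to the input count)
is testable; multi-rule matches are logged in `overlap_log` before
precedence is applied, and a multi-label mode is available, since the
original reporting convention for such streamlines is not recorded.

**Statistics.** Two-sided tests and two-sided 95% CIs: reconstructing the
t statistic from a printed CI of the form mean ± t~crit~·SEM with n = 12
reproduces the published t values to the printed precision, which is the
package's evidence for this convention. SEM is sd/√n with the n − 1
denominator. Zero-variance and all-zero cells — e.g. a tract to which no
subject contributed a single streamline — are reported as "test not
performed" with a reason rather than dropped, and the per-tract
`presence_k / presence_n` columns count subject-hemispheres with at
least one streamline in the tract.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own trade-off between coverage and turnaround:
phantoms of 7 × 15–30 truth streamlines on the default 41³ grid, candidate
sets of 200–8000, oracle sweeps of 500–1000 random instances, Monte-Carlo
checks of 2000 replicates, and pipeline group runs of 2–3 subjects
(12 subjects, ~100 streamlines per bundle and candidate sets in the
thousands remain the documented defaults for real use). All randomness is
seeded; phantom generation, signal simulation, candidate pooling and the
full pipeline are bit-reproducible given a seed, and pipeline outputs are
stamped with a hash of the scientific configuration.

## Known limitations

* The LiFE forward model is pinned to a single-stick, fixed-diffusivity
  kernel with per-voxel demeaning; the published method's unreleased
  defaults (iteration counts, tolerances, surviving-streamline counts)
  are not reproduced, only its structure.
* Waypoint ROIs are supplied as masks. The anatomical drawing rules
  (sulcal landmarks, mid-sagittal plane, cerebral peduncle coverage) are
  documented mask-authoring guidance; nothing here re-derives them from
  anatomy.
* The phantom's geometric separability makes classification essentially
  noise-free; real tracts border each other, and the phantom cannot
  quantify boundary misassignment.
* Group statistics implement exactly the published design (one-sample t
  against zero, Bonferroni over seven tracts); no mixed-effects or
  non-parametric alternatives are offered.
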