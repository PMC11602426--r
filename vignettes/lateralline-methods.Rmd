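---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `lateralline` computes and why its defaults
are set the way they are. The package analyses aminoglycoside (AG)
ototoxicity in the zebrafish lateral line along three axes: hair-cell
survival dose–response, single-cell calcium dynamics, and subcellular
drug localization — and ships a synthetic-data generator that stands in
for microscopy and fish-count data so every stage can be validated
against known ground truth.

## Dose–response model

Each fish contributes one number: its hair-cell count summed over four
identified neuromasts. Counts are normalized to the mean of untreated
(dose 0) control fish of the same batch, so 100% is control survival;
normalization never crosses batches, because clutch, age and staining
batch all shift absolute counts.

Survival as a function of dose is modelled as a Hill curve with the
asymptotes fixed at 100% and 0%:

$$S(d) = \frac{100}{1 + (d/\mathrm{HC}_{50})^{h}}.$$

`fit_hill()` estimates $\log_{10}\mathrm{HC}_{50}$ and $h$ by
Levenberg–Marquardt least squares (`minpack.lm`), starting from the dose
whose mean survival is closest to 50% and slope 1.5. Controls are used
only for normalization, not in the fit. Free asymptotes are available by
flag for partial-kill data. Uncertainty comes from fish-level bootstrap
resampling (seeded; off by default so large replicate studies stay
cheap, switched on with `n_boot`).

A deliberate refusal: when no dose brings mean survival below 60%
(`max_survival_for_fit`), the curve does not constrain the midpoint and
`fit_hill()` returns a *not determined* outcome rather than an
extrapolated number. This mirrors the empirical situation for 1-h
gentamicin exposure, where maximal kill stays around 20%.

ANOVA-type comparisons (`timecourse_summary()`, `protection_stats()`)
run on **raw counts**, not on normalized survival: dividing every fish
in a group by the same noisy control mean injects the control's sampling
error into the between-group variance and inflates false positives
(observable in the package's own null-calibration test). Survival
percentages are the presentation and curve-fitting scale. Both use
type-II sums of squares (`car::Anova`); per-dose arm comparisons are
Welch t-tests, Šidák-adjusted across doses.

## Calcium analysis

Traces are per-cell mean intensities of hand-drawn ROIs on
maximum-projected, rigid-registered time lapses (30-s frames; a 2.5-min
pre-exposure baseline, i.e. 5 frames by default — the actual count is
taken from the data, not hard-coded). `dff()` divides by the baseline
mean, so the baseline-window mean of F/F₀ is exactly 1; the baseline SD
is computed on the same frames on the F/F₀ scale. The package exposes
the raw-intensity variant of the SD too, but defaults to F/F₀ because
the threshold then scales with the cell's own brightness.

A dying cell *responds* if F/F₀ exceeds baseline mean + 2·SD anywhere in
its response window, which ends at the fragmentation frame — signal
after a cell breaks up is meaningless — while living cells are scored to
the last frame. Maxima are taken over the full pre-fragmentation trace
(endpoint alignment is a presentation device; whether maxima were
computed before or after alignment does not change them). Missing frames
are excluded, never imputed.

Condition-level statistics: Pearson chi-square without continuity
correction on the responders × conditions table (df = (R−1)(C−1));
Kruskal–Wallis with tie correction on per-cell maxima; Dunn's post-hoc
z-tests on pooled ranks with Holm adjustment. Holm was chosen because
the classical Dunn procedure names no particular adjustment; it is
uniformly valid and adjustable via `p_adjust`.

## Image processing and segmentation

All segmentation operates on percentile-clipped, [0, 1]-normalized
channels. The stages and their parameters:

- **Rigid registration** (`register_rigid()`): per frame (time lapse,
  estimated on the maximum projection) or per z-slice (slice-to-slice),
  with "previous" as the default reference and transforms accumulated.
  Estimation is coarse translation by phase correlation (with 3-point
  parabolic sub-pixel refinement), then joint (rotation, shift)
  Nelder–Mead refinement of the mean squared difference; a ±10° coarse
  rotation grid avoids local minima of rotationally near-symmetric
  rosettes. Bilinear interpolation; out-of-field pixels are zero-filled
  and carried in a validity mask. Displacements above half the field (or
  `max_shift_px`) are flagged with a warning.
- **Rolling-ball background subtraction** (`rolling_ball_subtract()`):
  grey-scale opening with a disc of radius 10 px (the classic macro's
  "pixel size"), slice-wise in 3-D, with replicate padding so borders see
  no artificial zero frame. Anti-extensive by construction; negative
  residuals are clipped to 0 because all downstream operators assume
  non-negative input.
- **Neuromast mask** (`segment_neuromast()`): Gaussian blur σ = 6 px
  (kept isotropic in physical units when the voxel size is supplied,
  since z spacing is typically 5–20× the lateral pitch), triangle
  threshold, slice-wise hole filling, small-artifact removal, largest
  connected component. Two degenerate-input guards reject structureless
  stacks: a foreground fraction above 50% (a neuromast is compact) or a
  foreground/background contrast below 10% of the input range (smoothed
  noise).
- **Hair cells** (`segment_hair_cells()`): the multi-Otsu background
  (5 classes; the number of *lowest* classes regarded as background is a
  parameter, default 1, because which classes are "background" depends on
  how broad the dark mode is) is replaced with 1e-7; Sauvola local
  thresholding (window 45 px, k = 0.2, dynamic-range parameter R = half
  the data range of the normalized image, applied slice-wise for
  consistency with the slice-wise vesicle detectors); hole filling and
  artifact removal; then seeded watershed on the negated Euclidean
  distance transform, one label per seed. Seeds are inputs (a CSV of one
  point per cell); seeds outside the foreground are flagged and skipped,
  coordinate-duplicate seeds are an error. Manual corrections replay
  from an edits file (merge/delete), keeping the interactive step
  scriptable.
- **Vesicles** (`segment_vesicles()`): union of a multi-scale
  Laplacian-of-Gaussian spot detector (σ = √(scale/2), scale-normalized,
  so an amplitude-A Gaussian spot at the matched scale responds A/2 at
  its centre — which makes the shipped cutoffs interpretable) and a
  Hessian bright-ridge (vesselness) detector (σ = scale, eigenvalue-ratio
  damped so an isotropic blob scores e⁻² of an equal ridge), slice by
  slice, thresholded per (scale, cutoff) pair. The shipped YAML presets
  carry the working parameter pairs for the endolysosomal-reporter and
  labeled-G418 channels; the cutoffs are preset defaults, not re-derived.
  Fused masks are hole-filled, cleaned (components < 4 voxels — the
  artifact-size bound is otherwise unspecified and exposed as
  `min_object_voxels`), and labelled by 26-connected components in 3-D;
  touching vesicles may share a label (no splitting). Labels with no
  voxel inside the neuromast are discarded; partially overlapping labels
  are kept and clipped by default (`outside = "strict"` drops them),
  which keeps the mask algebra exact.
- **Cytoplasm** (`make_cytoplasm_mask()`): the set difference
  neuromast − vesicles. The partition invariant (disjoint, union equals
  the neuromast) is asserted voxelwise on every call.

Determinism: no stage uses randomness; watershed ties break
first-in-first-out at equal priority, so identical input and parameters
reproduce identical label volumes.

The accumulation statistic (`compartment_ratio()`) is the **mean** drug
intensity in the vesicle mask over the mean in the cytoplasm mask — a
concentration-style contrast insensitive to compartment volume; the
total/total variant is available by flag. The cytoplasm denominator is
always neuromast − vesicles of the same mask that defines the vesicle
compartment. Replicate experiments are carried as a grouping column; no
mixed model is fitted.

## The synthetic-data generator

`gen_neuromast_stack()` builds a rosette of 8–14 (default 10) hair cells
as axis-aligned superellipsoids (quadratic laterally, quartic along z:
columnar cells with blunt ends rather than pointed ellipsoid tips) on a
ring, with a 0.25-µm unlabeled gap between neighbours — the dark
membrane boundary a cytoplasmic reporter shows, and the feature the
watershed needs. The ground-truth neuromast is the solid rosette (cells
plus gaps and interstitial core). Vesicles are ellipsoids of radius
0.4–0.8 µm, negative-binomially distributed per cell, placed with a
minimum separation inside the owning cell. Two intensity-allocation
modes for the drug channel:

- default: the cytoplasm receives `diffuse_fraction / (1 −
  diffuse_fraction)` of each cell's realized vesicle signal, so
  `diffuse_fraction = 0` is exactly punctate (G418-like) and 0.5–0.7
  mimics the mixed neomycin-like distribution;
- fixed budget (`ag_total_per_cell`): vesicles keep a fixed per-voxel
  amplitude and the cytoplasm absorbs the remainder — the
  lysosome-disruption (GPN-like) regime, where halving the vesicle count
  leaves per-vesicle volume and brightness and the per-cell total signal
  unchanged.

Noise is Poisson shot noise (400 photons per intensity unit) plus
additive Gaussian read noise, with `snr` = (mean in-structure reporter
signal − background)/read-SD; `Inf` disables noise. Defaults: 1-µm z
sections (the acquisition description's z interval), 0.2-µm lateral
pitch matched to the vesicle detector scales. The neuromast/cell mask
experiments instead use 0.05-µm lateral pitch (448² slices), the
super-resolution regime in which a σ = 6 px blur is strong smoothing but
small relative to a ~400-px rosette; at coarser pitch the triangle
threshold's corner sits a fixed ~2.3σ halo outside any object, which is
a property of the method, not of the phantom.

`gen_timelapse()` displaces the clean phantom by a known per-frame
rigid drift (bilinear warp, fresh noise per frame) and errors when the
cumulative drift would carry the object past half the field.
`gen_calcium_traces()` draws responder peaks from
Normal(`peak_mean`, `peak_sd`) floored at baseline + 6 noise-SD (so the
2-SD rule is met even after baseline-estimation noise), shapes them as a
Gaussian bump peaking 3 frames before fragmentation, truncates dying
traces at their fragmentation frame, and clamps non-responder dying
traces below their realized 2-SD threshold — making generated labels
agree with the rule by construction, on noiseless and noisy traces
alike. `gen_doseresponse_counts()` gives each fish a Poisson capacity
around the control mean and a beta-distributed survival probability
around the Hill value with intra-class correlation `dispersion`
(default 0.06), producing the fish-to-fish overdispersion real count
data show.

What the phantoms do **not** emulate: optics (no PSF convolution —
structures are sharp-edged), hair-bundle and kinocilium morphology,
regeneration after washout, photobleaching, and morphological
fragmentation (fragmentation is a trace index, not an image event).
Passing the ground-truth suites therefore demonstrates that the
algorithms recover what they are specified to recover under a clean,
controlled forward model — not that they are robust to every artifact of
real microscopy.

## Numerical choices and degenerate inputs

- Thresholds (triangle, multi-Otsu) operate on 256- and 128-bin
  histograms; multi-Otsu maximizes between-class variance exactly by
  dynamic programming. Between well-separated modes the criterion has a
  flat plateau; the implementation returns the left edge (the convention
  of the reference scientific-Python implementation, against which the
  package's tests cross-check). Constant images are errors for all
  thresholds and for normalization.
- Sauvola uses edge-clamped integral-image windows; the window must be
  odd and ≥ 3.
- The Euclidean distance transform is exact (per-axis lower-envelope
  algorithm) and anisotropy-aware via the physical voxel size.
- 32-bit TIFF storage quantizes intensities to ~2⁻³² of the data range;
  the range travels in the metadata sidecar and round-trips are exact to
  that step.
- Empty inputs follow a consistent rule: empty *results* (no vesicles in
  a field) are empty tables; empty *prerequisites* (no seeds, no
  controls, empty compartments) are warnings or errors naming the
  missing piece.

## Problem sizes used by the test-suite

Ground-truth suites run at the sizes a laptop CPU handles in seconds:
one 14×448×448 phantom for the mask criteria, 14×110×110 phantoms for
vesicle work, 100 phantom pairs (12×96×96) for the accumulation-ratio
direction check, 50 replicates per HC50 recovery (10 fish/dose, 8
doses), and 200×16 traces for calcium peak recovery. These sizes are the
package's validation design; all are parameters, and nothing in the
implementation depends on them.

## Known limitations

- Vesicle labels are connected components: adjacent vesicles merge, and
  no splitting is attempted; counts on dense fields are conservative.
- The rigid model is 2-D (per-frame/per-slice); axial drift is not
  corrected.
- The Hill fit fixes asymptotes at 100/0 by default; strongly
  regenerating or partially resistant populations need the
  free-asymptote flag and more dose levels.
- Dunn's z-tests use the normal approximation; for very small groups an
  exact permutation approach would be preferable.
- The responder rule tests one threshold per cell over many frames; its
  family-wise behaviour over long traces is the field's convention, not
  a calibrated test.
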