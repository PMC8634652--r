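---
title: "Targeted re-imaging of serial sections: methods and design"
author: "simtarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted re-imaging of serial sections: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Array tomography images serially cut ultrathin (here 90 nm) resin sections
by fluorescence microscopy; the axial resolution equals the section
thickness, so a stack of aligned sections is a 3-D volume with ~90 nm
z-resolution but survey-limited lateral resolution. Synapses between a
labeled presynaptic axon population and labeled postsynaptic dendrites can
only exist where the two structures physically appose. `simtarget`
exploits this: it detects apposition candidates on cheap survey images,
shortlists them by biological continuity, and emits a minimal acquisition
plan for super-resolution (SIM) re-imaging of only those coordinates.
The package does not drive hardware or reconstruct SIM images; its product
is the plan (CSV/JSON in global slide coordinates) plus the quantification
of the confirmed results.

## Pipeline stages and their assumptions

**Brightness normalization.** Survey tiles differ in illumination;
per-plane linear rescaling to a target mean μ and standard deviation σ
(`Img/sd(Img)·σ − mean(Img/sd(Img)·σ) + μ`) cancels tile- and
section-level brightness variance. The map is affine, hence rank-
preserving and idempotent. The sample (n − 1) standard deviation is used;
the convention only rescales by a factor common to the whole plane, so no
downstream decision depends on it. Defaults μ = 100, σ = 20 (arbitrary
intensity units).

**Background flattening.** The local brightness tendency, estimated by a
Gaussian blur of scale `background_sigma` (default 50 px — several times
larger than any neurite cross-section at 0.31 µm/px, small enough to track
illumination gradients), is subtracted. The blur uses reflective padding:
circular (FFT) boundaries would wrap intensity across opposite edges and
bias the border rows. Negative values are retained; the thresholder bins
over the min–max range, so clipping would only distort the histogram.

**Rényi-entropy binarization.** The threshold maximizes
`H_α(background|t) + H_α(foreground|t)` with
`H_α(p) = log(Σ pᵢ^α)/(1 − α)` over class-normalized histograms (256 bins
over the plane's min–max range; empty bins drop out of the sums, which
also keeps α < 1 well-defined). A single order α is used, default α = 2,
exposed in the configuration; as α → 1 the criterion converges to the
Shannon/Kapur maximum-entropy threshold, and the test suite verifies ±1-bin
agreement at α = 1.001. Ties break toward the lower threshold.

*Background-only guard.* Entropy criteria presume a signal tail. Applied
to a plane containing only noise, every order α splits the noise
distribution itself near mid-range (~30% spurious foreground — we measured
this across α = 0.5…8). A plane is therefore declared background-only
(empty mask) when its threshold fails to exceed the plane median by at
least `noise_guard_k` robust (MAD-based) standard deviations. On phantom
data the separation statistic is ~0.5 for structure-free planes and
3.4–5.3 for planes with neurites, so the default k = 2 sits between the
two regimes with margin on both sides; `noise_guard_k = 0` disables the
guard.

**Dilation.** Each positive pixel grows to a 3×3 block (one pixel of
radius; 9 pixels total). This absorbs the survey magnification's
localization error so genuine contacts separated by a sub-pixel gap in the
masks are still detected; it deliberately also admits near-miss bypasses,
which are adjudicated later at SIM resolution. Detection runs on dilated
masks; area quantification runs on undilated masks (dilation exists only
to protect recall, and would inflate areas by a perimeter term).

**Overlap detection and scheduling.** Candidates are 8-connected
components of axon ∧ dendrite ∧ target-area. Field-of-view boxes are
centered on component centroids, clamped (never shrunk) at image borders.
Merging seeks a minimal-overlap cover of all overlap pixels by FOV-sized
boxes: rectangle cover is NP-hard in general, so instances of ≤ 12 pixels
are solved optimally by deterministic iterative-deepening search over
pixel-anchored candidate positions, and larger instances use a greedy
max-new-coverage rule with topmost-then-leftmost tie-breaking. (Pure
greedy was our first design, but it pairs pixels short-sightedly and can
exceed the optimum by two boxes even on ten-pixel instances; the hybrid
keeps small instances exactly minimal.) Candidate positions may always be
anchored with a box edge on a covered pixel — sliding a box until its
left/top edge reaches a pixel of its covered set never loses coverage —
so the finite search loses no optima. Cover completeness is asserted on
every run.

**Interior rejection.** An overlap component lying strictly deeper than
`interior_margin` px (default 5) from the background of *both* masks sits
in the middle of a large double-labeled structure (e.g. overlapping somata)
rather than at an apposition, and is excluded. Distances come from the
Euclidean distance transform of each dilated mask.

**Continuity shortlisting.** Neuronal processes are continuous, so the
structures forming a real contact reappear at the same global coordinate
on neighboring sections, while one-section staining speckle does not. A
candidate is kept when axon foreground reappears within `match_radius` px
(default 3 = dilation radius + 2) in at least one neighbor (± 1 section by
default, ± 2 optional) *and* dendrite foreground reappears in at least one
neighbor. The two channels may reappear in different neighbors: at a
contact whose apposition plane is parallel to the cutting plane — the
common case for two mostly in-plane tubes crossing — the dendrite
continues below the contact section and the axon above, so no single
neighbor contains both. Demanding both channels in the same neighbor
(`require_same_neighbor = TRUE`) is available but rejects exactly that
geometry.

**Series binding and global coordinates.** Each shortlisted coordinate is
bound to the same global position on 1–2 preceding and following sections
(3–5 serial images, truncated at stack ends but extended on the open side
to keep at least three), mapped through each section's invertible affine
alignment transform; the acquisition plan lists one row per series entry.
Coordinates are pixel-centered, 0-based, with half-open boxes
`[x0, x1) × [y0, y1)`; global coordinates are micrometres on the slide.

**Quantification.** Areas are foreground pixel counts × pixel area,
summed per section within each target area (a z-projected variant is
available; per-section summation is the default because each 90 nm section
is an independent physical sample of the volume). Densities are counts per
100 µm² of dendrite (the headline denominator), axon, and intersection
area; fold ratios compare areas against a reference layer. Zero
denominators yield `NA`, never infinities. Rounding (count folds truncated
to integers, area folds to one decimal, percent saved to the nearest
integer) happens only in the presentation layer. The imaging plan is exact
arithmetic: `ceil(w/fov)·ceil(h/fov)` tiles per section × sections ×
minutes per tile. FWHM interpolates the half-height crossings linearly
with the baseline at the profile minimum.

## The phantom: what it emulates, and what it does not

The generator renders a configurable tissue block (default
57.66 × 57.66 × 3.15 µm at 0.31 µm/px — 186 × 186 px, 35 sections of
90 nm) containing:

* capsule-tube dendrites and axons (radius 0.25–0.45 µm, length 8–14 µm,
  mostly in-plane directions so processes persist across sections);
* 25 true synapses: crossing axon–dendrite pairs whose surfaces touch
  (gap 0), each carrying a synaptic-marker punctum rendered as a 3-D
  Gaussian of 0.3 µm FWHM;
* 25 near-misses: tube pairs running in parallel with a 0.1–0.3 µm
  surface gap, mostly lateral, and no punctum. Lateral gaps below the
  survey resolution are exactly the false positives the survey stage is
  expected to record and the SIM stage to adjudicate; axial gaps are
  already resolved by the 90 nm sectioning itself, which is why bypasses
  are rendered side-by-side rather than stacked;
* 10 + 10 unpaired distractor neurites;
* per-tile multiplicative brightness factors (3 × 3 grid, CV 0.1), a
  planar background gradient (amplitude 20 on a background of 100),
  Poisson shot noise and Gaussian read noise (SD 4).

Tube intensity uses a flat-topped cross-section with a Gaussian shoulder
(0.08 µm edge softness): the fluorescent label is cytosolic, so a neurite
is a filled volume, not a Gaussian filament. Each section's image is the
profile averaged over the physical slab (5 z-samples), not a mid-plane
sample — this matters, because the slab containing a contact genuinely
contains both apposed structures, which is what makes axial contacts
detectable in single sections. All randomness flows from one seeded
generator: identical seed and configuration reproduce the stack bit for
bit.

Not emulated: optical PSF beyond the edge-softness term, SIM
reconstruction artifacts, immunostaining chemistry, section wrinkles or
folds, curved neurites, and dense neuropil packing. Passing the phantom
suite therefore demonstrates the pipeline's geometric and statistical
correctness under controlled conditions, not segmentation performance on
real tissue; the binarization quality on real data depends on staining
contrast that the phantom idealizes.

The survey pixel size (0.31 µm/px at 20x) is a documented assumption of
the phantom, not a measured instrument property.

## Problem sizes in the test and acceptance runs

The unit suites use a small phantom (25 × 25 × 0.9 µm, 4 + 2 pairs) for
speed; the end-to-end suite and `scripts/acceptance.R` use the full
default phantom above (35 sections, 25 + 25 pairs). Oracle-equivalence
suites run 1,000 random histograms (≤ 256 bins) against an exhaustive
entropy-sum search, 150 random ≤ 10-pixel cover instances against an
exhaustive branch-and-bound optimum, and the blur against a direct
convolution oracle on small images. The acceptance bar for the phantom is
≥ 90% shortlist recall of true synapses and 100% removal of injected
one-section speckle.

## Degenerate inputs and numerical choices

* Constant planes (zero variance) are rejected explicitly by
  `normalize_plane` and `binarize_channel`, never silently divided.
* Histograms with fewer than two occupied bins are degenerate inputs to
  `renyi_threshold`.
* `ceil` on physical ratios uses a 1e-9 guard so 3.15/0.09 gives exactly
  35 sections despite floating-point representation.
* Affine transforms are validated (|det| > 1e-12); round-trip error is
  bounded at 1e-6 px in tests.
* Single-section stacks cannot establish continuity: every candidate is
  removed, with a warning rather than an error.
* Components larger than one field of view are legal; the cover is
  computed from overlap pixels, not from per-component boxes.

## Known limitations

* The continuity filter needs ≥ 2 sections and assumes alignment
  transforms are accurate to ~`match_radius` pixels; gross misalignment
  silently reduces recall.
* The background-only guard assumes foreground occupies a minority of the
  plane; a plane more than ~half covered by signal could in principle be
  mis-declared background-only (not observed on phantoms).
* Greedy covers for large overlap sets are near-minimal, not minimal.
* Interior rejection is per-section 2-D; a structure deep in 3-D but thin
  in one section is not flagged.
* Synapse confirmation is outside the package: `run_quant` consumes a
  confirmation table standing in for visual verification of the SIM
  series.
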