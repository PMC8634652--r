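# simtarget

Targeted super-resolution re-imaging of serial-section fluorescence stacks.

## The problem

Mapping which axons synapse onto which dendrites requires super-resolution
imaging, but synapses are sparse: re-imaging an entire tissue block with
structured illumination microscopy (SIM) is prohibitively slow (a 1.3 ×
1.45 mm² area over 35 ultrathin sections is ~61,600 tiles at ~3 min each,
i.e. 3,080 h). Since a synapse cannot exist without physical apposition of
its axon and dendrite, a fast low-magnification survey of the same sections
can shortlist the handful of locations worth re-imaging.

`simtarget` implements that computational shortlist for array-tomography
style data — serial 90 nm sections, each imaged in three channels (dendrite,
axon, synaptic marker) at survey magnification:

1. **Preprocess** — per-plane brightness normalization
   `Img/sd(Img)·σ − mean(Img/sd(Img)·σ) + μ`, then background flattening by
   subtracting a large-σ Gaussian blur (reflective padding).
2. **Segment** — per-channel binarization at the histogram cut *t*
   maximizing the summed Rényi entropies of the two classes,
   `H_α(bg|t) + H_α(fg|t)` with `H_α(p) = log(Σ pᵢ^α)/(1−α)` (default
   α = 2), followed by 3×3 dilation (one positive pixel becomes 9) to absorb
   survey-scale localization error.
3. **ROI scheduling** — 8-connected components of axon ∧ dendrite inside
   polygonal target areas (e.g. cortical layers L4/L5); SIM-sized
   field-of-view boxes merged into a minimal-overlap cover; rejection of
   overlaps buried deep inside large double-labeled structures; a
   cross-section continuity filter (real neurites reappear on neighboring
   sections, staining speckle does not); series binding (each shortlisted
   coordinate ± 1–2 neighboring sections, 3–5 images); export in global
   slide coordinates through per-section affine alignment transforms.
4. **Quantify** — per-layer structure areas, synapse counts and densities,
   fold ratios, imaging-time plans, bead-profile FWHM, and line profiles.
5. **Phantom** — a synthetic serial-section generator (capsule-tube
   neurites, true contacts with synaptic puncta, near-miss bypasses,
   per-tile brightness variation, background gradients, shot + read noise)
   with full ground truth, so every stage is testable without real data.

## Worked example

```r
library(simtarget)

# imaging-time arithmetic for the survey-vs-targeted comparison
imaging_plan(width_um = 1300, height_um = 1450, fov_um = 33,
             n_sections = 35, minutes_per_tile = 3, targeted_tiles = 3268)
#> imaging_plan: 40 x 44 tiles/section x 35 sections @ 3 min
#>   full grid: 61600 tiles, 3080.0 h
#>   targeted : 3268 tiles, 163.4 h (95% saved)
```

61,600 survey-grid tiles would take 3,080 h of SIM time; imaging only the
3,268 shortlisted tiles takes 163.4 h — a 95% reduction.

```r
# per-layer quantification from measured areas and confirmed counts
areas <- data.frame(area = c("L4", "L5"),
                    dendrite_area_um2 = c(7777.5, 83857),
                    axon_area_um2 = c(2497.6, 13813),
                    intersection_area_um2 = c(279, 4830))
density_and_folds(areas, c(L4 = 17, L5 = 447), reference = "L4")
#> quant_report (reference area: L4 )
#>  area dendrite_um2 axon_um2 intersection_um2 count density_dendrite fold_count
#>    L4       7777.5   2497.6            279.0    17            0.219          1
#>    L5      83857.0  13813.0           4830.0   447            0.533         26
#>  fold_dendrite fold_axon fold_intersection
#>            1.0       1.0               1.0
#>           10.8       5.5              17.3
```

Synapses are 26× more frequent in L5 than L4, while dendrite, axon and
intersection areas are only 10.8×, 5.5× and 17.3× greater — structural
apposition alone does not explain the synapse distribution.

```r
# end-to-end on a synthetic phantom with known ground truth
ph  <- generate_phantom(phantom_config(seed = 42))
ph$stack
#> section_stack: 35 sections of 186 x 186 px, channels dendrite/axon/marker
#>   0.31 um/px lateral, 90 nm sections
res <- run_detect(ph$stack, run_config())
res
#> roi_result: 865 detected, 0 interior-rejected, 32 continuity-rejected, 833 shortlisted
phantom_recall(res, ph$truth, ph$stack)$n_found
#> [1] 25   # all 25 true synapses have a shortlisted ROI
```

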