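# woundkit

Automated quantification of wound (scratch) assay time-lapses from
label-free microscopy.

## What problem this solves

In a scratch assay, a confluent cell monolayer is wounded and the cell-free
gap is imaged every few minutes for hours; the closure rate measures
collective cell motility and is a standard readout in drug testing and
cancer-cell biology. Transmitted-light images segment poorly with plain
intensity thresholds, so the assay is usually scored semi-quantitatively.
`woundkit` is for labs that collect multi-position, frequent-sampling
time-lapses (one folder of frames per stage position) and want per-position
edge velocities, with uncertainty, out of the box.

The pipeline:

1. **Enhancement** — each frame passes a five-stage filter chain: intensity
   powering, difference-of-Gaussians flat-field correction
   (σ₁ = 2, σ₂ = 1 px), a local Shannon-entropy texture filter, white
   top-hat background subtraction, and mean smoothing. The result looks
   like a fluorescence image: textured cells bright, smooth gap dark.
2. **Segmentation** — threshold at `mean(image) / T`, where `T` is the one
   main tunable (3.14 for 16-bit cameras, 2.2 for 8-bit; lower for
   low-contrast cell lines); morphological smoothing; a central-cleft check
   with automatic threshold recalculation; selection of the biggest central
   blob; hole filling. A closed wound yields an all-zero mask, not an
   error.
3. **Kinetics** — per-frame gap areas become the absolute area displacement
   DT(t) = |A(0) − A(t)|, smoothed by a trailing 6-frame (1 h) moving
   average, converted to per-edge displacement d(t) = DT/(2L) using the
   wound length L, and fitted by least squares over the 5–11 h window where
   closure is linear across cell lines (r² > 0.985). The slope is the edge
   velocity in µm/h.
4. **Comparison** — treated/control velocity ratios in percent with
   standard two-sample tests and dose–response tables.
5. **Synthetic benchmark** — a seeded generator of ground-truthed label-free
   time-lapses (textured monolayer, jagged advancing edges, uneven
   illumination, sensor noise, pioneer cells, debris) so the entire
   pipeline is testable without real data.

## Worked example

```r
library(woundkit)

# a small synthetic library: 3 positions, 73 frames each, 10-min sampling
bm  <- write_benchmark("lib", preset = "linear-easy", n_positions = 3, seed = 1)

# segment every frame (masks land in lib_masks/), then fit velocities
seg <- segment_library("lib", params = benchmark_filter_params())
res <- analyze_library(seg, window = c(5, 11))
for (est in res$estimates) print(est)

# how well did segmentation do against the generator's ground truth?
val <- validate_library("lib_masks", "lib_gt")
str(attr(val, "summary"))
```

Output:

```
<velocity_estimate> pos01: v = 14.650 um/h (r2 = 0.9990, SEM = 0.077, 95% CI [14.492, 14.807], n = 36, window 5.0-11.0 h)
<velocity_estimate> pos02: v = 14.589 um/h (r2 = 0.9988, SEM = 0.087, 95% CI [14.413, 14.766], n = 36, window 5.0-11.0 h)
<velocity_estimate> pos03: v = 14.553 um/h (r2 = 0.9999, SEM = 0.029, 95% CI [14.493, 14.612], n = 36, window 5.0-11.0 h)
List of 2
 $ mean_area_error_pct: num 2.06
 $ detection_rate     : num 1
```

The three positions were simulated with a programmed edge speed of
15 µm/h; the fitted velocities recover it to within a few percent, with
r² ≈ 1 over the 5–11 h window, and the masks deviate from ground truth by
about 2% of the gap area. A treated-vs-control comparison is one call:

```r
compare_conditions(c(12.1, 11.4, 12.8), c(14.2, 14.9, 13.8))
#> <treatment_effect> treated vs control: ratio 84.62% (p = 0.01305, significant)
```

A thin command-line wrapper covers the same flow
(`exec/woundkit segment|analyze|simulate|validate`).

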