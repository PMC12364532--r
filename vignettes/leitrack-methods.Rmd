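---
title: "Measuring rosette leaf elevation from dual-view time-lapse images"
author: "leitrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rosette leaf elevation from dual-view time-lapse images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leitrack)
```

## The cylinder model and its assumptions

A rosette plant viewed as a whole can be idealized as a cylinder: the
rosette spans a circle of radius $r$ on the soil, and the leaves reach up
to a height $h$ above it. When leaves rise (hyponasty, as in the shade
avoidance response), $h$ grows and $r$ shrinks, so the elevation angle of
the cylinder,

$$\mathrm{LEI} = \tan^{-1}\!\left(\frac{h}{r}\right)\cdot\frac{180}{\pi},$$

increases. The index is a *whole-plant proxy* for leaf elevation status.
It is not the inclination of any single leaf, and it makes three
assumptions worth keeping in mind:

* the rosette silhouette from above is approximately elliptical, so the
  mean of the ellipse major and minor axes is a fair diameter
  ($r = (\text{major}+\text{minor})/4$);
* the highest point of the side silhouette belongs to the plant, not to
  soil, pot or reflections — which is why everything at or below the soil
  reference row is excluded by default;
* both cameras are fixed, so a single pixel-to-millimetre factor per
  camera (from a photographed length standard, `calibrate(px, mm)`)
  holds for the whole series.

Because $h$ and $r$ are measured by *different* cameras, the two
calibration factors are kept separate and applied before the ratio is
taken.

## From photograph to record

Each plant contributes one top-view and one side-view frame per time
point, named `<plantID>_<view>_<minutes>.png`. The processing chain per
complete pair is:

1. **Segmentation.** The excess-green index $\mathrm{ExG} = 2G - R - B$
   (channels in $[0,1]$, index range $[-2,2]$) is thresholded; the index
   is first clipped at `max_value` so isolated overexposed pixels cannot
   dominate. The surviving foreground is restricted to the configured
   region of interest, interior holes are filled, and 8-connected
   components smaller than `size` pixels are discarded. ExG was chosen as
   the default because it is the standard green-vegetation index for
   dark-background scenes; the index function is pluggable
   (`segmentPlant(indexFun = ...)`) for setups where another transform
   separates plant from background better. If several components survive
   the size filter they are all kept — in the side view a rosette
   legitimately fragments across leaves; `keepLargestOnly = TRUE` is
   available where stray objects are a bigger risk than fragmentation.
2. **Top-view geometry.** The mask's equal-moment ellipse is computed
   from the exact first and second central moments of the foreground
   pixel coordinates: with $\lambda_1 \ge \lambda_2$ the eigenvalues of
   the coordinate covariance matrix, the full axes are $4\sqrt{\lambda_1}$
   and $4\sqrt{\lambda_2}$. This fit is deterministic, needs no contour
   extraction, and reproduces a disc's diameter exactly in the continuum
   limit. It is a deliberate, documented stand-in for contour-based shape
   fits used by general phenotyping toolkits; on convex rosette-like
   silhouettes the two agree closely, which the test suite verifies on
   analytic shapes.
3. **Side-view geometry.** Height is the row distance between the
   highest foreground pixel and the soil reference row (`line_position`),
   with rows counted downward from the image top. The highest-pixel rule
   (rather than a bounding-box property) was chosen because a single
   raised leaf should count; it is monotone — adding foreground above the
   current top can only increase height.
4. **Record.** Axes and height are converted to mm with the per-view
   factors, $r$ and $h$ are formed, and the LEI is computed. A failure on
   one pair (empty segmentation, unreadable file, degenerate geometry)
   becomes a logged skip; nothing aborts a batch.

### Parameters that matter

| parameter | unit | default | notes |
|---|---|---|---|
| `threshold` | ExG units | 0.5 | tuned once per series on an exemplary frame |
| `max_value` | ExG units | 2 | clipping ceiling; must exceed `threshold` |
| `size` | px | 50 | minimum component area; rejects specks and noise |
| `roi` | px | whole frame | `c(row0, col0, height, width)`, 1-based |
| `line_position` | row | — | soil reference row of the side camera |
| `mm_per_px_top`, `mm_per_px_side` | mm/px | — | from the length standard |
| `interval_min` | min | 30 | capture cadence; timestamps within ±10% of the interval snap onto the grid, others are flagged |
| `onset_min` | min | 0 | treatment onset; the ΔLEI reference point |

## Aggregation and normalization

At each time point the group mean LEI and its standard error (sample sd
with $n-1$ denominator over $\sqrt n$) are computed over the plants
present at that time point; dropped frames simply reduce $n$ there, and
$n$ is reported per time point. The *group mean* trajectory is then
shifted so its value at `onset_min` is exactly zero — the reported
quantity is the change in leaf elevation since treatment begin. The
onset reference is the single onset-time frame, not an average of
pre-onset frames. Normalizing the group mean (rather than each plant) is
the default; `normalize = "plant"` shifts each plant by its own onset
value first, which is useful when baseline elevation differs strongly
between plants. A time point carried by a single plant reports SEM 0 and
is flagged rather than rejected. Normalization is shift-invariant and
idempotent by construction.

## The synthetic scene generator

`renderScene()` draws the very object the model assumes: a plant of leaf
length $L$ at elevation angle $\theta$ appears from above as a filled
ellipse with semi-major axis $L\cos\theta$ (minor axis scaled by the
eccentricity $e$), and from the side as an isoceles triangle whose apex
sits $L\sin\theta$ above the soil row with half-base $L\cos\theta$. The
ground truth is always pushed through the same formulas the pipeline
uses — $r = L\cos\theta\,(1+e)/2$, $h = L\sin\theta$,
$\mathrm{LEI} = \tan^{-1}(h/r)$ — so for eccentric rosettes the true LEI
differs from $\theta$ and stays internally consistent. The triangle was
chosen over a rectangle so height extraction faces a non-trivial shape;
since only the apex matters for height, the choice cannot bias the LEI.

Edges are hard (no anti-aliasing) so silhouette pixel counts are exact
oracles for segmentation; Gaussian per-channel noise (sd up to 0.2 on the
$[0,1]$ scale) emulates sensor noise. What the generator does *not*
emulate: leaf-level 3D structure, petiole gaps and overlaps, specular
highlights, illumination drift, moving shadows. Passing the synthetic
round trip therefore demonstrates the correctness of the measurement
chain, not robustness to every real-world artefact — on real images the
segmentation parameters still have to be tuned per series.

`simulateTimecourse()` draws per-plant LEI trajectories

$$\mathrm{LEI}_i(t) = \text{baseline} + b_i +
A\,\sigma\!\big(k(t - t_{50})\big)\,D(t) +
\text{osc}\cdot\sin(2\pi t/\text{period}) + \varepsilon_{it},$$

with $\sigma$ the logistic function, $D(t)$ an optional exponential decay
for transient responses, $b_i$ a between-plant offset and
$\varepsilon$ frame noise, clipped to $[0, 89]$ degrees. One seed governs
every random draw of a dataset, so regeneration is bit-identical at the
truth-table level.

### Genotype presets

Four presets ship as fixtures reproducing the qualitative contrast
between wild type and shade-avoidance mutants under high/low R:FR; the
numbers are the package's own choices (a 22° baseline, a 24-h
oscillation of 1.5°, between-plant sd 2°, frame sd 0.75°), **not**
measured values:

| preset | A (°) | $t_{50}$ (min) | k (1/min) | decay | shape |
|---|---|---|---|---|---|
| `wt_low` | 25 | 300 | 0.015 | off | large rise saturating ~10 h |
| `wt_high` | 0 | — | — | off | oscillation only |
| `pif4pif5_low` | 12 | 480 | 0.008 | off | smaller, slower, max ~15 h |
| `pif7_low` | 15 | 300 | 0.015 | from 600 min, τ = 240 min | transient, back to baseline after ~20 h |

## Numerical conventions and degenerate inputs

* Row 1 is the top image row; rows increase downward; pixel centers sit
  at integer coordinates. Regions of interest are 1-based with inclusive
  origin.
* Moments are central and normalized by the pixel count, hence exactly
  translation invariant; the eigen-decomposition runs on a symmetric
  2×2 matrix, so axes are rotation invariant up to rasterization error.
* 8-connectivity for components and hole filling, matching common
  phenotyping practice.
* Ellipse orientation is reported in $(-\pi/2, \pi/2]$ against the
  column axis (counter-clockwise, row axis up); for near-circular masks
  it is numerically arbitrary, as for any axial quantity.
* A collinear mask yields minor axis 0 and a `degenerate` flag; the
  record is still produced if the major axis is positive, because
  $r > 0$ then still holds. Both axes zero aborts only that record.
* A mask entirely at/below the soil line gives height 0 with a flag; an
  empty mask is an error at the geometry level and a logged skip at the
  batch level.
* The onset ΔLEI is set to exactly 0 after the subtraction, immune to
  floating-point cancellation.

## Validation problem sizes

The shipped tests and the acceptance script validate: moments against
brute-force double-loop summation on 50 random masks up to 200×200
(agreement to $10^{-9}$); ellipse recovery on rasterized discs and
rotated 2:1 ellipses 30–220 px across (axes within 1.5%, orientation
within 1°); end-to-end LEI recovery on rendered scenes at
$\theta \in \{10,\dots,80\}°$ and $e \in \{0.8, 1.0\}$ (within 2° at zero
noise, 5° at channel noise sd 0.05); and the full simulate-then-analyze
round trip at the default study scale of 3 plants over 36 h at 30-min
intervals (438 images per preset), where the `pif7_low` group returns to
within 2° of baseline by series end while `wt_low` does not. These sizes
were chosen to cover the geometry range a real rosette series spans while
keeping the suite quick to run.

## Known limitations

* The index saturates: at high elevation both $h$ errors and $r$ errors
  move the arctangent little, but $r$ itself becomes small, so pixel
  calibration errors matter most near the top of the range.
* Overlapping neighbour plants must be separated by the region of
  interest; the package does not segment instances.
* No significance testing between groups is performed; the output is
  descriptive (mean ± SEM per group).
* Circadian oscillation is part of the signal, not removed; experiments
  should compare treatments sharing a time base.
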