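---
title: "Methods: serial-section reconstruction and retrograde-label mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial-section reconstruction and retrograde-label mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sectionmap` reconstructs whole brains from serial coronal fluorescence
sections and maps retrogradely labeled neurons (e.g. from a g-deleted rabies
tracer injected into the granule cell layer of the olfactory bulb) onto
anatomical regions. This vignette describes the model behind each stage, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical choices made where the design was open.

## Image model and coordinates

A section is a 2D raster of intensity counts (8- or 16-bit) with physical
metadata: pixel size (µm/px), section thickness (100 µm by convention for
coronal sectioning) and a 0-based rostro-caudal index. Coordinates are
`(row, col)` with row 1 at the image top; the dorsal-ventral axis is the row
axis, medial-lateral the column axis, and rostro-caudal the section index,
so a cell's physical position is `(col, row) * pixel_size` and
`z = rc_index * thickness`. Virtual Z-planes within one section are
collapsed to a per-pixel maximum intensity projection before any analysis.

Large scans are handled through a mean pyramid: level 0 is the image, level
*l* the non-overlapping 2×2 block mean of level *l* − 1 (window M = N = 2,
stride 2). Odd dimensions are padded by edge replication, pyramid values are
kept at floating precision (quantization only on export), and pixel size
doubles per level.

## Maximum correlation thresholding (MCT)

For a gray value *i*, let `y(i)` be the binary mask with `y = 1` exactly
where the pixel exceeds *i* (strict inequality). The MCT curve is the
Pearson correlation between the original intensities and `y(i)`, computed
for every *i* in the gray range from the histogram in closed form:

$$
\mathrm{corr}(x, y(i)) \;=\;
\frac{\sum_{j > i} n_j (j - \bar x)}
     {\sqrt{\sum_j n_j (j - \bar x)^2}\;
      \sqrt{N_i (N_m - N_i) / N_m}}
$$

with `n_j` the count of pixels at gray value *j*, `x̄` the image mean,
`N_i` the number of pixels above *i* and `N_m` the pixel total. The curve is
undefined (flagged `NA`, never silently zero) where the mask would be
constant. The *optimal* threshold is the argmax of the curve; ties break
toward the lowest threshold, which favors inclusion and makes the selection
deterministic.

An image of dim tissue with a minority of bright somata produces a curve
with distinct transitions. Each intensity population (tissue
autofluorescence, labeled somata) creates an excursion in the curve's first
finite difference. Transitions are detected by smoothing the derivative
with a centered moving average (default window 5 gray levels), collecting
local extrema, and keeping the `n_transitions` (default 2) largest in
magnitude, suppressing extrema closer than `min_separation` (default 5) to
a stronger one. Each selected extremum marks a population; the *reported*
threshold for it is placed in the sparse histogram gap below the extremum —
specifically the middle of the first minimal-count run of gray levels
between the previous extremum (or the start of the defined range) and this
one. Thresholding at the lowest transition reproduces the tissue
silhouette; at the highest only labeled somata survive. The valley placement
was chosen over reporting the raw extremum location because the extremum
sits inside a population, where thresholding splits that population in half;
the histogram valley is the stable separating point and is insensitive to
the exact extremum position. Automated selection can be overridden per
section (`threshold_mode = "manual"`), mirroring manual threshold choice in
the original protocol.

The implementation assumes the off-tissue background is dark relative to
tissue (slide-scanner glass). A bright, broad background population would
contribute the largest derivative excursion and displace the two reported
transitions; for such data, request `n_transitions = 3` and use the upper
transitions, or supply manual thresholds.

## Segmentation

The raw image is median filtered (default 3×3, the smallest window that
removes isolated saturated shot-noise pixels) with edge replication; the
same filtered image feeds the correlation curve, the tissue silhouette and
cell detection. The 3×3 path uses a vectorized 19-exchange sorting network;
larger windows go through `EBImage::medianFilter` on a replicated-edge pad.
Note that a 3×3 median bridges gaps of one pixel between two bright blobs
whose edges flank the gap — somata closer than about the filter width plus
their diameter merge into one component, which is the mechanism behind
undercounting at dense injection sites.

Tissue boundaries are traced with the Moore-Neighbor algorithm (clockwise,
from the top-left-most foreground pixel, Jacob's stopping criterion); only
outer contours are traced, since the tissue silhouette is what alignment
uses. Contours are rasterized and convolved with an isotropic Gaussian
(default σ = 2 px, kernel truncated at 4σ) to make alignment insensitive to
pixel noise on the edge.

Cells are found by thresholding at the labeled-cell transition, restricting
to the region-of-interest masks, grouping contiguous foreground pixels
(8-connectivity by default; 4 available) and filtering groups by
morphology. Circularity is `4πA/P²` with the perimeter taken from the
traced contour (√2 for diagonal steps); the staircase length of a digital
disc closely matches the isoperimetric value, and the statistic is capped
at 1 so very small shapes (whose staircase undershoots) stay in range.
Defaults: area 60–600 µm² (converted to pixel counts via the pixel size)
and minimum circularity 0.4. These cutoffs are declared, not inferred: they
bracket a granule-cell soma at the package's default 4 µm/px desk scale and
reject both sub-somatic specks and unresolvable clumps. Dropping oversized
clumps is deliberate — no watershed splitting is attempted — so counts are
biased low exactly where somata overlap.

## Alignment

Sections are aligned by rigid integer translation only. Each section
receives the shift (within `search_radius`, default 50 px) maximizing the
Pearson correlation between its smoothed boundary raster and the previous
aligned section's; since translation leaves the rasters' variances
unchanged, the correlation argmax equals the argmax of circular
cross-covariance, searched exhaustively via FFT. Ties break toward the
smallest shift so identical stacks map to the identity. Alignment runs on
pyramid level 2 by default (shifts rescaled ×4) for tractability on
full-resolution scans; fixtures inject level-2-compatible shifts
(multiples of 4) so recovery is exact.

Edge-based alignment has a tolerance set by the boundary smoothing: if
adjacent silhouettes differ in radius by more than roughly the blur width,
ring overlap is maximized near tangency rather than concentricity and the
estimated shift is biased. Adjacent 100 µm coronal sections vary little, and
the validation report makes the tolerance explicit: boundaries are dilated
with discs of increasing radius ("edge thickness") and all pairwise
correlations reported; adjacent sections correlate strongly, correlation
falls with rostro-caudal lag, and thicker edges raise correlations at any
fixed lag.

## Quantification

Detected cells are mapped through their section transforms and scaled to
micrometers. Region label masks — integer images with a name table, standing
in for manual ROI drawing and atlas registration, which this package
deliberately does not perform — live in the aligned frame; each cell takes
the label under its centroid pixel (no area voting, so assignment is
deterministic). Reports: injection-site center of mass (arithmetic mean of
positions over the organ's cells) and fraction inside the target layer
(the layer being nested inside the organ, organ membership is the union of
the two labels); per-region counts and percentages over assigned cells,
with unassigned cells reported separately; normalized axis histograms;
2D density maps, optionally recentered on the injection-site center of
mass; and two-compartment shares (e.g. MOB vs AOB).

## Validation

Automated counts are compared per section against reference counts —
ground truth for synthetic data, standing in for the expert annotator of
the original protocol, a strictly cleaner reference than a human rater.
Reported: squared Pearson correlation, the least-squares line, per-section
signed errors, mean error per density decile, and the Spearman correlation
of error with density (negative when dense sections are undercounted).

## The synthetic generator

Sections are nested-ellipse phantoms: a tissue ellipse whose axes vary
smoothly along the rostro-caudal span (raised-sine profile), and labeled
region ellipses clipped to the tissue interior, including a non-spherical
granule-cell layer nested inside the bulb. Intensities: background 0
outside tissue by default (dark glass; a nonzero background models
scattered light and scales with the rostro-caudal decay), tissue
`N(60, 5)`, somata rendered as Gaussian blobs (amplitude `N(180, 15)`,
σ = 1.25 px) truncated at their stated radius (2.5 px) — truncation keeps
the histogram gap between tissue and soma populations that thresholding
relies on, the blur of the real point-spread function being represented by
the blob profile itself. All tissue and soma intensities decay as
`exp(-rate * rc_index)`. Shot noise saturates a random pixel fraction
(default 2 × 10⁻⁴). All randomness derives from one seed, split per
section, so stacks are bit-identical across runs.

Separated cells are placed on a randomly phased square lattice of pitch
`min_separation_px` (default 8 px) restricted to the region mask eroded by
4 px. The pitch guarantees rendered somata never touch after median
filtering (blob diameter ≈ 5 px plus one bridging pixel), so detection of
separated cells is essentially exact and recovery tests measure the
pipeline, not placement luck. Injection-site overlap is generated
explicitly: a configurable fraction of a region's cells is drawn from a
dense Gaussian cluster with no separation constraint, so blobs merge — the
mechanism that produces density-dependent undercounting. Per-region counts
are apportioned from proportions by largest remainder (exact, not a
multinomial draw), so a fixture's generating percentages are hit exactly
and recovery error reflects detection alone.

What the generator does not emulate: optical point-spread functions and
defocus, illumination flat-field errors, stitching seams, tissue tears and
deformations, dendritic processes, anisotropic soma shapes, and real
anatomical geometry. Passing recovery tests therefore demonstrates that the
algorithms read back what the generator encodes through the full image →
cells → regions path under realistic intensity statistics — not that the
pipeline is robust to every artifact of real microscopy; the
density-undercount behavior quantifies its known failure mode.

## Packaged fixtures

* `fig2_gradient` — 12 sections with a strong fluorescence decline; the
  selected optimal thresholds track the decay.
* `fig3_density_sweep` — 100 sections, 512×512 px, true counts geometrically
  spaced 10–2,000 per section, clustered-overlap fraction rising linearly
  from 0 to 0.7: the accuracy and undercount fixture.
* `fig4_example` — ~1,500 bulb cells, 84% placed inside the nested granule
  cell layer; `fig4_replicates()` provides nine variants whose generating
  proportions (0.43–0.99) have mean 0.80 and sd 0.18.
* `fig5_distribution` — 36 sections, 10 named regions with shares
  (ipsilateral AON 58%, contralateral AON 5%, piriform+nLOT 27.9%, HDB
  6.568%, amygdala 1.4%, zona incerta 0.001%, piriform-entorhinal
  transition 0.001%, hypothalamus 0.08%, entorhinal cortex 0.3%, CA1
  0.75%). The individually itemized small-region percentages do not total
  100 together with the three large shares; the un-itemized remainder is
  carried by the HDB entry, the largest coarsely reported non-olfactory
  share, so that the three summary properties hold simultaneously: combined
  AON 63%, and non-olfactory regions ≈ 9–10% of the total.
* `fig6_injection` — adjacent MOB and AOB granule-layer compartments with
  2,979 and 21 injection-site cells (99.3% MOB; the reference AOB share is
  recorded as 0.07%, which cannot complement 99.3 — the fixture uses the
  0.7% complement and the discrepancy is documented rather than silently
  corrected).
* `alignment_shifts` — 10 sections with known injected shifts (multiples of
  4 px) and 2% smooth shape variation, below the boundary-smoothing
  tolerance, so recovery is exact.

Fixtures run at 512×512 px and 4 µm/px — a deliberate desk scale; every
algorithm is resolution-agnostic and the original ~30,000×50,000 px scans
differ only in pyramid depth and runtime. Test problem sizes (100 sweep
sections, 5,000/20,000 distribution cells, nine replicates) are the
package's chosen balance of statistical resolution against suite runtime.

## Degenerate inputs and numerical conventions

Constant images are rejected as degenerate rather than returning a zero
correlation; per-section failures are flagged without aborting a stack.
Empty masks trace to empty boundary lists; blank sections inherit the
previous alignment transform and are flagged. The correlation closed form
is validated against a brute-force Pearson oracle to 10⁻⁹; block means use
exact arithmetic; all argmax/tie situations resolve toward the lowest
index. Counts use doubles where products can exceed 32-bit integer range.

## Known limitations

Rotation, scaling and nonrigid deformation are not corrected; atlas
registration is out of scope (label masks are the interface); touching
somata are never split, so dense regions are undercounted by design;
multi-channel imaging and 3D (across-section) cell merging are not
supported.
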