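# sectionmap

Reconstructing a whole mouse brain from serial coronal fluorescence sections
and mapping retrogradely labeled neurons onto anatomical regions is the
workhorse analysis behind tracing studies: a retrograde tracer (for example
a glycoprotein-deleted rabies virus) is injected into a target structure
such as the granule cell layer (GCL) of the main olfactory bulb, every
~100 µm coronal section is scanned, and the labeled somata found across the
brain are counted per region to describe the feedback projections to the
injection site. `sectionmap` implements that pipeline for people who have
stacks of section images and region annotations and want reproducible,
automated counts: microscopists, tracing labs, and method developers who
need a fully ground-truthed benchmark for soma detection.

## The method

**Maximum correlation thresholding (MCT).** For every gray value *i*, let
`y(i)` be the binary mask `y = 1` where the pixel exceeds *i*. The package
computes the Pearson correlation corr(x, y(i)) between image and mask at
every threshold from the gray histogram in closed form,

    corr(x, y(i)) = Σ_{j>i} n_j (j − x̄) /
                    ( sqrt(Σ_j n_j (j − x̄)²) · sqrt(N_i (N_m − N_i) / N_m) )

and selects thresholds from this curve: the argmax (optimal single
threshold) and, from the largest-magnitude excursions of the smoothed
derivative, the two transitions that correspond to the tissue edge and to
the labeled somata.

**Segmentation.** Median filtering (3×3) removes shot noise; Moore-Neighbor
tracing extracts closed tissue contours, which are Gaussian-smoothed;
thresholded cell pixels are grouped by 8-connectivity and filtered by area
(60–600 µm²) and circularity 4πA/P² ≥ 0.4. Unresolvable clumps are dropped,
so counts are deliberately conservative at dense injection sites.

**Alignment and quantification.** Sections are rigidly aligned by
exhaustive (FFT) search for the integer shift maximizing smoothed-boundary
correlation, validated by pairwise boundary correlations at increasing edge
thickness. Detected cells are placed in micrometer coordinates
(z = section index × thickness), assigned the region label under their
centroid, and summarized as injection-site precision (fraction of bulb
cells inside the GCL), per-region percentages, axis histograms, density
maps and compartment ratios (e.g. MOB vs AOB).

**Synthetic ground truth.** A generator renders section stacks of
nested-ellipse phantoms with two intensity populations, shot noise, a
smooth rostro-caudal fluorescence decline, dense overlapping injection-site
clusters and per-section rigid shifts — with every cell position, label,
threshold and shift recorded — so each pipeline stage is testable without
any data download. See `vignette("sectionmap-methods")` for the full model.

## Worked example

```r
library(sectionmap)

# A packaged fixture: ~1,500 injection-site cells in a bulb with a nested
# granule cell layer, 84% placed inside the layer.
brain <- generate_brain(preset("fig4_example"))
res <- process_stack(brain$stack, brain$region_labels, brain$name_table)

res$selections[[1]]
#> <threshold_selection> optimal 0 | tissue 21 | cell 72 (0 missing)

nrow(res$cells)
#> [1] 1500

injection_site_report(res$recon, organ_region = "MOB", layer_region = "GCL")
#> <injection_site_report> 1260 inside / 240 outside (84.0%), COM (1055, 966, 350) um
```

The threshold selection says the tissue silhouette separates from the dark
background at gray value 21 and labeled somata from tissue
autofluorescence at 72; all 1,500 generated cells are detected, and 84% of
the bulb's cells fall inside the GCL mask — the generating proportion read
back through the full image → cells → regions path. The same objects
expose the correlation curves (`res$curves`), alignment transforms and
validation matrices (`res$transforms`, `res$alignment`), and the assembled
reconstruction (`res$recon`) for region summaries via
`region_assignment()`.

A full run with artifacts on disk (thresholds, cells, transforms, region
tables, JSON reports, log and manifest):

```r
run_pipeline(list(input = list(preset = "fig4_example"),
                  quantify = list(organ_region = "MOB",
                                  layer_region = "GCL")),
             output_dir = "out/fig4")
```

or from a shell, `inst/scripts/sectionmap run --preset fig4_example --out out/fig4`.

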