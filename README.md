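# octseg

Graph-based multi-surface segmentation of mouse retinal SD-OCT volumes,
with layer-thickness analysis for longitudinal photoreceptor-degeneration
studies.

## What problem this solves

Spectral-domain OCT volumes of the mouse retina (typically 1000 A-scans x
100 B-scans x 2048 depth voxels over a 1.4 x 1.4 x 1.6 mm field) contain up
to ten resolvable retinal surfaces. Studies of the light-damage (LD) model
image both eyes of every animal at several timepoints, which makes manual
tracing infeasible — and in LD retinas the outer nuclear layer (ONL) and
photoreceptor bands progressively vanish, so a useful segmenter must let
surfaces coincide where a layer has disappeared. `octseg` is aimed at
researchers running such studies: it segments healthy (10 surfaces) and LD
(6 surfaces) volumes automatically, validates against manual tracings, and
performs the standard 8-layer, four-quadrant thickness statistics.

## The method

Surfaces `z = S(b, x)` are recovered simultaneously, per stage, as the exact
global minimizer of

```
sum_s sum_{b,x} c_s(b, x, S_s(b, x))
```

subject to hard constraints: `|ΔS| <= smooth_x` between laterally adjacent
columns, a relaxed `|ΔS| <= smooth_b` between B-scans (axial motion), and
`min_sep <= S_lower - S_upper <= max_sep` for adjacent surface pairs (with
`min_sep = 0` for the LD-mode ONL, allowing zero thickness). The problem is
encoded as a minimum closure graph — node `(s, b, x, z)` in the source set
iff `S_s(b,x) >= z`, node weights `c(z) - c(z-1)`, constraints as
infinite-capacity arcs — and solved with one minimum s-t cut. Ties resolve
to the unique pointwise-minimal optimum, and an exhaustive-enumeration
oracle (`brute_force_segment`) verifies exactness on small instances.

Costs come from per-stage random-forest voxel classifiers (`cost = 1 - P`)
trained on sparse control-point delineations, over features of smoothed
intensities, axial derivatives and ROI-relative geometry; the coarse
localization stage uses plain gradient costs at quarter resolution. The
full pipeline: downsample 2x (lateral, axial) -> coarse ILM/outer-boundary
ROI -> three constrained stages -> rescale to native resolution.

Because the original study's scans are not deposited, the package includes
a synthetic phantom (`generate_phantom`) with ground truth — layered mouse
retina reflectivity, ONH depression, vessel shadows, B-scan jitter, speckle
— plus simulated raters and cohort simulation, which power the entire test
suite.

## Worked example

```r
library(octseg)

# 1. Simulate a healthy scan with known ground truth
params <- phantom_params(shape = c(12, 64, 448))
train <- generate_phantom(params, seed = 11)
scan  <- generate_phantom(params, seed = 22)

# 2. Train the per-stage boundary classifiers on six traced slices
tracing <- simulate_rater(train$truth, rater_model(sd_um = 1, spacing_px = 4),
                          slice_ids = c(1, 3, 5, 7, 9, 11), seed = 5)
models <- train_segmentation_models(train$volume, tracing, "healthy", seed = 42)

# 3. Segment
seg <- segment_retina(scan$volume, "healthy", models)
print(seg)
#> <oct_segmentation> mode healthy: 10 surfaces on a 12 x 64 grid
#>   total time 46.4 s (downsample=0.0, coarse=0.1, features=0.1, stage1=6.0, stage2=10.2, stage3=30.0)

# 4. Mean unsigned border error (um) against truth, inside the analysis annulus
mask <- make_eval_mask(dim(scan$volume)[1:2], scan$volume$spacing)
sapply(names(seg$surfaces$surfaces), function(nm)
  border_error(seg$surfaces$surfaces[[nm]],
               scan$truth$surfaces$surfaces[[nm]],
               mask, scan$volume$spacing[3])[["mean"]])
#>       ILM RNFGC-IPL   IPL-INL   INL-OPL   OPL-ONL       ELM    EZ-Top EZ-Bottom
#>      0.47      0.64      0.61      0.75      0.76      0.53      0.60      0.71
#>    OS-RPE        BM
#>      0.64      0.62
```

Every surface lands within a micrometre of truth — below typical
inter-rater variability (1.6–2.2 um on real scans). Thickness analysis and
a simulated day-6 control-vs-LD comparison of the outer retina (OR):

```r
maps <- thickness_maps(seg$surfaces, scan$volume$spacing, "healthy")
quadrant_stats(maps$TRT, scan$volume$spacing)
#>   quadrant n_px  mean     sd
#> 1        S  106 190.0 0.8246
#> 2        I  106 190.3 1.0353
#> 3        N  102 189.9 0.8617
#> 4        T  102 190.3 1.1642

tab <- ld_reference_thickness()
co <- generate_cohort(tab[tab$layer == "OR" & tab$day == 6, ],
                      n_per_group = 5, seed = 1)
group_compare(co[co$group == "control", ], co[co$group == "ld", ])[1, ]
#>   layer quadrant day n mean_a mean_b    t df        p significant
#> 1    OR        I   6 5    113   37.4 63.5  4 3.68e-07        TRUE
```

The total retinal thickness recovered in each quadrant (≈190 um) matches
the phantom's configured healthy retina, and the simulated day-6 cohorts
separate decisively at p < 0.01 — the pattern that motivates the LD model.

A command-line front end wrapping the same functions lives at
`inst/cli/octseg.R` (subcommands `simulate`, `train`, `segment`,
`thickness`, `compare`).

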