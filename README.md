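# adiposcore

Per-nucleus lipid droplet scoring for adipogenesis image cytometry.

Adipocyte differentiation assays stain neutral lipid droplets (Nile Red /
AdipoRed in fluorescence, Oil Red O in colour brightfield) and ask what
fraction of cells has differentiated. Whole-well readouts — plate-reader
fluorescence, dye extraction — are corrupted by the very artefacts that
differentiation protocols create: overconfluent monolayers with heavy
non-uniform background staining, dead cells, and dense multilayer clumps
that soak up dye non-specifically. `adiposcore` measures per cell instead
and reports, for every well, the **adipogenic score**: the percentage of
nuclei whose lipid score exceeds a gate threshold.

The pipeline, per imaging field:

1. **Local adaptive binarisation.** A pixel is foreground iff it strictly
   exceeds the Gaussian-weighted mean of its z×z neighbourhood
   (σ = 0.3((z−1)/2 − 1) + 0.8, kernel normalised to unit sum), with
   physical kernel sizes of 33 µm (nuclei) and 66 µm (lipid) converted
   through the pixel pitch. Local prominence, not absolute brightness,
   defines signal — which is what survives heavy background.
2. **Nucleus segmentation.** Watershed on the distance transform splits
   touching nuclei; 8-connected components are then filtered by area and
   aspect ratio, excluding debris and misshapen dead-cell nuclei
   (too small / too elongated) and saturated clumps (fused components far
   above any single-nucleus size). Exclusion counts per reason are
   first-class output.
3. **Lipid scoring.** For each kept nucleus, within its bounding box
   dilated by 3 µm: S = P<sub>T</sub> × I<sub>s</sub>, where
   P<sub>T</sub> is the fraction of searched area above the lipid
   threshold and I<sub>s</sub> the mean lipid intensity over that
   foreground. Cells with S strictly above the gate are differentiated.
4. **Aggregation.** Nuclei pool across fields; each well gets its score
   histogram, mean lipid score, and adipogenic score; screens rank wells
   by delta against control (e.g. DMSO) wells.

Colour Oil Red O + haematoxylin images enter the same pipeline through
red/blue colour-bias unmixing (lipid = max(0, R − max(G,B)), nuclei =
max(0, B − max(R,G))). Droplet radii can be estimated separately by
background subtraction plus a circular Hough transform. A fully
ground-truthed synthetic scene generator (nuclei, droplet clusters,
background gradients and blotches, dead cells, saturated clumps) backs
the validation suite.

## Worked example

Simulate a four-well plate with known differentiated fractions
(0, 0.25, 0.5, 1), analyse it, and compare:

```r
library(adiposcore)
library(tibble)

wells <- tibble(well_id = c("A01", "A02", "A03", "A04"),
                differentiated_fraction = c(0, 0.25, 0.5, 1))
simulate_plate(wells, "demo_plate", base_spec = scene_spec(), seed = 7)

cfg <- pipeline_config(manifest = "demo_plate/manifest.csv",
                       out_dir = "demo_plate/results",
                       offset = -6,          # threshold at local mean + 2x noise SD
                       gate_threshold = 10)  # between the two score modes
results <- run_pipeline(cfg)
well_summary(results)
#> # A tibble: 4 × 6
#>   well_id n_nuclei adipogenic_score mean_lipid_score gate_threshold valid
#>   <chr>      <int>            <dbl>            <dbl>          <dbl> <lgl>
#> 1 A01          200                0            0.921             10 TRUE
#> 2 A02          200               25           16.2               10 TRUE
#> 3 A03          200               50           30.4               10 TRUE
#> 4 A04          200              100           60.6               10 TRUE
```

The planted fractions are recovered as adipogenic scores of 0 %, 25 %,
50 % and 100 % of the 200 nuclei per well; `mean_lipid_score` is the
population mean of S (the grey line in the per-well histogram,
`autoplot(results[["A03"]])`). `demo_plate/results/` now holds the
per-well and per-nucleus CSVs, a JSON summary, and the per-field
exclusion log. On real plates, derive the gate from control wells
(`control_ids = c(...)`, gate = control mean + 2 SD) instead of fixing it.

Droplet sizing on a field of 20 planted discs:

```r
fld <- generate_droplet_field(n = 20, radius_range_um = c(2, 8), seed = 3)
det <- detect_droplets(subtract_background(fld$image, window_um = 64),
                       r_min_um = 1.5, r_max_um = 10)
summarize_radii(det)
#> <droplet_summary> 20 droplets, mean radius 4.86 um
```

A command-line wrapper with `analyze`, `screen`, `simulate` and
`droplets` subcommands is installed at `inst/scripts/adiposcore`.

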