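# fpmtools

Object-based analysis of excitation-resolved fluorescence polarization
microscopy (FPM) images in R.

FPM acquires four images of a field while rotating the excitation
polarization through 0°, 45°, 90° and 135°. Because fluorophores absorb in
proportion to cos² of the angle between the excitation field and their
transition dipole, each pixel's intensity traces a sinusoid in the
excitation angle ω, and two quantities can be retrieved by pixelwise
arithmetic:

    S0 = (I0 + I45 + I90 + I135) / 2      S1 = I0 − I90      S2 = I45 − I135

    order    p = sqrt(S1² + S2²) / S0          (in-plane dipole alignment)
    azimuth  α = atan2(S2, S1) / 2             (mean dipole direction, mod 180°)

For whom: cell biologists and microscopists who want per-structure (not
per-image) order and orientation statistics — desmosomes and other puncta,
actin filaments and other linear structures — without writing image-analysis
code. The package provides:

* pixelwise order/azimuth maps with optional flat-field correction and a
  plug-in point for custom per-pixel statistics;
* "puncta" (top-hat → Otsu → connected components) and "filaments"
  (ridge enhancement → skeleton → branch split) segmentation schemes;
* per-object features: morphology, intensity, local signal-to-background,
  mean order, axial mean azimuth, azimuthal disorder s0;
* **midline-relative azimuths**: a Voronoi-based medial-axis midline per
  object, so azimuths can be expressed relative to the structure's local
  orientation (α_midline = 90° means perpendicular to the structure);
* axial (period-180°) circular statistics; object filtering, labeling (e.g.
  short/long filaments at the 17.5 µm persistence-length cutoff) and
  k-means clustering; project-level batch processing;
* composite visualizations (order–intensity overlay, azimuth HSV, azimuth
  sticks, axial polar histograms);
* a synthetic-scene generator with per-pixel ground truth, so the entire
  pipeline is testable by parameter recovery without microscopy data.

## Worked example

```r
library(fpmtools)

# a synthetic field of 30 puncta with Poisson noise and known ground truth
scene <- make_puncta_field(n = 30, noise = list(type = "poisson", gain = 1),
                           seed = 7)
stack <- render_stack(scene)

maps <- compute_pixel_maps(stack)
#> <fpm_pixel_maps> 128 x 128 px; mean order 0.296; 0 custom statistic(s)

seg <- segment_puncta(maps$S0)
#> <fpm_segmentation scheme='puncta'> 30 object(s), 879 mask px

obj <- extract_features(seg, maps, stack, compute_midlines = FALSE)
obj <- kmeans_cluster(obj, "local_sb", k = 2, seed = 1)
head(obj[, c("object_id", "area_px", "local_sb", "mean_order",
             "mean_azimuth_image_deg", "cluster_id")], 4)
#>   object_id area_px local_sb mean_order mean_azimuth_image_deg cluster_id
#> 1         1      27    5.350     0.5465                 147.43          2
#> 2         2      30    5.035     0.5380                 137.60          1
#> 3         3      30    5.227     0.5320                  16.55          1
#> 4         4      28    5.380     0.5885                  38.73          2
```

All 30 planted puncta are recovered. The scene plants order 0.7 on a
background of 10 with amplitude 90; the unpolarized background dilutes the
recovered per-object order toward `p·A/(A + 2·Bg) ≈ 0.57`, and Poisson noise
accounts for the remaining scatter — exactly the signal-to-background effect
the `local_sb` feature and the S/B clustering are designed to expose
(cluster 1 is always the low-S/B cluster).

The same workflow runs from a shell via the thin CLI wrapper:

    Rscript inst/cli/fpm.R simulate --type puncta --out sim --seed 7 --n 30
    Rscript inst/cli/fpm.R process  --input sim/stack.tif --out results
    Rscript inst/cli/fpm.R render   --input sim/stack.tif --type azimuth-hsv --out hsv.png

`process` writes float32 TIFF maps (S0, order, azimuth), an 8-bit mask, an
object CSV and a midline CSV.

## Testing

    Rscript -e 'testthat::test_dir("tests/testthat", package = "fpmtools",
                                   load_package = "installed")'

The suite validates every stage against independent oracles: brute-force
Otsu and 1-D k-means searches, grid-search sinusoid fits and axial means,
analytic midline geometry (bars, discs, S-shaped ribbons with known
generating curves), and parameter recovery on seeded synthetic scenes.

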