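---
title: "Object-based analysis of fluorescence polarization microscopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based analysis of fluorescence polarization microscopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpmtools)
```

## The measurement model

Excitation-resolved fluorescence polarization microscopy (FPM) acquires four
images of the same field while rotating the excitation polarization through
0, 45, 90 and 135 degrees (anticlockwise from the +x axis of the microscope
frame). A fluorophore absorbs in proportion to $\cos^2$ of the angle between
the excitation field and its transition dipole, so over the many fluorophores
in a diffraction-limited spot the measured intensity varies sinusoidally with
the excitation angle $\omega$:

$$I_\omega \;=\; a + b\,\cos 2(\omega - \alpha).$$

Two quantities summarize the response at each pixel. The **order**
$p$ is the normalized modulation amplitude: $p = 0$ when dipoles are
isotropically distributed (no modulation), $p \to 1$ when they are perfectly
coaligned in the image plane. The **azimuth** $\alpha$ is the phase: the mean
in-plane dipole direction, an *axial* quantity defined modulo 180 degrees.
Both follow from pixelwise arithmetic on the four images:

$$S_0 = \tfrac{1}{2}(I_0 + I_{45} + I_{90} + I_{135}), \qquad
  S_1 = I_0 - I_{90}, \qquad S_2 = I_{45} - I_{135},$$

$$p = \frac{\sqrt{S_1^2 + S_2^2}}{S_0}, \qquad
  \alpha = \tfrac{1}{2}\,\mathrm{atan2}(S_2, S_1).$$

For the equally spaced four-angle design these closed forms are exactly the
least-squares sinusoid fit (`fit_pixel_sinusoid()` verifies this identity to
machine precision; the test suite additionally checks it against a grid
search over $(a, b, \phi)$). Out-of-plane dipole tilt enters only as a
$\sin^2\theta$ factor absorbed into the amplitude; no attempt is made to
recover the polar angle.

Numerical conventions worth knowing:

* $p$ is **not clipped above 1**. Shot noise can push
  $\sqrt{S_1^2+S_2^2}$ above $S_0$, and clipping would bias exactly the
  signal-to-background analyses the package supports.
* Pixels with $S_0 = 0$ have undefined order; pixels with $S_1 = S_2 = 0$
  have undefined azimuth, encoded as `NaN` — never as 0, which is a valid
  direction.
* Azimuths are radians in $[-\pi/2, \pi/2)$ in maps and map files, degrees in
  $[0, 180)$ in object tables.

Flat-field correction (`flat_field_correct()`) averages the calibration
stacks per angle, divides each averaged flat by its own mean (so a uniform
flat is a no-op and the photoelectron scale is preserved), and divides the
data pixelwise. This mean-normalized form was chosen because it is the
weakest standard correction: it removes illumination shape without
rescaling total intensity.

## Why objects, and what is measured per object

An image-level mean order pools desmosomes or filaments of very different
quality and architecture into one number. The package therefore segments the
average-intensity image into objects and reports features per object:

* morphology: area, perimeter, eccentricity (standard region properties of
  the 8-connected mask);
* intensity: mean $S_0$ and the **local signal-to-background ratio** — mean
  $S_0$ over the object divided by mean $S_0$ over a surrounding annulus
  (dilation by `buffer_px + annulus_px` minus dilation by `buffer_px`,
  default 2 + 2 px), excluding pixels of *any* object so a close neighbor
  does not contaminate the background estimate. Low local S/B predicts
  noise-inflated background and therefore *reduced* recovered order; the
  acceptance suite reproduces this monotone relationship on seeded Poisson
  scenes.
* polarization: mean order $\bar p$, the axial circular mean azimuth in the
  image frame ($\bar\alpha_\mathrm{image}$), the midline-relative mean
  azimuth ($\bar\alpha_\mathrm{midline}$), and the azimuthal disorder $s_0$
  (axial circular standard deviation of the object's pixel azimuths).

Two built-in segmentation schemes cover the common morphologies. The
**puncta** scheme (white top-hat with a disc of radius 8 px, Gaussian smooth
of 1 px, global Otsu threshold on the 256-bin histogram, hole filling,
minimum area 10 px²) targets diffraction-limited spots and small curvilinear
structures at roughly 0.1 µm/px. The **filaments** scheme enhances ridges
with the scale-normalized most-negative Hessian eigenvalue across sigmas
{1, 2, 3} px, thresholds at the 0.95 quantile of the enhanced image,
skeletonizes, cuts the skeleton at junctions, prunes branches below 10
skeleton pixels and dilates each branch by 2 px into its own labeled object.
The operator chains are this package's own reconstructions of
"morphology + Otsu" and "detect linear, extended structures"; every step is
a parameter, so either chain can be retuned per dataset. The 0.95 ridge
quantile assumes filaments occupy at most a few percent of the field — the
regime of sparse cytoskeletal preparations — and should be lowered for
denser scenes; a secondary magnitude floor (`ridge_floor`, default 5% of
the maximum response) keeps near-zero background responses out of the mask
when filaments are much sparser than the quantile assumes.

Two implementation notes on the filaments chain. Thinning produces
4-connected staircases on oblique lines and small loops at crossings, so the
skeleton is first reduced to minimal 8-connectivity by deleting 8-simple
pixels; junctions are then detected with the 8-neighborhood crossing number
(three or more emanating arms), which a naive neighbor count gets wrong on
staircases. Where dilated branches overlap, pixels are assigned to the
geodesically nearest branch.

## The midline and midline-relative azimuths

Raw azimuths are expressed in the microscope frame and say nothing about a
structure unless the structure happens to be aligned with the image axes.
The biologically meaningful quantity is the azimuth **relative to the local
orientation of the structure**: for a junction whose dipoles stand normal to
the membrane, $\bar\alpha_\mathrm{midline} \approx 90°$ regardless of how
the junction lies in the image.

The midline algorithm proceeds: trace the 8-connected perimeter of the
object (Moore tracing, anticlockwise); offset the boundary outward by 1 px
along vertex normals, smooth it with a circular 5-point moving average and
resample it at 1 px arc-length spacing; build the Voronoi diagram of the
boundary points and keep the finite edges whose endpoints lie strictly
inside the boundary polygon — a discrete medial-axis approximation; prune
spur branches shorter than 4 px; take the **longest leaf-to-leaf geodesic**
through the remaining graph; smooth and resample it; and finally extend both
ends along their end tangents until they meet the original object boundary,
so the midline spans the full structure. Tangents are computed by central
differences and are axial — no attempt is made to orient the midline.
Each object pixel then inherits the tangent of its nearest midline point
(ties to the lower point index), and
$\alpha_\mathrm{midline} = (\alpha_\mathrm{image} - \mathrm{tangent}) \bmod 180°$.

Design choices that were genuinely open:

* *"Central most edges" of the Voronoi diagram* is operationalized as the
  longest geodesic between leaves. It yields a single open centerline for
  both curvilinear puncta and filament branches, and degrades gracefully: on
  a disc the interior graph is a small web with no long path.
* *Validity*: a midline is accepted only if the pre-extension spine is at
  least `min_length` (5 px) **and** at least twice the median
  spine-to-boundary distance. Near-isotropic objects (discs, compact
  puncta) therefore keep $\bar\alpha_\mathrm{image}$ but have
  $\bar\alpha_\mathrm{midline}$ undefined rather than guessed from a
  spurious axis.
* *Degenerate Voronoi input*: boundary points resampled at uniform spacing
  are frequently exactly collinear or cocircular, which breaks Voronoi
  adjacency construction. Points are perturbed by a deterministic 1e-3 px
  pattern (escalated tenfold on failure), three orders of magnitude below
  the geometric tolerances.
* *End extension*: extending to the boundary makes a bar's midline span its
  full length. The synthetic ribbon generator draws **flat-capped** ribbons
  (pixels within half-width of the curve, clipped by projection at the curve
  ends) precisely so that the generating curve and the full-length midline
  coincide; with round caps the two definitions necessarily differ by half a
  width per end, under any endpoint convention.

## Axial circular statistics

Azimuths are directions modulo 180°, so ordinary circular statistics do not
apply directly. The package uses the standard doubled-angle treatment
throughout (`axial_mean()`, `axial_std()`): double the angles onto the full
circle, form the (optionally weighted) circular resultant with mean
direction $\mu_2$ and length $\bar R$, and report $\mu_2 / 2$ as the axial
mean and $s_0 = \tfrac{1}{2}\sqrt{-2\ln\bar R}$ as the axial standard
deviation — i.e. the doubled-scale dispersion halved back to the axial
scale; the halved convention is fixed and documented here because both
conventions appear in the literature. The mean is reported as undefined when
$\bar R < 10^{-9}$ (e.g. an orthogonal pair {0°, 90°}, which cancels
exactly). Polar histograms duplicate each angle at $\theta$ and
$\theta + 180°$ so that plots show both equivalent directions and total
count $2n$.

## The synthetic-scene generator

Every stage of the pipeline is validated by parameter recovery on scenes
with per-pixel ground truth. The forward model is

$$I_\omega = B_g + \tfrac{1}{2} A \left(1 + p_\mathrm{true} \cos 2(\omega -
\alpha_\mathrm{true})\right),$$

rendered at the four angles, then optionally blurred (Gaussian PSF — optics
precede detection) and then degraded with noise (additive Gaussian, or
Poisson counts with configurable gain), all under the scene seed with the
caller's RNG state restored. Three consequences of this parameterization are
used as oracles: recovered $(p, \alpha)$ equal the scene truth *exactly*
wherever $B_g = 0$; with background, the recovered order is diluted to
$pA/(A + 2B_g)$, so noise-free background tests assert that value, not
$p_\mathrm{true}$; and the mean $S_0$ over an object is $2B_g + A$, giving a
constructed local S/B of $(2B_g + A)/(2B_g)$.

Morphologies: disc puncta at rejection-sampled centers with a minimum
separation; S-shaped ribbons around a full sine period with a configurable
rotation, width and dipole rule (`"parallel"`, `"normal"`, or a fixed
angle — `"normal"` plants a ground-truth $\alpha_\mathrm{midline}$ of 90°
by construction); and straight filaments with planted metric lengths for
the short/long split at the 17.5 µm persistence-length cutoff of
phalloidin-stabilized F-actin (boundary value inclusive: L = 17.5 µm is
"long"). Default study conditions — puncta of radius 3 px with amplitude 90
photoelectrons on background 10 at 0.1 µm/px, filaments 4 px wide at
0.2 µm/px — represent a bright fluorescent-protein label on a modern sCMOS
detector.

What the generator does **not** emulate: vectorial high-NA depolarization,
photobleaching between the four frames, detector read-noise structure,
spatially varying background, and out-of-focus light. Passing recovery tests
therefore demonstrate the correctness of the arithmetic and geometry, not
robustness to every artifact of real microscopy; flat-field correction and
the local S/B diagnostics exist precisely because real data violate the
generator's uniformity assumptions.

## Clustering, filtering, batch processing

`run_pipeline()` processes a project (groups → images → objects) image by
image: flat-field → maps → segmentation → features → midlines → relative
azimuths. It is deterministic given the configuration; per-image failures
are logged and skipped. Object filtering is a conjunction of
(feature, comparator, value) predicates; labeling rules must form a
partition and fail loudly on overlap or gaps. `kmeans_cluster()` z-scores
the chosen features and runs `stats::kmeans` with 20 restarts and 300
iterations under a caller-supplied seed; clusters are renumbered so cluster
1 has the lowest mean of the first feature, making "cluster 1 = low S/B" a
stable reporting convention. With 20 restarts on the low-dimensional,
well-separated feature sets used here, the choice of initialization scheme
is immaterial; the 1-D case is verified against an exhaustive best-split
oracle in the tests.

## Worked example

```{r example, eval = FALSE}
library(fpmtools)

scene <- make_puncta_field(n = 30, noise = list(type = "poisson", gain = 1),
                           seed = 7)
stack <- render_stack(scene)
maps  <- compute_pixel_maps(stack)
seg   <- segment_puncta(maps$S0)
obj   <- extract_features(seg, maps, stack)
obj   <- kmeans_cluster(obj, c("local_sb"), k = 2, seed = 1)
write_object_table(obj, "objects.csv")
render_azimuth_hsv(maps, path = "azimuth_hsv.png")
```

The same workflow is scriptable from a shell through the `fpm` CLI
(`inst/cli/fpm.R`): `simulate`, `process`, `segment`, `midline`, `cluster`,
`export`, `render`.

## Problem sizes and limitations

The validation suite and the acceptance script run on deliberately small
scenes — 96–256 px frames, tens of objects, $10^4$ random pixels for the
fit-equivalence check — chosen so the full battery completes in well under a
minute while still exercising every code path; all of the quantities
measured are size-stable (errors are per-pixel, not aggregate).

Known limitations: no vendor-format readers (convert to TIFF/OME-TIFF
first); no registration between the four polarization frames; midlines are
2-D and tangent-only (no curvature features); the filament scheme labels
branches, not whole branched trees; and the crossing of two filaments is
split at the junction rather than resolved into two continuous objects.
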