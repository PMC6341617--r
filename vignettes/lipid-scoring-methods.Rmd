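---
title: "Per-nucleus lipid scoring: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-nucleus lipid scoring: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Adipocyte differentiation assays stain neutral lipid droplets (Nile
Red/AdipoRed in fluorescence, Oil Red O in brightfield) and ask what
fraction of cells has become lipid-storing. Plate-reader readouts integrate
the whole well, so they are corrupted by exactly the artefacts that
differentiation protocols produce: overconfluent monolayers with heavy,
spatially varying background staining, dead cells, and dense multilayer
clumps that adsorb dye non-specifically. Manual counting avoids some of
this but is slow and observer-biased.

`adiposcore` scores each cell instead. Per imaging field it:

1. binarises the nuclei and lipid channels with a *local* Gaussian-mean
   adaptive threshold;
2. splits touching nuclei by watershed on the distance transform;
3. excludes implausible regions by size and shape (debris, dead cells,
   clump remnants);
4. scores every kept nucleus by the lipid signal in its neighbourhood,
   $S = P_T \times I_s$;
5. gates scores into differentiated / non-differentiated and pools wells
   into an **adipogenic score** — the percentage of nuclei above the gate.

## Adaptive binarisation

For a window size $z$ (odd, in pixels) the kernel is the normalised 2D
Gaussian on the centred integer lattice with

$$\sigma = 0.3\left(\frac{z-1}{2} - 1\right) + 0.8 ,$$

the convention that ties bandwidth to window size, so one physical length
determines the filter completely. The threshold at a pixel is the
Gaussian-weighted mean of its window, and a pixel is foreground iff its
intensity *strictly* exceeds that local mean (minus an optional constant
`offset`, default 0). Because only local prominence matters, a stain is
detected even when the background elsewhere in the image is brighter than
the signal here. Two consequences of the strict comparison are worth
knowing:

* a perfectly flat image yields an empty mask — that is the intended
  contract;
* on a *noisy* flat region, roughly half of all pixels sit above their
  local mean, so foreground "flecks" appear. At high densities those
  flecks can 8-connect into large components. The `offset` parameter
  exists for this: with uncorrelated camera noise of standard deviation
  $\sigma_n$, setting `offset = -2 * sigma_n` (the comparison is
  `In > mean - offset`) raises the effective threshold by $2\sigma_n$ and
  suppresses the flecks while leaving genuine stains, whose prominence is
  tens of intensity units, untouched. All synthetic-scene analyses in the
  test-suite use `offset = -6` for the generator's noise SD of 3; the
  package default remains 0.

Window sizes are given physically: 33 µm for nuclei and 66 µm for lipid
droplets by default (two to three times the typical object-group size
works well), converted through the pixel pitch and rounded to an odd pixel
count with a floor of 3. Pixel pitches of 2 µm/pixel or more trigger a
warning — the convolution costs resolution, and detection of small
droplets degrades — but processing continues. Borders are handled by
replicate-edge padding, which avoids the artificial dark rim that zero or
reflective padding would diff against. The convolution is computed in
floating point as two separable shift-and-add passes; the threshold field
is never re-quantised before comparison.

One interpretive note: descriptions of this thresholding scheme sometimes
stack a $1/z^2$ averaging on top of an already unit-normalised kernel.
Taken literally that would divide thresholds by $z^2$ and mark every
pixel foreground; the meaningful reading, used here, is that the
threshold *is* the unit-sum Gaussian-weighted local mean — the standard
adaptive-Gaussian threshold.

## Nucleus detection and exclusion filters

Foreground components are labelled with 8-connectivity. Touching nuclei
are first separated by a watershed on the negated Euclidean distance
transform, seeded at distance-transform maxima no closer than
`min_seed_distance_um` (default 6 µm, about one nucleus radius — smaller
separations over-segment textured nuclei). The implementation uses
EBImage's watershed with its local-maxima search radius set from that
distance; where two basins meet, the higher-labelled side yields a
one-pixel background cut, a deterministic tie-break that makes masks
reproducible.

Each region then receives a status, and *nothing is deleted*:

| status      | rule                                   | what it catches              |
|-------------|----------------------------------------|------------------------------|
| `too_small` | area < `min_area_um2` (default 20 µm²) | debris, pyknotic dead nuclei |
| `too_large` | area > `max_area_um2` (default 500 µm²)| saturated clumps, fused masses |
| `misshapen` | aspect ratio > `max_aspect_ratio` (3)  | elongated/crescent dead nuclei |
| `kept`      | all bounds pass                        | live, countable nuclei       |

Aspect ratio comes from second central moments with the usual 1/12
per-pixel (unit-square) variance term, so a single pixel has ratio 1 and a
1×N line has ratio ≈ N rather than infinity. Filter bounds are
user-definable configuration, not canonical constants: mammalian nuclei
are ~7–12 µm across, which motivates the defaults. Filtering happens
*after* watershed splitting (the order matters for fused masses and is a
documented choice). Saturated embryoid-body-like clumps need no special
detector: saturation in both channels fuses the clump into one giant
component whose area exceeds `max_area_um2`, and nuclei inside it are
invisible, so the clump is simply absent from scoring — which is the
robustness property the exclusion log makes auditable (per-field counts of
each status are first-class output).

## The lipid score

For each kept nucleus the search region is its bounding box dilated by
`search_radius_um` (default 3 µm — a good balance of false positives and
negatives at high density) and clipped to the image. Then

* $P_T$ = fraction of search-region pixels above the lipid threshold,
* $I_s$ = mean lipid intensity over those foreground pixels (0 if none),
* $S = P_T \times I_s$.

Two definitional choices are configuration-visible. $I_s$ is a *mean*
rather than a sum so that $S$ is bounded by the bit-depth maximum and
independent of nucleus size — one gate value then works across the
population (`intensity_mode = "sum"` restores the alternative). The
$P_T$ denominator is the whole dilated box, including the nucleus's own
pixels. Search regions of neighbouring nuclei may overlap and
double-count droplets; droplets are tied to nuclei by proximity only.

A nucleus is differentiated iff $S$ strictly exceeds the gate threshold.
Lipid scores are in arbitrary fluorescence units, so no universal gate
exists. When control (undifferentiated) wells are declared, the default
gate is mean + 2 SD of the pooled control scores; otherwise an explicit
gate is required. For the synthetic study conditions below, the score
distribution is bimodal by construction — a background-fleck mode below
~2 and a droplet mode above ~30 — and analyses use an explicit gate of 10
placed between the modes; with separated modes, any gate in the gap gives
identical counts, which is what makes exact recovery at fractions 0 and 1
a meaningful check rather than luck. (The mean + 2 SD rule cannot give an
exactly-zero rate on a 200-nucleus control well — about 2.5 % of a
roughly Gaussian score distribution exceeds its own mean + 2 SD — which
is why the explicit-gate route exists.)

Wells pool nuclei across fields with no per-field weighting; the
adipogenic score is 100 × differentiated / total, the histogram (default
50 uniform bins over $[0, \max S]$) is presentation only, and an empty
well is reported invalid with a missing score, never 0.

## Colour (Oil Red O / haematoxylin) images

RGB brightfield images are converted to the same two-channel form by
colour biases: lipid = `max(0, R - max(G, B))`, nuclei =
`max(0, B - max(R, G))`. Subtracting the *maximum* of the other two
channels makes neutral background cancel exactly and attenuates purple
overlap pixels — the reason colour imaging reads systematically lower
than fluorescence on dense cultures, where droplets sit on top of
counterstained nuclei. This is deliberately an RGB-space difference, not
Beer–Lambert optical-density stain deconvolution; users who need proper
stain separation under varying illumination should apply OD deconvolution
upstream and feed the resulting channels in as fluorescence-mode inputs.

## Droplet sizing

Radius estimation uses background subtraction followed by a circular
Hough transform. Background is a large-window Gaussian smooth (default
window 4× the largest droplet diameter; below 2× the droplets themselves
are attenuated, which warns). The transform:

* smooths lightly (5-px Gaussian) before central-difference gradients, so
  rasterised rims give accurate normals;
* takes edge pixels above the 90th percentile of non-zero gradient
  magnitudes, with an absolute floor of 3× the median magnitude over all
  pixels (a robust noise estimate) so noise cannot define the edge
  population;
* casts one inward vote per edge pixel per candidate radius (bright discs
  have rim gradients pointing at the centre), pools adjacent radius
  slabs, box-sums 3×3, and normalises by circumference;
* accepts peaks above `sensitivity` × the global maximum, subject to
  non-maximum suppression (no accepted circle may cover a later centre)
  and an angular-support gate: at least half of 32 rim samples must carry
  edge strength, which rejects arc fragments of larger circles;
* refines each accepted radius on the rim-gradient profile at 0.25-px
  steps.

Overlapping droplets are not deconvolved; heavily clustered droplets
under-count. This matches the monolayer context the sizing analysis is
meant for.

## The synthetic scene generator

Because per-cell ground truth cannot be obtained from real stained
cultures, validation runs on generated scenes with known truth. The
default `scene_spec()` describes a 640×640 px field at 1 µm/pixel with
200 non-overlapping elliptical nuclei (equivalent radius 5 ± 0.8 µm,
axis ratio up to 1.4, intensity 150 ± 20 on an 8-bit scale), a chosen
fraction of which are differentiated. Each differentiated nucleus carries
`8 + Poisson(4)` droplets (radius 1.5 ± 0.4 µm, intensity 180 ± 20)
placed inside the 3 µm dilation of its bounding box — the floor of 8
guarantees no differentiated cell is dropletless, keeping the two score
modes separated the way a well-stained culture is, and making the
exactness checks at fractions 0 and 1 well-posed. Background is a base
level (20) plus a linear gradient (15) and smooth blotches (10), with
additive Gaussian noise (SD 3). Optional extras: thin high-aspect
dead-cell slivers placed clear of nuclei and of each other (below the
minimum area *and* above the aspect bound once binarised), and a clump
disc saturated in both channels after noise, as a saturated detector
would record it.

Scenes are pure functions of their spec (seed included) and restore the
caller's RNG state. What the generator does *not* model: optical PSF,
correlated or signal-dependent (shot) noise, autofluorescence texture,
out-of-focus fields, or partially saturated clump borders. Passing the
suite therefore demonstrates the algorithmic contracts — robustness to
smooth background, exclusion of planted artefacts, score recovery under
known truth — not performance on any particular instrument's images,
where the gate and filter bounds must be set from control wells as in any
real screen.

Problem sizes used by the test-suite and the acceptance script: 25
wells of 200 nuclei for fraction recovery (fractions 0–1 × 5 seeds),
single 640×640 fields for the clump comparison, 5 seeded 320×320 scenes
for dead-cell exclusion, 3 fractions for the colour-imaging round trip,
and 3 × 20-disc fields plus a small/large-radius pair for droplet sizing.
These sizes give stable statistics at interactive runtimes.

## Numerical notes and limitations

* Thresholding uses exact separable summation (no FFT), so results are
  reproducible across platforms to floating-point associativity.
* On an exactly linear ramp the local mean equals the pixel value; the
  strict comparison then resolves by float rounding, so assertions about
  ramps use a tiny offset (−1) to absorb that flicker.
* Per-well CSVs print doubles with 17 significant digits; re-reading with
  a correctly-rounded parser reproduces every value bit-exactly.
* EBImage's connected-component labelling is 4-connected; diagonal-only
  contacts are merged afterwards through a label-adjacency graph, and
  final labels follow raster order of each component's first pixel.
* The watershed is tolerance-based; very unequal overlapping nuclei can
  still merge, and strongly lobed single nuclei can split. The ±5 % count
  accuracy asserted on dense synthetic fields bounds the net effect there.
* The colour-bias unmixing is linear in RGB and has no white-balance
  model; strongly tinted illumination will leak into both biases.
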