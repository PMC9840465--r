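---
title: "Methods: dome imaging, EDF reconstruction and assay computations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dome imaging, EDF reconstruction and assay computations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models and numerical
choices behind its pipeline: what is computed, under which assumptions,
which parameters matter, and what the synthetic validation does and does
not demonstrate about real microscope data.

## The measurement problem

An epithelial monolayer that actively transports solutes basolaterally
lifts off its impermeable substrate in fluid-filled domes. Because domes
are three-dimensional while transmitted-light images are not, a single
focal plane cannot capture them: cells on a dome apex may sit tens of
micrometers above the plate. The pipeline therefore acquires a z-stack per
field, fuses it into an all-in-focus composite plus a topography
height-map (extended depth of field, EDF), stitches tiled fields into a
whole-well mosaic, and measures transport function as the total area of
height-map components elevated above the plate plane, alongside a nuclei
count for cell number.

## EDF model and assumptions

For stack planes $I_0, \dots, I_{K-1}$ spaced $\Delta z$ apart, a focus
score $F$ is computed per plane and pixel, and the raw height-map is the
per-pixel argmax over $z$, ties resolved to the lowest plane index (a
stable, documented rule). The default $F$ is the local intensity variance
in a $7\times7$ window; Tenengrad (windowed squared Sobel gradient) is
available by configuration. Borders are handled by reflection padding, so
scores are translation-equivariant away from edges.

The raw argmax map is median-filtered (radius 2 px) to suppress
salt-and-pepper argmax noise without rounding dome edges, and the composite
is sampled from the smoothed indices. Two consequences of this design are
worth knowing:

* **Quantization.** The height-map is discrete: a surface at height $h$
  maps to the nearest plane, so heights are only defined to
  $\pm\Delta z/2$. Exactly between two planes both are equally sharp and
  the recovered index is legitimately either.
* **Window support on slopes.** A $7\times7$ focus window straddling a
  sloped surface sees several heights and reports the locally dominant
  one; on steep dome rims the argmax can differ from the centre pixel's
  nearest plane by one. The package's property tests therefore assert
  exact argmax recovery only where the surface is locally flat within the
  window, and a within-one-plane bound (at least 95% of textured pixels)
  everywhere else. "Textured" means local variance of the underlying
  specimen pattern at least $10^{-4}$ on a $[0,1]$ intensity scale; below
  that floor focus selection is uninformative for any metric.

## Stitching

Tiles are laid out on a regular grid with a configured overlap fraction.
Pairwise residual shifts between grid neighbours are estimated by
normalized phase correlation on the nominal overlap strips (mean-subtracted,
spectrum-whitened; integer-pixel peaks). Per-tile offsets are reconciled in
raster order by averaging the estimates propagated from the left and top
neighbours, rounded to integer pixels and clipped to the search radius.
Subpixel and nonrigid registration are out of scope. Pairs whose
correlation peak falls below 0.03 (featureless overlap, e.g. blank medium)
fall back to the nominal offset and are flagged.

Intensity mosaics are blended with linear distance-to-edge feathering.
Height-map mosaics are never blended: plane indices are categorical, and
averaging two plateaus would fabricate an intermediate height, so each
mosaic pixel is taken from the tile whose centre is nearest, and the same
offsets are used for composite and height-map. At least 16 px of overlap is
required in each registered dimension — below that the correlation support
is too small to be reliable.

## Dome segmentation and its error model

The plate-attached base plane is the *mode* of the height-map (robust as
long as domes cover less than half the field, unlike the mean), and the
dome mask is `height - base >= min_height_um`, followed by connected
components and a minimum-area filter (default 500 µm², rejecting residual
argmax specks).

`min_height_um` deserves care. Because of quantization, any value in
$(0, \Delta z]$ admits pixels from the first elevated plane upward — the
most sensitive well-posed setting, used by the pipeline default
(`quant.dome_min_height_um = 2.5` µm, half a z-step). Values up to
$1.5\,\Delta z$ are more conservative against unsmoothed argmax noise but
ignore the dome rim below the second plane; with the median-smoothed maps
this conservatism is unnecessary. Total dome area is non-increasing in both
`min_height_um` and the area filter, which the suite checks as an
invariant.

Domes are modelled as spherical caps, and a cap tapers continuously to
zero height at its rim. Pixels whose true elevation is below
$\Delta z / 2$ are indistinguishable from the base plane in any quantized
height-map, so the measured area of a cap of apex height $h$
systematically misses the outer annulus, approximately a fraction
$\Delta z / (2h)$ of the disc area for a shallow cap. This is why the
generator's default apex is 40 µm (8 z-steps): real domes lift the
monolayer by tens of micrometers — which is the reason 20-50 plane stacks
are acquired in the first place — and at $h = 40$ µm the rim loss is about
3-6%, within the 10% end-to-end recovery target the validation asserts.
Dome apexes of only 1-2 z-steps cannot meet that target under
quantization, with any algorithm, and the synthetic defaults deliberately
avoid that degenerate regime.

## The synthetic scene generator

The generator is first-class, tested code: every downstream stage is
validated against its exact ground truth. It emulates:

* a square field (default 512-540 µm at 1 µm/px for whole-well work;
  48 µm at 0.1 µm/px presets for mitochondria) with a granular brightfield
  texture (Gaussian-smoothed white noise, s.d. 0.17 about mid-grey) that
  gives every pixel focus information;
* nuclei as soft-edged discs (radius 5-7 µm) placed by rejection sampling
  with a minimum centre separation of one nucleus diameter (the default
  "crowded" condition; well-separated tests use two);
* domes as spherical caps (apex $\le$ radius, so the surface never
  overhangs) on an otherwise flat surface;
* mitochondria and autophagosome puncta as discs with areas drawn from
  disjoint regular (0.4-1.5 µm²) and enlarged (2.5-6 µm²) ranges, a
  configurable enlarged fraction (default 0.2), and densities per
  100 µm²;
* optics: isotropic Gaussian defocus with
  $\sigma = \text{rate} \cdot |z_\text{plane} - \text{height}|$
  (default 0.5 px/µm, so one z-step defocuses by 2.5 px — clearly
  distinguishable from the in-focus plane yet far from obliterating the
  texture), with $\sigma$ quantized to 0.5 px bins so one blurred copy per
  bin serves the whole stack;
* noise applied after blurring: Poisson shot noise at a scale of 200
  photons per unit intensity plus Gaussian read noise (s.d. 0.01), then
  clipping to the $[0,1]$ detector range.

All randomness derives from one integer seed; per-channel render substreams
are derived deterministically from it, and identical parameters give
bit-identical scenes, stacks and tilings.

What the generator does **not** emulate — and hence what passing tests do
not show — includes real cell texture and its spatially varying contrast,
illumination gradients and vignetting (no flat-field correction is
implemented), photobleaching, chromatic aberration, diffraction PSFs, and
segmentation-confounding debris. Recovery rates on real wells should be
expected to be lower than on the synthetic scenes, and the deterministic
thresholds may need retuning per experiment.

## Quantification choices

* **Nuclei:** Gaussian smooth (σ 1 px) → Otsu threshold → hole filling →
  distance-transform watershed → minimum-area filter (20 µm²). Watershed
  reliably splits pairs overlapping by less than about 30% of a radius; at
  the generator's default one-diameter separation recovery is exact to
  within 5%.
* **Mitochondria:** a deterministic threshold path (Otsu or fixed) and a
  trainable path (random-forest pixel classifier on a 5-feature ×
  n-scales stack: Gaussian intensity, gradient magnitude, Laplacian,
  largest structure-tensor eigenvalue, local variance) are interchangeable
  behind one interface. Tests validate the deterministic path against
  ground truth and the trainable path on a separable two-class problem
  (held-out pixel accuracy ≥ 0.99, deterministic for a fixed seed). The
  footprint is foreground pixels over field pixels, so per-object areas
  sum to footprint × field area exactly.
* **Enlarged mitochondria:** classed by `area > threshold`. No universal
  µm² cutoff exists; the default takes the 97.5th percentile of object
  areas in untreated control fields, recomputed per experiment
  (`enlarged_threshold()`), and any fixed value can be supplied. Reporting
  follows per-field sampling units (48 × 48 µm for mitochondria,
  331.5 × 331.5 µm for autophagosomes), both configurable.
* **Puncta:** intensity-quantile threshold (default 0.99) then a minimum
  area; counts are non-increasing in the area cutoff.

## Assay conventions

* **Mito Stress Test:** reference cycles follow the common plate-assay
  convention — last basal cycle, minimum post-oligomycin, maximum
  post-FCCP, last post-rotenone/antimycin-A — selectable to phase means
  instead. Identities `basal = ATP-linked + leak` and
  `spare = maximal - basal` hold exactly by construction;
  `spare_pct = 100 · maximal / basal` is undefined (NA) when basal
  respiration is not positive. OCR values are not normalized to cell
  number by default: confluent monolayers enter the assay with essentially
  identical cell counts across groups, and any normalization can be
  applied upstream.
* **Biopsy Z-scores:** background-corrected (per-fluorophore no-primary
  mean, clipped at zero, clipped tubules flagged), normalized to the
  mitochondrial-mass marker VDAC1 per tubule, standardized against control
  tubules using the sample (n−1) standard deviation. Scale invariance to a
  common rescaling of any one fluorophore is a tested property.
* **Metabolite quantification:** monoisotopic masses from the standard
  isotope table (C = 12 exactly, H = 1.0078250319, ...), [M−H]⁻ as
  mass − 1.007276 Da — the proton-mass convention that reproduces the
  published tenofovir-series values to 4 decimal places, which the suite
  asserts. Extraction windows are half-open $[lo, hi)$ around the target
  m/z for deterministic boundary behaviour; peak bounds are the contiguous
  above-baseline region around the global apex (flat-zero or
  linear-endpoints baseline), integrated by the trapezoidal rule with no
  smoothing or deconvolution.

## Validation scale

The test suite and the acceptance script exercise the full pipeline at the
scale the science dictates: 512-540 µm fields at 1 µm/px, 20 planes at
5 µm, 2 × 2 tile mosaics with 12.5% overlap, five independent seeds for
the imaging recoveries, and 100-trace property sweeps for the assay
identities. Larger mosaics (e.g. 5 × 5 grids) change nothing
algorithmically — the registration graph and blending are
grid-size-agnostic — and the tile arithmetic is tested at that size.

## Known limitations

Integer-pixel registration only; no flat-field or illumination correction;
no deconvolution; dome detection requires domes to span at least one
z-step in height; the pixel classifier's feature set is a conventional
texture bank, not a learned representation; no mitochondrial network
topology, 3D segmentation, or cell-boundary instance segmentation; MS
support is centroided MS1 peak lists only (no profile data, MS2, or
isotope-pattern scoring).
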