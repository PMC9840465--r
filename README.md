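# domescope

Quantitative imaging and metabolic-assay analysis for renal epithelial
monolayers.

Differentiated proximal-tubule cells grown on an impermeable dish pump
solutes (and, osmotically, water) from their apical to their basolateral
side. With nowhere for the fluid to go, the monolayer lifts off the plastic
in blisters called **domes**; the total dome area of a well is a direct,
label-free readout of active transepithelial transport. `domescope`
implements the image-analysis pipeline that turns tiled z-stacks of such
monolayers into that readout, together with the companion measurements used
to characterize nephrotoxic injury: mitochondrial morphology, autophagosome
counts, Mito Stress Test respiration parameters, qPCR relative abundance,
ATP-per-protein, glutathione redox ratio, biopsy immunofluorescence
Z-scores, and targeted metabolite quantification from MS1 peak lists.

It is intended for cell biologists and image-analysis engineers building
high-throughput toxicity screens on epithelial cultures, and every stage is
validated against a built-in synthetic-scene generator with exact ground
truth, so the pipeline can be tested end to end without any microscope.

## What the pipeline computes

1. **Extended depth of field (EDF).** Each field is acquired as a z-stack
   (20-50 planes, 5 µm apart). For every pixel, the plane with the highest
   local focus score (local intensity variance in a 7x7 window by default,
   Tenengrad optional) is selected:

       height(p) = argmax_k F(I_k)(p),   composite(p) = I_height(p)(p)

   yielding a single all-in-focus composite plus a *topography height-map*
   of in-focus plane indices. Dome cells sit above the plate, so domes
   appear as plateaus in the height-map.
2. **Stitching.** Tiled fields are registered by normalized phase
   correlation on their overlap strips and blended into a whole-well mosaic
   (linear feathering for intensities; strict nearest-tile assignment for
   height-maps, whose plane indices are categorical).
3. **Quantification.** Nuclei are counted by Gaussian smoothing, Otsu
   thresholding and distance-transform watershed; dome area is the total
   area of height-map components elevated above the modal (plate) plane;
   mitochondria are segmented by threshold or by a trainable random-forest
   pixel classifier, measured as a *footprint* (fraction of field area) and
   classed regular/enlarged by an area cutoff; large autophagosome puncta
   are counted above an intensity quantile.
4. **Assays.** Mito Stress Test traces are partitioned into non-mitochondrial,
   basal, ATP-linked, proton-leak, maximal and spare respiration (the
   identities `basal = ATP-linked + leak` and `spare = maximal - basal`
   hold exactly by construction); qPCR fold changes use 2^-ddCt; metabolites
   are quantified as the trapezoidal area under the MS1 extracted-ion
   chromatogram of the deprotonated [M-H]- ion inside a 3 ppm window.

## Worked example

Simulate one field with a single dome (radius 50 µm, apex 40 µm) and 30
nuclei, image it through the defocus model, and recover both measurements:

```r
library(domescope)

p <- scene_pars(field_size_um = 256, n_planes = 10, n_nuclei = 30,
                dome_specs = list(list(center = c(128, 128), radius_um = 50,
                                       apex_height_um = 40)), seed = 1)
sc    <- generate_scene(p)
stack <- render_zstack(sc$ideal$brightfield, sc$surface, p)
cr    <- edf_compose(stack)
d     <- segment_domes(height_to_um(cr$height_map, p$z_step_um),
                       pixel_size_um = 1, min_height_um = 2.5)
d$total_dome_area_um2              # 7350
sc$truth$true_total_dome_area_um2  # 7854 (pi * 50^2): recovered within 7%

nz <- render_zstack(sc$ideal$nuclear, sc$surface, p, channel = "nuclear")
count_nuclei(edf_compose(nz)$composite, pixel_size_um = 1)$count  # 30
```

The measured dome area (7350 µm²) sits 6.4% below the analytic disc area
because the spherical-cap rim tapers below the height-quantization floor of
half a z-step — see the methods vignette for the error model. A Mito Stress
trace reduces the same way:

```r
tr <- data.frame(time_min = 1:4, ocr = c(100, 40, 160, 10),
                 phase = c("basal", "post_oligomycin", "post_fccp",
                           "post_rot_aa"))
mito_stress_params(tr)
# non_mito 10, basal_resp 90, atp_linked 60, proton_leak 30,
# maximal 150, spare 60, spare_pct 166.7
```

A thin command-line wrapper over these functions lives at
`inst/scripts/domescope.R` (subcommands `run`, `simulate`, `mzquant`,
`assay`).

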