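# speckleflow

Laser speckle contrast imaging (LSCI) is a dye-free, non-contact technique
for visualizing tissue perfusion: coherent laser light scattered by tissue
forms a speckle pattern on the camera, and moving red blood cells blur that
pattern within the exposure. The blur is quantified by the spatial speckle
contrast

```
K = sigma / <I>
```

the ratio of the standard deviation to the mean intensity within a sliding
window (7 × 7 pixels by default). Low contrast means high flow. Contrast is
converted to laser speckle perfusion units (LSPU = 1/K², arbitrary units,
higher = better perfused), masked where the sensor is underexposed, and
rendered as a Viridis false-color map next to the white-light view — the
display convention used by laparoscopic perfusion imagers during intestinal
anastomosis surgery, where intraoperative detection of poorly perfused bowel
is the clinical goal.

`speckleflow` implements this full processing chain in R, together with a
physics-based dynamic speckle simulator. The simulator evolves a
band-limited circular-Gaussian speckle field with a per-pixel decorrelation
time τc (short τc = fast flow), integrates it over a finite exposure
(default 20 ms at 20 frames/s) and applies a sensor model, so every
downstream stage can be validated against known ground truth:

- the contrast of a simulated scene with uniform τc follows the closed form
  `K(T, τc) = sqrt(β [τc/T + τc²/(2T²)(e^(−2T/τc) − 1)])`,
- τc can be recovered by inverting that relation (`estimate_tau_c()`),
- a three-tier phantom (well / marginally / poorly perfused bands) is
  recovered pixel-by-pixel by the end-to-end pipeline.

## Worked example

```r
library(speckleflow)

# simulate a three-band intestinal segment: tau_c = 1 / 5 / 50 ms
scene   <- default_scene(seed = 5)
phantom <- make_phantom(scene)
stack   <- generate_dynamic_stack(phantom,
                                  acquisition_params(n_frames = 16),
                                  noise_params(seed = 2))
#> Warning: exposure sub-step (1.25 ms) exceeds tau_c/4 for the fastest
#> pixels (min tau_c 1 ms); ... Increase n_subframes for closer agreement
#> with the closed form.
stack
#> <speckle_stack> 16 frame(s) of 192 x 192 px at 20 fps, exposure 20 ms, 16-bit

res <- run_pipeline(pipeline_config(), stack, out_dir = "maps")
res$labels
#> <label_map> 192 x 192 px (thresholds 18% / 55%)
#>    well=11192, marginal=11895, poor=11509, invalid=2268
res$relative
#> <relative_perfusion_map> 192 x 192 px, reference 21.77 LSPU
#>   percent (valid): median 32.4%, range [7.2%, 125.4%]
length(res$contours)
#> [1] 2
```

(The warning is deliberate: the fastest tier of the default scene is
integrated coarsely at the default 16 sub-frames per exposure, which is
fine for classification; raise `n_subframes` when quantitative agreement
with the closed form matters.)

The three tissue tiers are recovered in roughly equal thirds of the frame
(the 2268 invalid pixels are the 3-pixel contrast border rim), the
reference value is the 95th percentile of LSPU over the well perfused band,
and the two demarcation contours trace the ground-truth band boundaries.
`maps/` receives the LSPU and relative-perfusion TIFFs, the label and
false-color PNGs, the side-by-side composite, the contour JSON and a
summary JSON echoing the full configuration.

A thin command-line wrapper with `simulate`, `process`, `visualize` and
`pipeline` subcommands is provided at `inst/cli/speckleflow.R`.

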