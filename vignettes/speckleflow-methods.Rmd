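---
title: "Speckle contrast perfusion imaging: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle contrast perfusion imaging: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleflow)
```

## The measurement model

Laser speckle contrast imaging infers perfusion from the blurring of a
laser speckle pattern during a camera exposure. The primary statistic is
the spatial speckle contrast, computed per pixel over a sliding square
window:

$$K = \frac{\sigma}{\langle I \rangle},$$

with $\sigma$ the *population* standard deviation (divide by $n$, not
$n-1$) and $\langle I \rangle$ the mean of the $7\times7$ neighborhood.
The population convention matters for exact hand-checks (for the window
$1\ldots9$, $K = \sqrt{60/9}/5 \approx 0.5164$); at $n = 49$ the two
flavors differ by under 2%. The window size, exposure time (20 ms) and
frame rate (20 fps) defaults match the laparoscopic acquisition this
package emulates.

`spatial_contrast()` uses running box sums (integral images), which the
test suite requires to agree with an explicit per-window loop to
$10^{-8}$ relative error. Edges are handled by symmetric reflection so
the output keeps the input's size for display; the affected rim — half a
window on each side — is flagged in `border_mask` and treated as invalid
downstream. A `"valid"` mode that crops instead is available. Windows
with zero mean (fully dark) would be $0/0$; they are defined as $K = 0$
and flagged invalid, which is consistent because such pixels are
underexposed and masked anyway.

Perfusion is reported in laser speckle perfusion units. The literature
agrees only that LSPU is inversely related to $K$; this package fixes

$$\mathrm{LSPU} = 1/K^2,$$

which is proportional to flow under the Lorentzian decorrelation model in
the strong-blur regime ($T \gg \tau_c$, where $1/K^2 \approx
2T/\tau_c$), with `form = "k1"` available for the plain reciprocal. Near
$K = 0$ the reciprocal diverges, so values saturate at `lspu_cap`
(default $10^4$) rather than returning infinities. This is an explicit
software convention, not a claim about any commercial device's internal
scaling.

## The simulator

No public raw-speckle acquisition accompanies the clinical setting this
package addresses, so all validation runs on synthetic data with known
ground truth. The simulator is deliberately the simplest physically
grounded model that admits a closed-form oracle:

1. **Static speckle.** A circular complex Gaussian random field is drawn
   in the spatial-frequency domain, band-limited by a circular aperture,
   and squared in magnitude. The aperture radius is mapped analytically
   to the speckle grain size, defined as the FWHM of the intensity
   autocovariance: for aperture radius $\rho_0$ cycles/pixel the field
   correlation is $2J_1(x)/x$ with $x = 2\pi\rho_0 r$, giving
   $\mathrm{FWHM} = x_{1/2}/(\pi \rho_0)$ where $x_{1/2} \approx 1.616$
   solves $|2J_1(x)/x|^2 = 1/2$. `estimate_speckle_size()` inverts this
   definition empirically (FFT autocovariance, sub-pixel interpolated
   FWHM) and round-trips the requested size within 25%.
2. **Dynamics.** The field evolves by a first-order autoregressive update
   with per-pixel correlation $\rho = \exp(-\Delta t/\tau_c)$, i.e. a
   Lorentzian field correlation $g_1(t) = e^{-t/\tau_c}$. Innovations are
   fresh band-limited fields, so the spatial statistics are stationary.
3. **Exposure integration.** Each output frame averages `n_subframes`
   (default 16) instantaneous intensities across the exposure, then
   advances across the inter-frame dead time in one autoregressive step.
   The discrete sum integrates $\tau_c \ll \Delta t_{sub}$ coarsely; the
   generator warns (but proceeds) when $\Delta t_{sub} > \tau_c/4$.
4. **Sensor.** Illumination falloff (quadratic radial vignette reaching
   $1 - {falloff}$ at the corners), optional Poisson shot noise at unit
   gain, Gaussian read noise, dark offset, clipping and quantization to
   8/12/16 bits. Simulation is floating point throughout; quantization
   happens once, at the end.

Under this model the finite-exposure contrast has the closed form

$$K(T, \tau_c) = \sqrt{\beta\left[\frac{\tau_c}{T} +
  \frac{\tau_c^2}{2T^2}\left(e^{-2T/\tau_c} - 1\right)\right]},$$

implemented in `theoretical_contrast()` (with a series expansion for
$T/\tau_c < 10^{-4}$ to avoid cancellation) and verified in the tests
against direct numerical integration of
$K^2 = \beta\,(2/T^2)\int_0^T (T-t)\,|g_1(t)|^2\,dt$.
`estimate_tau_c()` inverts it by bracketed root finding on
$[10^{-6}T, 10^6 T]$ at $10^{-9}$ relative tolerance; contrasts at or
above $\sqrt\beta$ have no finite solution and are rejected.

**Coherence calibration.** The requested $\beta$ (partial coherence,
modelled by mixing speckle intensity with a uniform background so the
static contrast is $\sqrt\beta$) is an upper bound: the windowed
estimator itself depresses measured contrast slightly because a $7\times
7$ window spans only a dozen independent grains at the default 2-px
speckle size. `calibrate_beta()` measures the attained asymptote once by
simulating static speckle and applying the same windowed estimator, and
that `beta_effective` ($\approx 0.84$ at size 2, window 7) is what the
closed-form comparisons and $\tau_c$ inversions use. Because calibration
and measurement share the estimator, the window bias cancels in the
ratio; simulated contrast then tracks the closed form within a few
percent over $T/\tau_c \in [0.1, 10]$, and $\tau_c$ recovery stays
within 20% over $T/\tau_c \in [0.5, 5]$.

## Clinical-display conventions

- **Underexposure mask**: a pixel is invalid when its window-mean
  intensity is below 2% of full scale (configurable). Invalid pixels are
  rendered exact black, labelled `invalid`, and excluded from every
  statistic — the mask-conservation contract checked by the tests.
- **Relative perfusion**: following the idea that an ischemia threshold
  should be expressed as a percentage of the maximum perfusion in
  healthy tissue, `relative_perfusion()` normalizes LSPU by a reference
  ROI statistic. The default statistic is the 95th percentile rather
  than the literal maximum, which under $1/K^2$ is dominated by the
  noisiest window in the ROI. With no ROI configured the pipeline uses
  the whole frame, so the reference reads off the best-perfused tissue
  in view.
- **Classification thresholds**: tissue is labelled well ($\ge$ 55% of
  reference), marginal (18–55%) or poor (< 18%). These defaults are
  derived from the package's own model: under the discrete exposure
  integration at 16 sub-frames, the default phantom tiers ($\tau_c$ =
  1/5/50 ms at $T$ = 20 ms) land at roughly 91% / 32% / 10% of the p95
  reference, and 18/55 are the log-midpoints between adjacent tiers —
  placed for symmetric noise margins, and robust to finer integration
  (which moves the tiers to about 90% / 22% / 6%). They are a software
  convention for separating the simulator's tiers, **not** clinically
  validated ischemia cut-offs, and are configurable everywhere they
  appear.
- **Demarcation lines** are traced on the label grid, not on raw LSPU,
  so the displayed contours coincide exactly with the announced classes.
  Every edge between 4-adjacent pixels with differing valid labels
  contributes a unit segment on the half-pixel grid; segments are
  chained into polylines (open paths first, then closed loops). Contours
  therefore never cross invalid tissue.
- **Rendering**: Viridis false color with per-frame percentile (1–99%)
  scaling by default, mimicking high-contrast clinical maps; fixed
  scaling is available for cross-frame comparability. Side-by-side
  composition places white light left, perfusion right, separated by a
  2-px divider, resampling the perfusion view if heights differ.

## What the phantom does and does not show

`default_scene()` — three equal vertical bands at $\tau_c$ = 1, 5, 50 ms,
speckle size 2 px, $\beta = 0.8$, 30% corner vignette, 16 frames with
shot + read noise at 10,000 mean counts — is the package's stock test
scene; the preset $\tau_c$ values are chosen to straddle the 20 ms
exposure and produce visually distinct LSPU tiers, and are not claimed to
match in vivo bowel (no public $\tau_c$, wavelength or $\beta$ values
exist for that setting). On this phantom the full pipeline reaches 100%
label accuracy on valid pixels more than 5 px from a band boundary, and
mean demarcation-to-truth distance under 1 px (see
`scripts/acceptance.R`).

Passing these tests shows the chain is *internally consistent* with its
own physics model. Real laparoscopic data differ in ways the simulator
does not attempt: multiple scattering and depth-dependent $\tau_c$,
non-Lorentzian velocity distributions, static scatterer fractions,
specular reflections, motion of the laparoscope itself, and spatially
varying coherence. Threshold values and the LSPU convention in
particular must be recalibrated against outcome data before any clinical
interpretation.

## Numerical and design notes

- All problem sizes in the test-suite are chosen for desk-scale runs:
  calibration frames 256², closed-form comparisons 128² with 2 frames,
  end-to-end phantom 192² with 16 frames.
- Coordinates are 0-based `(row, col)`; rectangles half-open — pixel
  counts of rasterized regions then match analytic areas exactly
  (ellipses to a one-pixel boundary band).
- The simulator is deterministic given its seeds: the scene seed drives
  the field evolution, the noise seed (offset per frame) drives the
  sensor model, and the two streams are kept separate so disabling noise
  does not change the clean frames.
- Stacks are written as 16-bit multi-page TIFF with a JSON sidecar
  (exposure, frame rate, bit depth, provenance); integer data round-trip
  losslessly at any supported bit depth. Float maps are written as
  32-bit float TIFF normalized by a sidecar-recorded scale (float TIFF
  storage covers $[0,1]$), exact to float32 precision.
- A reference-ROI must contain at least 25 valid pixels; degenerate
  requests (zero-variance frames for speckle-size estimation, contrasts
  $\ge \sqrt\beta$ for inversion, threshold misordering) fail fast with
  descriptive errors rather than propagating NaNs.
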