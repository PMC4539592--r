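---
title: "Spectral GP imaging: models, defaults and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral GP imaging: models, defaults and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralGP)
```

## The measurement

Polarity-sensitive membrane probes report lipid packing through a spectral
shift: in a tightly packed (liquid-ordered, Lo) bilayer little water
reaches the probe and emission stays blue; in a loosely packed
(liquid-disordered, Ld) bilayer dipolar relaxation of penetrating water
red-shifts it. The generalized polarization condenses this into

$$\mathrm{GP} = \frac{I_B - I_R}{I_B + I_R} \in [-1, 1],$$

with $I_B$ read at $\lambda_{Lo}$ (the probe's emission maximum in a
reference ordered membrane) and $I_R$ at $\lambda_{Ld}$ (disordered
reference). Built-in presets: C-Laurdan 440/490 nm and Di-4-ANEPPDHQ
565/605 nm. GP is a *relative* index — it changes with the probe, the
wavelength pair and the analysis method, so comparisons are only valid
within one consistent setup. For parity with the classic 8-bit (ImageJ
plug-in style) implementations, $I_B$ and $I_R$ are divided by 255 before
the ratio; the
normalization cancels algebraically and the package keeps it purely as a
documented convention.

A lambda-mode confocal detector records the emission spectrum of every
pixel across uniform wavelength windows — typically 32 channels of 8.9 nm
starting at 415 nm, covering 415–700 nm. Each stack slice is treated as
the intensity at its channel's central wavelength
(`start + width·(k − 1/2)`); the blue tail of the spectrum below the
detector cut-off is not recorded, which biases all GP values identically
and therefore cancels in within-study comparisons.

## Pipeline

`compute_gp_map()` runs, in order:

1. **Sensitivity correction** (optional): per-channel positive multipliers
   for detectors without factory-normalized channels. A uniform correction
   cancels in the GP ratio, which the tests assert.
2. **Z-projection**: pixelwise sum over channels.
3. **8-bit rescale**: the projection is mapped linearly min→0, max→255 and
   rounded, so the mask threshold always lives on a 0–255 scale regardless
   of detector bit depth. Whether the original workflow min–max rescales or
   bit-truncates is not observable from its description; linear min–max is
   this package's documented convention. A constant projection maps to all
   zeros, so nothing passes a positive threshold — fail-safe for blank
   frames.
4. **Mask**: pixels strictly above the threshold (default 15) are
   analyzed. Everything else is "dark area".
5. **Background subtraction** (default on): each channel's background is
   the mean of its dark-area pixels (median available for heavy-tailed
   backgrounds), subtracted inside the mask and clipped at zero. Using the
   full mask complement rather than a hand-drawn dark region is
   deterministic, user-free and maximizes the sample size. Clipping keeps
   the data in the nonnegative model space.
6. **Readout** per masked pixel: direct channel sampling (nearest channel
   center to each preset wavelength, ties to the lower wavelength — an
   arbitrary but fixed convention) or whole-spectrum fitting followed by
   continuous evaluation of the fitted curve at the preset wavelengths.
7. **R² filter** (fitting only): a pixel enters the GP map when
   `r_squared >= r2_tolerance` (default 0.8). The inclusive inequality
   means a perfect fit always passes even at tolerance 1.0. Failed fits
   and filtered pixels are counted separately and become NaN.

Excluded pixels are always NaN — never 0, which is a legal GP value.

## Line-shape models

**Gaussian (no offset)**: $I(\lambda) = A e^{-(\lambda-\mu)^2/2\sigma^2}$.
No additive offset term — the background is removed in preprocessing, and
an offset would trade off against the tails of the 3-parameter model.

**Gamma Variate**:
$$I(\lambda) = A\left(\frac{\lambda-\lambda_0}{\alpha\beta}\right)^{\alpha}
e^{\alpha - (\lambda-\lambda_0)/\beta},\qquad \lambda > \lambda_0,$$
zero otherwise: the standard gamma-variate bolus form, peak-normalized so
that the maximum is exactly $A$ at $\lambda_0 + \alpha\beta$. The
peak-normalization decouples amplitude from shape, which stabilizes the
optimization. Small $\alpha$ gives the right-skewed line shapes typical of
ordered-phase spectra; as $\alpha \to \infty$ the curve converges to a
Gaussian with $\sigma = \sqrt{\alpha}\,\beta$, so symmetric spectra are in
the model family's closure. The onset is constrained blue of the detection
window ($\lambda_0 \le$ first channel center − 1 nm, enforced through a
smooth penalty residual): physically, the emission onset lies below the
recorded range.

### Fitting

Per-pixel fits use bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`, up to 200 iterations, cost tolerance $10^{-10}$)
with uniform weights (no per-channel variance model is assumed), started
from moment-based guesses: amplitude = maximum intensity, peak =
intensity-weighted mean wavelength, width = intensity-weighted SD floored
at half a channel width; gamma shape and scale by matching those moments to
a gamma density with shape $\alpha+1$, scale $\beta$.

Two numerical choices matter:

* **Internal coordinates.** The gamma variate is optimized in
  (amplitude, peak $m=\lambda_0+\alpha\beta$, width
  $s=\sqrt{\alpha}\beta$, skew $q = 1/\sqrt{\alpha}$), not in
  $(\lambda_0, \alpha, \beta)$. Near-symmetric spectra drive the raw
  parameters along a curved ridge ($\lambda_0 \to -\infty$,
  $\alpha \to \infty$) on which the optimizer stalls far from the optimum
  (measured: GP errors of order $10^{-2}$); in $(m, s, q)$ the Gaussian
  limit $q \to 0$ is a smooth interior direction and the same fits reach
  GP errors below $10^{-6}$ in a handful of iterations. Results are
  reported in the conventional $(A, \lambda_0, \alpha, \beta)$
  parametrization.
* **Deterministic restarts.** If the first attempt fails to converge or
  lands on a grossly wrong optimum ($R^2 < 0.2$), a fixed set of perturbed
  starts is tried (width halved/doubled, peak shifted by one channel) and
  the best convergent result kept. No random numbers are used anywhere in
  fitting, so GP maps are bitwise reproducible without seed bookkeeping.

Failures are recorded (`converged = FALSE`, counted per map), never
raised: one bad pixel must not abort a many-thousand-pixel map. The $R^2$
score is computed on the channel-center predictions — the same points that
were fit.

Continuous evaluation of the fitted curve at $\lambda_{Lo}/\lambda_{Ld}$
is exact (no wavelength grid), which meets and exceeds a 1 nm-grid
inference convention; tests cross-check it against a 0.01 nm brute-force
grid oracle.

## Synthetic scenes: what they emulate, and what not

`make_two_phase_vesicle()` + `render_stack()` emulate the equatorial-plane
image of a giant vesicle: a one-pixel-sharp ring of thickness 6 px (radius
30 % of a 128 px image) over a flat background, split into equal angular
sectors each carrying one closed-form spectrum. Defaults — the package's
reference conditions — are Gaussian spectra peaked at 440 nm (Lo sector)
and 490 nm (Ld sector) with $\sigma$ = 25 nm, matching the observed
C-Laurdan spectral positions in ordered and disordered membranes; peak
amplitude 400 counts (peak SNR 20 under Poisson noise, a realistic
good-quality confocal signal); background 5 counts/channel. Shot noise is
Poisson per channel; additive Gaussian read noise is available, clipped at
zero. The analytic GP of each sector,
`gp_value(I(λ_Lo), I(λ_Ld))` on the continuous model, is the ground truth
every end-to-end test compares against. For the *direct* readout the
matching oracle evaluates the model at the nearest channel *centers*
(437.25 / 490.65 nm on the default axis): direct sampling reads channels,
and its GP carries a systematic channel-discretization offset (≈ +0.01 at
a 440 nm peak) that is intrinsic to the method — precisely the limitation
whole-spectrum fitting removes.

Deliberately not modeled: optics (no PSF blur — ring pixels are pure
single-phase spectra, no edge mixing), photobleaching, detector
afterpulsing, 3-D geometry, polarization photoselection, spatially varying
background. Passing tests therefore demonstrate correctness of the
*computation* under known spectra and shot noise; they do not certify
performance on real images with partial-volume pixels or structured
background.

## Defaults and units

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| axis | 415:8.9:32 | nm | 32-channel lambda detector covering 415–700 nm |
| preset | C-Laurdan 440/490 | nm | published Lo/Ld reference maxima |
| mask_threshold | 15 | 8-bit counts | excludes shot-noise background after min–max rescale |
| background_subtraction | on | — | per-channel dark-area mean |
| r2_tolerance | 0.8 | — | permissive enough for SNR ≈ 10 fits, excludes garbage |
| bin_width | 0.02 | GP | ≥ 15 bins across a 0.3 GP phase separation |
| max_iterations | 200 | — | per-pixel fit cap |

The Di-4-ANEPPDHQ preset is 565/605 nm ($\lambda_{Lo}/\lambda_{Ld}$),
following the emission maxima observed in ordered (565 nm) and disordered
(610 nm) reference membranes; published wavelength choices for this probe
vary, and with spectral detection any pair can be set via a custom preset.

## File formats

Input stacks are multi-page grayscale TIFF / OME-TIFF, one page per
channel in ascending wavelength; integer data are used as recorded (no
rescaling), and an explicit `wavelength_axis()` always overrides file
metadata (an OME `EmissionWavelength` grid is read when no axis is given;
mismatches are errors, never silently resolved). Negative intensities are
clipped to zero with a warning (detector offset artifacts). GP and R²
images are written as 32-bit float TIFF with NaN marking excluded pixels;
the writer emits plain uncompressed little-endian float TIFF (installed R
TIFF writers only store 32-bit data as [0,1]-scaled integers, which cannot
represent NaN or values outside [0,1]). Values round-trip bit-exactly at
single precision. The color rendering uses a fixed diverging blue→red HCL
palette over GP ∈ [−1, 1] (blue = disordered, red = ordered); the palette
is a display convention only.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run entirely on synthetic
scenes: 128 × 128 reference scenes (~1450 ring pixels) for end-to-end
recovery, de-noising and determinism checks; 64 × 64 single-phase scenes
(~740 ring pixels) for the model-comparison statistics; 300-replicate
Monte-Carlo for fit-bias checks. These sizes give sub-percent standard
errors on every reported mean while keeping a full run around a minute.

## Known limitations

* Single 2-D plane per analysis; no time series or z-stacks.
* One spectral peak per pixel: mixed-phase pixels (partial volume) are fit
  with a single line shape and land between the phase GP values.
* The per-channel scalar background model cannot represent structured
  (spatially varying) background.
* Proprietary microscope containers (.lsm) are out of scope; export to
  TIFF/OME-TIFF first.
* Direct-sampling GP inherits a channel-discretization offset set by the
  axis; use a fitting method when absolute spectral positions matter.
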