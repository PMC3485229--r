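---
title: "Bolus-kinetic CBF mapping: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bolus-kinetic CBF mapping: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbfmap)
```

## The measurement problem

After a rapid intravenous injection, an intravascular near-infrared dye
(indocyanine green bound to serum albumin) passes through the cerebral
circulation and produces, in every pixel of an overhead fluorescence
camera, a transient time–intensity curve: a first-pass peak followed by
smaller, broader peaks from systemic recirculation, superimposed on a dark
baseline. The timing and slope of the first pass differ systematically
between tissues — cortex peaks earliest, the large draining vein later,
extracranial muscle last and with a weak first pass — so per-pixel curve
descriptors separate the brain from surrounding tissue and report relative
cerebral blood flow without any absolute calibration.

`cbfmap` reduces each pixel's curve to four descriptors:

| parameter | definition | units |
|---|---|---|
| `t_arrival` | time the bolus first appears (foot of the first rise) | s |
| `t_rising` | `t_peak - t_arrival`, duration of the first-pass rise | s |
| `mtt` | centre of gravity of the baseline-zeroed curve over a fixed post-arrival window | s |
| `bfi` | `(i_peak - i_arrival) / t_rising`, slope of the first peak | a.u./s |

All four are *relative* quantities. No arterial input function is
deconvolved (a projected 2D image has no uncontaminated arterial pixel),
so none of them is a flow in mL/100 g/min; they support comparisons
between regions, hemispheres and conditions within the same acquisition
setup.

## The per-pixel algorithm

1. **Analysis window.** Only the initial frames covering the first pass
   and early recirculation are used (default 40 frames at 0.58 s/frame,
   23.2 s). Later frames add clearance-dominated signal that carries no
   first-pass information.
2. **Smoothing.** Savitzky–Golay with third-order polynomials (default
   window 7 frames). Each output sample is the local least-squares cubic
   evaluated at the window centre; near the trace ends the window shrinks
   symmetrically, and where fewer than `order + 2` points remain the
   nearest `order + 2` points are used. Shrinking avoids padding
   artefacts in exactly the frames where the bolus arrives.
3. **Interpolation.** Natural cubic spline, resampled to 11.6 ms
   (1/50 of the frame interval). The natural boundary condition (zero
   second derivative) is used because no derivative information exists at
   the window ends.
4. **Anchoring.** `t_half` is the first time the processed curve reaches
   its median over the window. The median of an even-length window is the
   mean of the two central order statistics.
5. **Tracing.** From `t_half` the curve is walked backward while each
   earlier sample is strictly lower — the last point reached is
   (`t_arrival`, `i_arrival`) — and forward while each later sample is
   strictly higher, giving the *first* peak (`t_peak`, `i_peak`).
   Plateaus terminate the walk. The global maximum (`t_max`, `i_max`) is
   recorded separately; over muscle it belongs to a recirculation peak,
   not the first pass.
6. **Baseline and MTT.** The baseline is the mean intensity before
   `t_arrival` (minimum of the trace as a fallback when fewer than three
   pre-arrival samples exist). MTT is the centroid
   `integral(tau I(t_arrival + tau)) / integral(I(tau + t_arrival))` over
   `tau` in `[0, 20 s]` by trapezoidal quadrature, with `tau` measured
   *since arrival*: the arrival-relative reading makes MTT invariant to
   injection-time variation, which is the property that makes
   inter-acquisition comparison meaningful. When the acquisition ends
   earlier than 20 s after arrival the window is clipped with a warning
   rather than failing — a 40-frame acquisition barely covers a late
   arrival — and the clipped length is part of the estimand.
7. **BFI.** Computed from the interpolated-grid `i_peak`/`i_arrival`;
   the baseline cancels in the difference.

Any stage failure (flat trace, truncated peak, non-positive curve mass,
zero rise) produces an invalid record with a reason code; a map
computation never aborts on a single pixel.

## Quality control

A pixel enters the maps only if its smoothed amplitude (maximum minus the
pre-peak baseline) is at least `qc_snr_threshold` (default 5) times a
robust noise scale: 1.4826 × the median absolute deviation of
raw-minus-smoothed residuals over the pre-peak frames, excluding the
smoother's half-width just before the peak. That exclusion matters: on
the steep bolus onset the least-squares fit is biased, and treating the
bias as noise would reject noiseless high-amplitude boluses. QC is a
statistical test — isolated noise pixels slip through at roughly the 1%
level and either fail the kinetic analysis or appear as speckle that ROI
averaging removes; the mask never admits systematic background areas.

## The synthetic phantom

The generator exists so that every stage is testable against known ground
truth without animal data. The first pass is a peak-normalized
gamma-variate `A ((t-t0)/(ab))^a exp(a - (t-t0)/b)` (peak `A` at
`t0 + ab`), recirculation is a sum of delayed, dispersion-widened
gamma-variates, and an exponential clearance term damps the tail;
Gaussian camera noise is added and the result is quantized to 12-bit
digital numbers. The default 64 × 64 scene holds two hemisphere
ellipses, a midline vein strip, a posterior muscle band and signal-free
background. Preset kinetics are plausibility-chosen: cortical onset near
4 s with a ≈2.7 s rise, the vein slightly later and brighter, muscle
weak with dominant recirculation, and an "ischemic" hemisphere delayed
by 2.9 s (five frames, so that pure-delay comparisons stay on the frame
grid) with a slower, weaker first pass and stronger delayed collateral
recirculation. Ground truth is analytic: arrival is `t0`, the rising
time is `ab / (1 + c b)` (the clearance-damped peak location; `ab` when
clearance `c = 0`), BFI is the closed-form damped peak height over that
rise, and MTT is a fine-quadrature centroid of the noiseless model over
the same effective window the analyzer can integrate.

What the phantom does **not** emulate: scalp/skull optics and
depth-dependent signal mixing, motion, photobleaching, spatially
correlated noise, or within-region heterogeneity (regions are kinetically
uniform by default). Passing recovery tests therefore demonstrates
correctness of the computation, not robustness to every property of
in-vivo data.

## Known limitation: arrival-tracing bias at coarse frame intervals

The backward trace stops at the first local minimum of the *processed*
curve before the rise. Two processing steps place that minimum early:
the Savitzky–Golay kernel has negative side lobes, so a flat baseline
followed by a bolus produces a pre-onset undershoot whose minimum sits
roughly half a frame to one frame before the true onset; and the cubic
spline of 0.58 s samples undershoots similarly even without smoothing.
The acceptance suite quantifies the effect on the noiseless phantom:
about half a second of early arrival at the default window, inflating
`t_rising` by the same amount and biasing BFI down and MTT up by several
percent. The bias is a *common-mode* property of curve shape and
sampling: differences of arrival between identically shaped regions
cancel it exactly (the phantom's 2.9 s inter-hemisphere delay is
recovered to within one interpolated step), and all hemisphere *orderings*
under ischemia are preserved. Absolute single-pixel timing at the 0.05 s
level would require a finer native frame interval, not a different
implementation of the tracing rule.

## Numerical and interface choices

* Frame `k` (1-based) is at `t = (k-1) * frame_interval`; `t = 0` is the
  first acquired frame. Coordinates are `(row, col)`, row 1 at the image
  top, matching TIFF order.
* ROI convention: the animal is prone, viewed dorsally, anterior at the
  image top; posterior offsets increase rows, left-lateral offsets
  decrease columns. A 2 mm ROI at 0.1 mm/px is exactly 20 px; half-pixel
  centres round away from bregma so the footprint never shrinks.
* Masked pixels are `NA` in float maps and sentinel gray 0 in display
  PNGs (with the QC mask exported alongside); display ranges default to
  the 1st–99th percentile of valid pixels so isolated hot pixels cannot
  crush contrast. BFI is max-normalized for display only, never for
  analysis.
* Group comparisons use the classical pooled-variance two-tailed t-test
  (Welch behind a flag) and the paired t-test for hemisphere contrasts,
  with explicit conventions for degenerate inputs (identical constant
  groups give p = 1; constant nonzero paired differences give p = 0 with
  a degeneracy flag). No multiple-testing correction is applied: the
  analysis makes at most four planned comparisons.
* Problem sizes in the test and acceptance suites (64 × 64 × 40 phantom,
  500 noisy traces, 200-sample oracle comparisons) were chosen as the
  smallest sizes at which every region and failure mode is exercised;
  a full 64 × 64 map computes in a few seconds.

## Reproducing the numbers

```{r, eval = FALSE}
spec <- phantom_spec(preset = "ischemic", seed = 7)
ph <- generate_phantom(spec)
maps <- compute_maps(ph$stack)
roi <- make_roi(c(2, 2), c(2, 2), pixel_size = spec$pixel_size,
                bregma_px = spec$bregma_px, shape = dim(maps$qc))
rbind(roi_mean_params(maps, roi, "ipsilateral"),
      roi_mean_params(maps, mirror_roi(roi, spec$midline_col), "contralateral"))
```

`scripts/acceptance.R` recomputes every headline quantity (processing
constants, oracle agreements, analytic worked examples, phantom recovery
errors and the ischemia orderings) from scratch and writes them as JSON.
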