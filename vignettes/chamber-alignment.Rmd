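---
title: "Fiducial-mark detection and closed-loop chamber realignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiducial-mark detection and closed-loop chamber realignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markalign)
```

## The problem

Long-term time-lapse monitoring of a multichamber microfluidic device
(here a 4 × 8 array of culture chambers) requires the motorized xy stage
to revisit each chamber thousands of times. Preset chamber-to-chamber
distances are never exact, the device creeps on its mount (tubing pull,
vibration, thermal relaxation), and the errors accumulate: after a few
serpentine scans an uncorrected field of view can be off by tens of
micrometers. The remedy is a micropatterned fiducial next to each
chamber — three equal circles forming a right-angle triangle — detected
in every captured frame; the measured displacement of the mark from its
target position drives a corrective stage move, repeated until the
position error `E` (the Euclidean pixel distance between detected and
target mark position) drops below a tolerance of 3 px (~3 µm at the
0.94 µm/px camera scale).

`markalign` implements the full image pipeline, a virtual stage, a
synthetic renderer with exact ground truth, and the experiment drivers,
so the whole closed loop can be exercised and characterized without a
microscope.

## The detection pipeline

1. **Gray conversion** — plain channel mean `(R + G + B)/3`, kept
   real-valued.
2. **Gaussian lowpass** (`make_gaussian_mask()`, `gaussian_filter()`) —
   the mask follows `G(i,j) = 1/(2Nπσ²)·exp(−(i²+j²)/2σ²)` with
   `N = D²`. That prefactor does not sum to one; a literal mask darkens
   the image by a constant factor, so by default weights are
   renormalized to unit sum (the literal form stays available behind
   `normalize = FALSE` for fidelity checks). Borders are replicated to
   avoid a dark frame spawning spurious edges. Defaults `D = 5`,
   `σ = 1 px`: strong enough to suppress the few-percent sensor noise,
   weak enough not to merge the concentric edges of the mark annuli.
3. **Sobel gradients** (`sobel_gradients()`) — the canonical 3 × 3 mask
   pair; magnitude uses the `|Sx| + |Sy|` approximation; the gradient
   angle is computed with the two-argument arctangent (well-defined at
   `Sx = 0`) and quantized to multiples of 45°.
4. **Non-maximum suppression** (`non_max_suppress()`) — a pixel is an
   edge iff its magnitude exceeds a global threshold *and* strictly
   exceeds both neighbors along the quantized gradient direction. Ties
   suppress: on an exactly linear ramp both candidates die, which is
   what keeps edges from doubling on plateaus. The threshold defaults to
   Otsu's method on the magnitude histogram (the field's standard
   automatic gate; a constant can be configured instead).
5. **Thinning** (`thin_edges()`) — Zhang–Suen two-subiteration thinning
   iterated to a fixed point, producing one-pixel-wide, idempotent edge
   sets.
6. **Template matching** (`make_circle_template()`,
   `match_template()`) — tri-valued circle templates of side
   `D_T = 2 r_t + 5`: a *white* (weight 1) one-pixel circle of radius
   `r_t`, optionally *gray* (weight `g = 0.5`) rings at `r_t ± 1` that
   catch rasterization round-off, and *black* excluded pixels that enter
   neither numerator nor denominator of the normalized score
   `C(x,y) = Σ S_E(x+i, y+j) I_T(i,j) / Σ I_T(i,j)`.
   Border positions where the template overhangs score 0 — a mark that
   close to the frame edge is treated as a detection failure rather than
   renormalized.
7. **Peak extraction** (`find_circle_triad()`) — three global maxima
   separated by an exclusion disc of radius `2 r_t` (large enough that
   one circle cannot yield two peaks, smaller than the 40 px circle
   spacing), deterministic tie-breaking (smallest y, then x), sub-pixel
   refinement, and a floor score below which detection fails loudly.
8. **Pose** (`assign_roles()`, `estimate_pose()`) — the corner circle
   (minimizing `x + y`) is the reference `c1`; of the other two, `c2`
   has the larger `x − y`. The orientation averages the two leg angles,
   `θ_m = [atan2(Δy₂, Δx₂) + atan2(Δy₃, Δx₃) − 90°]/2` in y-down image
   coordinates, so an unrotated mark reads exactly 0° and a mark rotated
   by α reads α. The printed single-argument arctangent form is
   undefined at vertical legs and, evaluated naively y-down, reads −90°
   for an unrotated mark; the two-argument y-down form above is the
   behaviorally fixed resolution.

### Numerical choices worth knowing

* **Circle rasterization.** The white ring is the thin 8-connected
  midpoint-style circle (28 px at r = 5), *not* the `round(d) = r`
  annulus. The thinned edge of a rendered circle has exactly the thin
  8-connected topology; a fatter rasterization inflates the score
  denominator and halves every match score.
* **Score scale and the floor.** With gray rings in the denominator,
  even a *perfect* white-ring edge scores only ~0.47 against the
  gray-boundary template, and the real pipeline's edges reach C ≈
  0.28–0.35 at true centers (noiseless included) versus ≤ 0.10 for the
  strongest speckle or microwell-edge peaks. The detection floor
  therefore defaults to 0.2 — mid-gap, more than twice the background
  ceiling. A floor at 0.3 would reject valid detections under mild
  noise.
* **Sub-pixel refinement.** Peak positions are refined by a 3 × 3
  center of mass after subtracting the window minimum (removing the
  pedestal that biases the centroid toward the window center) and
  cubing the remaining mass (sharpening the peak). Measured on rendered
  ground truth this yields ~0.2–0.8 px reference error and ≤ ~0.7°
  orientation error across ±10° rotations at 4 % intensity noise;
  plain 3 × 3 centroids err up to ~1.9 px.
* **Gray vs white templates.** The white-only template scores *higher*
  on near-exact matches (its denominator is half), so the gray template
  does not dominate pointwise: for a ring displaced 1 px along one
  axis the two scores tie exactly (half the ring slides along itself).
  The gray template wins precisely where it matters — displacements
  with a component in both axes (score 0.250 vs 0.214 for a 1-px
  diagonal round-off) — and its peak stays unique where the white-only
  map plateaus.

## The virtual stage and its stated world

`stage_state()` tracks a believed and a hidden true position that
diverge only through three modeled terms:

| term | default | meaning |
|---|---|---|
| `pitch_bias` | 0.2 % | systematic scale error of every commanded move |
| `rel_sigma` | 0.05 % | per-axis Gaussian noise proportional to the commanded distance |
| `sigma_move_um` | 0.3 µm | absolute per-axis repeatability floor |
| `drift_um` | (25, 18) µm/scan | deterministic creep (tubing pull, thermal) |

Calibration is phenomenological and fixed once: a 3 mm chamber-pitch
move errs by ~6 µm systematically plus ~2 µm stochastically — about
7 px at 0.94 µm/px, matching the observed per-move arrival error — and
the split (mostly systematic) is what makes chamber-distance updating
halve the pre-alignment error, as observed. Because both bias and noise
scale with distance, a corrective move of tens of micrometers lands
almost exactly; this is why one realignment iteration suffices in
practice, and why a purely *absolute* 7-px-per-move noise model cannot
reproduce the reported post-alignment error of ~1 px (each correction
would re-randomize E with mean ~9 px). The distance-proportional model
is therefore the package's reading of the hardware; the absolute-only
model remains the `rel_sigma = 0` special case and is tested as such.

Scans traverse the grid boustrophedon; even-numbered scans retrace the
reversed path so consecutive scans start where the previous ended.
Per-scan drift is applied in per-move increments. The drift default
dominates the stochastic walk (~9 px/scan), so the unaligned mean error
increases strictly scan over scan for essentially every seed — with a
weaker drift the random walk can transiently shrink E, which the real
device also does, but the characterization experiments target the
accumulating regime.

`realign_chamber()` implements the loop: capture, detect, stop if
E ≤ 3 px, else command the measured displacement (pixels → µm) and
repeat, at most 5 times. Corrections are translation-only: the detected
orientation is recorded for diagnostics but not compensated, since a
single-field correction of a sub-degree device rotation is below the
per-move noise. Non-convergence yields a flagged record, not an
exception — multi-day scans must survive sporadic failures. Chamber
distance updates replace the believed pitch with commanded + residual.

## The synthetic renderer, and what a green test does not establish

`render_mark_image()` draws three dark annuli (outer radius 8 px,
thickness 3 px, leg spacing 40 px) on a bright background (200 vs 60
intensity), 4× supersampled so sub-pixel ground truth is meaningful,
with optional microwell disc, background gradient, and additive
Gaussian noise; it returns the exact continuous pose. This emulates the
bright-field appearance of PDMS relief marks; polarity is configurable.

It does **not** emulate: optical point-spread blur, shading/vignetting,
debris and cells crossing the mark, defocus, or photon noise. A green
pose-recovery test therefore establishes the correctness and
self-consistency of the geometry and the pipeline's noise robustness at
the stated contrast — not detection performance on arbitrary real
micrographs, where threshold and template radius would need tuning to
the actual mark scale (the fabricated mark's radius in pixels is not
published; renderer and template share one configured radius).

`render_mixing_frames()` models liquid replacement as first-order
mixing, `I(t) = I_end + (I_start − I_end)·e^{−t/τ}`. The published
flow-rate curves map to unreported time constants, so the generator
exposes τ directly; `chamber_trace()` normalizes between plateaus
estimated from the first/last 5 % of frames (an invented but
documented anchor), and `fit_time_constant()` recovers τ by log-linear
regression on the 5–95 % band. The readout statistic is the time to
90 % replacement.

## Case definitions for the error characterization

`run_experiment()` reproduces four conditions: (1) E accumulating with
alignment disabled; (2) E immediately after realignment; (3) E on
arrival before correcting, without distance updates; (4) the same with
updates. Cases 2 and 4 come from one aligned run. Case 1 reads E from
simulator ground truth because at ~100+ px error the mark leaves the
301-px camera frame (the physical system's sensor was larger); cases
2–4 run the full imaging pipeline. The published enumeration of cases
3/4 contradicts its own discussion of which is larger; the package
follows the physics (updates reduce pre-alignment error), which the
simulation reproduces.

## Known limitations

* Rotation is measured but not corrected; marks rotated beyond ~±30°
  break the role-assignment rule (by design — such a device is
  mis-mounted).
* Detection accuracy is pixel-scale by design; no FFT matching, no
  scale- or rotation-invariant matching.
* The stage model is phenomenological; its parameters are stated
  assumptions, not measurements of any particular stage.
* TIFF I/O is not available in this environment; PNG and ASCII PGM are
  supported instead.
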