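---
title: "Dual-resolution monitoring of C. elegans motility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-resolution monitoring of C. elegans motility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormrig)
```

## The problem

Locomotion is among the best predictors of healthspan in *Caenorhabditis
elegans*: strains or treatments that damage neurons or muscle move less,
pause more, and cover less ground. Manual assays (counting thrashes in
liquid) are laborious and blunt; whole-plate cameras see every worm but at
too coarse a resolution to capture fine movement; and rigs that restrain
single worms in wells or microfluidic chips distort the very behaviour
being measured.

The approach emulated here resolves the tension with two resolutions at
once on a standard 55 mm Petri dish. A fixed **macro** view (27.31 µm/pxl)
watches the whole backlit plate and tracks every worm in software. A
**micro** view (1.09 µm/pxl) rides on a virtual Cartesian XY carriage: a
state machine picks one worm at a time, drives a laser spot (which marks
the head position in the macro image) onto it, then servoes the carriage so
the worm stays centred at high resolution while a 30 s sequence is captured
at 2 fps. The per-instant carriage corrections, in motor steps, are
themselves the measurement: their magnitudes

$$M_k = \sqrt{(x_k - x_{k-1})^2 + (y_k - y_{k-1})^2}$$

(the displacement *module*, one motor step ≈ 1.09 µm) quantify how much the
worm moved in each half-second. Per-worm module sums are compared between
strains with the two-sided Wilcoxon rank-sum test; module-value histograms
give a finer fingerprint, with the `[0,1)` step bin read as "the worm was
effectively static in that instant".

Everything in this package is simulated — trajectories, optics, lighting,
robot — so that every downstream component can be tested against exact
ground truth.

## The synthetic scene

No quantitative per-strain motion model is available for the real strains,
so the simulator uses a deliberately minimal **persistent random walk**
(`simulate_trajectories()`). Per time step `dt`:

* the heading relaxes toward a fresh uniform angle with weight
  `1 - heading_persistence`;
* with probability `pause_prob` the worm does not move;
* otherwise it advances by `speed * dt`, with `speed` drawn from a Gamma
  distribution (shape 4) whose mean is `speed_scale`;
* the dish wall reflects: worm counts never change, as in a real walled
  plate.

Three presets (`strain_presets()`) stand in for a wild-type reference, a
mild locomotor deficit and a severely uncoordinated mutant:

| preset | speed scale (µm/s) | pause prob. | persistence |
|---|---|---|---|
| `wild_type` | 150 | 0.35 | 0.90 |
| `mild_deficit` | 112.5 (−25 %) | 0.40 | 0.90 |
| `severe_unc` | 40 | 0.75 | 0.50 |

The magnitudes were chosen once, from the range of published crawl speeds
for healthy young adults on agar (roughly 100–300 µm/s) and the qualitative
description of the mutants (a subtle deficit of order 20–30 % in speed; a
severe, pause-dominated phenotype). They are stand-ins, not calibrations:
passing tests demonstrate that the *pipeline* separates strains whose
motility differs by these amounts, not that any real strain has these
parameters.

Worm bodies are rendered as S-curved thick polylines, dark on the
backlight. The S-curve (point-symmetric about the centroid) is intentional:
its silhouette centroid coincides exactly with the trajectory position, so
centroid-based tracking can be compared with ground truth without a
body-shape bias term. Undulatory posture dynamics, bacterial lawn texture
and agar artefacts are out of scope — the module index depends only on
centroid motion.

## Image processing and tracking

Macro frames are segmented with an **adaptive threshold**: a pixel is
foreground iff it is more than `offset` grey levels below the local mean
over a `window × window` neighbourhood (computed exactly with integral
images). This is what makes segmentation robust under the deliberately
non-uniform illumination used during capture (below); a global threshold
provably fails on a ramp steeper than the worm contrast, and a test
constructs exactly that case. Components are labelled 8-connected, gated by
area (`classify_by_size()`), and associated frame-to-frame by
**minimum-distance optimal assignment** (`associate_identities()`, solved
as a linear sum assignment problem). "Minimum distance" is made
well-defined for many worms by using the global optimum rather than greedy
nearest-neighbour matching; ties break toward the lower worm id keeping
the nearer detection.

Association is gated: a pair further apart than `max_jump` (default three
times the expected per-frame travel of a fast worm) is broken. Worms lost
to merges or gates are **censored**, never re-identified — contact breaks
identity confidence, and re-identification is explicitly not attempted.
Identity numbers are never reused.

One deliberate deviation from pure per-frame processing: while the laser is
on, detections inside its occlusion neighbourhood are ignored and the
occluded worm's identity is carried through on its last position. The
saturated spot otherwise fragments the silhouette and spawns phantom
identities — the simulated counterpart of the real spot "making
segmentation difficult".

## The robot and the servo loops

The virtual rig uses a step pitch of 1.09 µm/step, under which the micro
camera's steps-per-pixel ratio is 1.0 and the macro's ≈ 25. The
configured constant is defined as *steps per pixel*, so multiplying a pixel
error by it yields the step command directly (`pixels_to_steps()`,
rounding half away from zero). Carriage moves follow a trapezoidal
velocity profile under `v_max` = 8000 stp/s, `a_max` = 25 000 stp/s².

**Goal acquisition** measures the laser→worm pixel error in the macro
image and commands the corresponding steps; with an exact model one
iteration lands within rounding, and the state machine switches to
microtracking when the error drops below 15 pxl. With a model mis-scaled
by a factor `1 ± ε`, the error contracts geometrically by `ε` per
iteration, which bounds the iterations needed from any start.

**Microtracking** turns the laser off (it saturates the micro image) and
servoes on the worm centroid in the micro frame. Note one sign convention:
the controller's command is the *image shift* that recentres the centroid;
the physical carriage moves by its negation, and the logged control
actions are the carriage deltas, so their sum telescopes to the worm's
own displacement in steps. This is what makes the module index meaningful:
a test asserts the per-instant agreement with ground truth to one step.

**Autofocus** maximizes mean squared intensity gradient over a set of
candidate head heights; the simulated defocus is a Gaussian blur growing
linearly with `|z − focus_z|`, so the score peaks at the true focus.

The per-worm sequence — select lowest-id untested worm, acquire, centre,
focus, capture 60 frames, restart — is driven by a six-state machine whose
legal edges are exported (`machine_transitions`) and asserted against
every session trace.

## Active illumination

The backlight display (800 × 480 texels) and macro camera form a closed
loop: a projective texel↔pixel map is calibrated from single-dot patterns
(normalized-DLT least squares on dot centroids; a 5 × 5 grid by default,
four non-collinear dots minimum), each texel owns its nearest pixels, and
a proportional controller (gain 0.5) brightens texels whose pixels are
darker than the reference and dims the brighter ones. Integral action is
omitted deliberately: only the fixed point matters, and under a linear
camera response the loop is a contraction for any gain in (0, 2).

During micro capture the worm-goal region needs more light. The
high-intensity circle is a logistic sigmoid of distance to the goal,
`I(d) = low + (high − low)·σ((r − d)/s)`: radially symmetric, exactly
`(low + high)/2` at `d = r`, and with spatial gradient bounded by
`(high − low)/(4s)` — small enough that the adaptive threshold is
untroubled. The logistic was chosen as the sigmoid; the functional form is
a free choice and only the bounded-gradient property matters.

## Statistics

Per-worm module sums are compared with a hand-implemented two-sided
Wilcoxon rank-sum test (`rank_sum_test()`): exhaustive enumeration of all
`choose(n+m, n)` splits of the pooled midranks when `min(n,m) ≤ 8` and
`n + m ≤ 16` (ties exact by construction), otherwise a normal
approximation with tie and continuity corrections. The implementation is
cross-checked in the tests against both a direct enumeration of the
Mann-Whitney U statistic and `stats::wilcox.test`. Two-sided throughout.

Two presentation choices were genuinely open and are exposed as options:
the module-sum "percentage" is normalized to the per-experiment maximum
worm (alternative: percent of group total), and strain histograms pool
modules across worms (alternative: averaging per-worm histograms), both
defaults chosen for interpretability of single worms.

## Numerical and scale choices

* Histogram bins are unit-width in steps from 0, with an overflow bin;
  the `[0,1)` bin is kept and read as "static instant".
* The parallax model `Δx = Δz · tan α` with α = 20.7° gives 0.378 mm of
  XY error per mm of surface-height change — the documented value of the
  implemented formula.
* Statistics-scale runs (30 worms × 4 replicates per strain) use the
  image-free session mode: ground-truth positions at 2 fps quantized to
  motor steps, i.e. exactly what an ideal servo would log (the rendered
  closed-loop controller agrees with this to one step per instant, which
  is itself a test). Image-in-the-loop sessions are exercised at desk
  scale: a 512² macro sensor at 110 µm/pxl and 0.5 mm worms, a faithful
  scaled geometry chosen to keep a full session in seconds. The motion
  model is stationary, so a worm's 30 s capture window is statistically
  exchangeable with any other — image-free mode therefore measures all
  worms over a common window instead of sequential slots.
* Per-plate seeds are derived deterministically from the master seed and
  kept below 2³¹; identical configuration and seed reproduce trajectory
  CSVs bit for bit.

## Known limitations

* The strain presets are invented stand-ins; absolute module values should
  not be compared with real recordings, only the machinery and the
  qualitative ordering.
* Worms are rigid S-curves: posture metrics (body bends, reversals,
  pirouettes) are out of scope, as is re-identification after contact.
* The simulated camera is orthographic with a linear grey response; real
  optics add vignetting, noise and perspective the active-vision loop
  would have to absorb.
* Stereo/3D reconstruction from the second micro camera is not modelled.
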