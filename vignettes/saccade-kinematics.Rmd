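---
title: "Saccade curvature and velocity-profile deviation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccade curvature and velocity-profile deviation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(saccurv)
```

## The problem

Saccades are often idealized as ballistic: straight paths with a
stereotyped, well-modelled velocity profile. During natural viewing —
watching video, for instance — a substantial fraction of saccades bend in
flight or show velocity profiles that standard models fit poorly. Both
properties matter practically: gaze-contingent displays that predict the
saccade landing point in real time mispredict exactly those saccades.
`saccurv` packages the measurement pipeline needed to quantify the two
phenomena per saccade — a **median pointwise curvature** score and a
**velocity-profile deviation** score — together with everything around
them: preprocessing of 1 kHz gaze traces, velocity-threshold saccade
detection with kinematic inclusion rules, shot-boundary (scene-cut)
detection in the viewed clips, in-flight flagging, and construction of a
log-polynomial analysis table for regression modelling.

Because raw natural-viewing recordings are bulky and rarely shareable,
the package includes a first-class synthetic generator that produces
ground-truth-labelled gaze sessions and clips with the statistical
structure the analysis assumes. All validation in the test suite runs
against this generator.

## Preprocessing

The cleaning chain is fixed: blink excision, gap interpolation,
smoothing, speed.

* **Blink excision** (`excise_blinks()`). Tracker-flagged gaps are kept
  invalid; valid samples flanking each gap are additionally invalidated
  while the local sample-to-sample speed exceeds 30 deg/s, marching
  outward up to 50 ms per side. The cap is ours: without it a noisy
  trace can let the march run away; 50 ms generously covers the
  closing/opening lid artifact at 1 kHz.
* **Interpolation** (`interpolate_gaps()`). Interior gaps are filled by a
  natural cubic spline through the valid samples. Natural (zero second
  derivative) boundary conditions are a deliberate choice — nothing in
  the data constrains curvature at the gap edges, so the least-committal
  spline is used. Edge gaps have no bracketing data and hold the nearest
  valid value instead.
* **Smoothing** (`smooth_gaze()`). A 3rd-order Savitzky–Golay filter
  with a 15-sample window, applied to x and y independently. Near the
  trace ends the filter's off-centre projection rows are used (a
  polynomial fit on the available window, no zero padding), which avoids
  spurious edge velocities. An order-3 filter reproduces cubic signals
  exactly; the test suite asserts this.
* **Speed** (`compute_speed()`). Velocity per axis by central
  differences on the sampling grid (one-sided at the ends), speed as the
  Euclidean norm, in deg/ms. We differentiate the smoothed signal in a
  separate step rather than using the filter's analytic derivative
  because the two-step chain is the conventional description of this
  pipeline; the analytic-derivative variant is available via
  `speed_method = "sgolay"` in `run_config()`.

**What smoothing costs.** A 15 ms window cannot be transparent to
events whose velocity peak is only a few milliseconds wide. On noiseless
synthetic saccades the filter changes the true peak speed by under 2%
for durations of 40 ms and up, but attenuates the peak of the shortest
admissible saccades (16 ms duration with a sharp, low-`p3` profile) by
up to roughly 29%. This is filter physics, not an implementation defect;
it is why detection uses a threshold on sustained speed rather than the
peak, and the test suite asserts the two regimes separately.

## Saccade detection

Detection operates on the speed trace: a saccade begins when speed
exceeds 30 deg/s and stays above it for at least 10 ms, and ends at the
last sample before speed drops back below. Duration follows the
sample-count convention (a 12-sample suprathreshold run at 1 kHz is a
12 ms event). Candidates then pass through inclusion rules, each
rejection labelled with the first failing rule:

| rule | bound | rationale |
|---|---|---|
| magnitude | strictly between 1 and 40 deg | microsaccades below; display diagonal above |
| duration | strictly over 15 ms | excludes noise blips (shortest kept: 16 ms) |
| initial speed | < 0.075 deg/ms at the onset sample | saccades start from (near) fixation |
| terminal speed | < 0.3 deg/ms at the offset sample | excludes truncated events |
| first-quartile speed | >= 0.15 x peak | removes uniform slow-rise profiles (pursuit fragments) |

The first-quartile speed is read at the single sample at
`onset + floor(duration/4)` — an instant, not an average — for
determinism. Threshold comparisons are strict in the direction the rule
names (exceeded / went below). Candidates touching the trace boundary
are rejected outright (`boundary`), since their kinematics are not fully
observed. No minimum inter-saccade gap is imposed beyond the offset
rule. Orientation uses the conventional bands: horizontal within 5
degrees of 0/180, vertical within 22 degrees of 90/270, otherwise
oblique; under the package's y-up convention, leftward means direction
strictly inside (90, 270) and downward strictly inside (180, 360).

## Curvature

For the sampled path of one saccade, the pointwise curvature at interior
samples is the Euclidean norm of the discrete second difference,
normalized by the total path length; the saccade's score `k` is the
median of the series. Both numerator and denominator are lengths, so `k`
is dimensionless and invariant to rotation, translation and uniform
scaling — properties the suite verifies to 1e-10.

Two variants are provided. The default (`"as_written"`) uses the full
second difference. Note a subtlety: the full second difference contains
the tangential (along-track) acceleration as well as the turn, so a
perfectly straight saccade traversed at varying speed — which is every
saccade — scores `k > 0`. The `"perpendicular"` variant projects the
second difference onto the normal of the local chord and is zero on any
straight path; it isolates actual bending, and it is the variant under
which measured curvature is exactly monotone in the generator's injected
bow amplitude. Verbose analyses should report both; the default stays
with the full second difference for comparability with the conventional
second-derivative measure.

## Velocity-profile deviation

The along-track displacement of a saccade is modelled by the compressed
exponential
$$f(t) = p_1\left[1 - e^{-(t/p_2)^{p_3}}\right],$$
with amplitude $p_1$ (deg), time scale $p_2$ (ms) and shape $p_3$;
$p_3 = 1$ is the standard exponential saturation, and $p_3 > 1$ gives
the slower deceleration phase typical of real saccades. The model is fit
per saccade to the distance-from-onset series by bounded
Levenberg–Marquardt least squares (`minpack.lm`), initialized at
$p_1 = $ magnitude, $p_2 = $ duration/2, $p_3 = 2$, with bounds
$p_1 \in (0, 3\,\mathrm{mag}]$, $p_2 \in (0, 3\,\mathrm{dur}]$,
$p_3 \in [0.5, 10]$, at most 200 iterations and relative tolerance
1e-10. Displacement is distance from the onset position — not cumulative
path length — so that $p_1$ is the saccade amplitude; a curved path's
extra length shows up in the velocity residuals, where it belongs.

The **deviation** score is the root-mean-square difference between the
measured speed over the event and the fitted model's velocity, in
deg/ms. RMSE (not MSE) is used so the score carries velocity units and
normalizes for event length.

**A numerical point that matters.** The measured speed is a central
difference at 1 kHz. On these kinematics that operator carries a
truncation bias of order 1e-3 deg/ms (the model velocity rises like
$t^{p_3-1}$ at onset, so its slope is unbounded there for $p_3 < 2$).
If the model side of the residual were evaluated with the exact
derivative, every saccade — including one that follows the model
perfectly — would be charged that bias, and the score's floor would be
set by the differentiation scheme rather than by the eye movement. The
package therefore evaluates the fitted model's velocity **through the
same finite-difference operator applied to the fitted position curve**
(`model_speed = "discrete"`, the default): shared truncation bias
cancels exactly, the score is zero for model-consistent data, and what
remains is genuine profile mismatch. The closed-form evaluation is
available as `model_speed = "analytic"` for comparison; on noisy real
data the two differ by the bias floor, which is comparable to the
smallest deviations one observes in practice.

## Scene cuts and in-flight saccades

Frames are converted to grayscale (BT.601 luma weights 0.299, 0.587,
0.114) and, for each consecutive pair, the metric is the log of the mean
absolute pixel difference (sum of absolute differences normalized by the
pixel count, with epsilon 1e-6 guarding log(0)). "Size" here is taken to
be the frame's pixel count, making the metric resolution-independent. A
transition is a cut candidate when its metric exceeds the clip's mean
plus one standard deviation (mean and sd over all transitions of the
clip, cuts included — no robust re-estimation). Gradual fades produce
runs of three or more consecutive suprathreshold transitions with
near-equal metrics; with `fade_reject` on, runs whose relative spread is
below 10% are dropped. This operationalizes what would otherwise be a
manual screening step and is documented as a heuristic. Candidates
closer than 5 frames keep only the larger metric. The cut time is
assigned to the later frame of the pair.

A saccade is flagged in flight at a cut when some cut time lies in its
closed onset–offset interval; the closed boundary means a cut landing
exactly on the onset or offset sample counts.

## The analysis table

`build_analysis_table()` produces one row per accepted saccade with
base-10 logs of curvature, deviation and duration plus their exact
squares and cubes (asserted at export time); one-hot orientation dummies
with horizontal as reference; leftward/downward indicators (reference
rightward/upward); the in-flight flag; and the time-on-task bin, the
ordinal 30 s interval of the session (1-based). Content ratings on the
0–5 importance scale are recoded low (<= 1) / medium (2–3) / high
(>= 4); genre uses comedy as the reference category. Rows with
nonpositive curvature or deviation (possible for perfectly straight
synthetic saccades under the perpendicular variant) cannot be
log-transformed and are dropped with a reported count.

Mixed-effects fitting itself is deliberately out of scope: the novel
content of the pipeline is the measures and codings, not the solver. The
exported table is written so any established mixed-model tool (`lme4`
and the like) can fit subject and clip as crossed random factors with
random slopes for log duration and log curvature/deviation.
`fit_log_cubic()` covers the univariable cubic summaries on log-log
scales by ordinary least squares.

## The synthetic generator

`make_session()` emulates 1 kHz recordings: fixations hold position plus
optional jitter; saccades follow the compressed exponential along-track
with a quadratic perpendicular bump `bow * 4 s (1 - s)` injecting
controllable curvature (endpoint-preserving, single-parameter, monotone
in the perpendicular curvature measure — a generative stand-in, not a
physiological model); blinks are invalid gaps whose five flanking
samples on each side move at 40–100 deg/s, exercising the blink-edge
rule; pursuit segments drift at constant velocity below the detection
threshold; i.i.d. Gaussian measurement noise is added everywhere. A
fixed seed gives bit-identical output.

`random_session_spec()` fixes the reference conditions used throughout
the tests: magnitudes log-uniform on 2–20 deg; durations from a
main-sequence-like rule (2.2 ms/deg + 21 ms, jittered, clipped to
18–95 ms, from which $p_2$ is derived); $p_3$ uniform on 1.5–2.5;
uniform directions constrained to a 33 x 19 deg viewing area;
inter-saccade fixations of 250–450 ms; measurement noise sd 0.02 deg.
These values are what a 1 kHz video-based tracker and normal viewing
produce; they were chosen once and are not tuned per test.

What the generator does **not** emulate: oculomotor plant dynamics
(glissades, dynamic overshoot), binocular disparity, head motion,
tracker-specific noise spectra (the noise here is white), or any
generative model of *why* saccades curve. Passing tests therefore
demonstrate that the measurement chain is correct and well-conditioned
under realistic signal structure — not that any physiological claim
holds on real recordings.

Synthetic clips (`make_clip()`) are constant-intensity fields with
Gaussian pixel noise, abrupt base-level steps of at least 40 gray levels
at cuts, and linear ramps for fades — the minimal structure the
adaptive threshold and the fade heuristic need.

## Problem sizes and numerical choices

The reference checks run at deliberately modest scale: 100-saccade
sessions for detection (recall and precision at least 0.95 against
ground truth at noise sd 0.02 deg), 100 noiseless model saccades for
parameter recovery (amplitude within 1%, shape within 2%), 50 seeded
clips for cut detection (perfect sensitivity at 3x noise contrast), and
a 300,000-sample session for throughput. Degenerate inputs are errors,
not warnings: all-invalid traces, fewer than 4 valid samples for
splines, traces shorter than the smoothing window, paths of fewer than
4 samples or zero length for curvature, events of fewer than 8 samples
for the profile fit, constant predictors for the fits. Ties and
boundaries are resolved as documented above (closed interval for
in-flight, inclusive orientation bands, strict detection thresholds).

## Known limitations

* The curvature score depends on sampling rate through the second
  difference; scores are comparable only across traces at the same rate.
* The default curvature variant's tangential floor makes very small bows
  on fast saccades hard to resolve; use the perpendicular variant when
  bending itself is the quantity of interest.
* Short saccades (< 25 ms) have their peak velocity attenuated by the
  prescribed smoothing window; main-sequence summaries inherit that
  bias.
* The fade-rejection rule is a heuristic stand-in for manual screening;
  dissolve-heavy footage will need inspection of the rejected runs.
* EyeLink input support covers sample lines only (no events/messages),
  and no binary EDF parsing.
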