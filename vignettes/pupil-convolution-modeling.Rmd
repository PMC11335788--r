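---
title: "Modeling pupil size responses to dynamic visual input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling pupil size responses to dynamic visual input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plrconv)
```

## The problem

Pupil size reflects a superposition of influences: the pupillary light
response (PLR) to luminance changes, transient orienting constrictions to
salient visual events, and slower cognitive modulations. When observers view
dynamic stimuli -- movies, games, natural scenes -- luminance and contrast
change continuously and their pupillary consequences overlap in time, so
isolating the cognitive component requires an explicit model of the
stimulus-driven part. `plrconv` builds that model: it extracts luminance and
contrast events from the stimulus itself, predicts the pupil trace they
should produce, and fits the few free parameters of that prediction to a
recorded pupil trace.

## The model

The core assumption is that each pupil-driving pathway behaves as a linear
time-invariant (LTI) system: the response to a sequence of events is the sum
of time-shifted copies of one impulse response, a gamma-shaped *response
function* (RF). Two RF families are available.

The **Erlang gamma** function,

$$h(t) = t^{\,n} e^{-n t / t_{max}},$$

is parameterized by the peak time $t_{max}$ (seconds) and a shape parameter
$n$ controlling the width; the peak time depends on $t_{max}$ alone, which
makes the fitted values directly interpretable. The sampled kernel is
peak-normalized before an amplitude gain is applied, so amplitude, $n$ and
$t_{max}$ are not scale-confounded. The **gamma probability density**
family,

$$d(t) = \frac{c}{\theta^{k}\,\Gamma(k)}\; t^{\,k-1} e^{-t/\theta},$$

integrates to its amplitude $c$ and peaks at $(k-1)\theta$; timing and
shape are controlled jointly by $k$ and $\theta$. Both kernels are preceded
by a fixed 200-ms onset delay, the latency before the pupil starts to move,
and truncated at a 4-s support (a 3-s response epoch plus the delay; both
are configurable in `model_spec()`).

The predicted pupil trace combines two components:

* **sustained luminance**: the signed per-region luminance change is
  convolved with the luminance RF and *cumulated* (discretely integrated),
  because a luminance step shifts the pupil to a new equilibrium rather
  than transiently;
* **transient contrast**: the unsigned change (the absolute value of the
  luminance change) is convolved directly with the contrast RF, modeling
  the short-lived orienting constriction that scales with event salience.

The components are combined as
`luminance + contrast_weight * contrast`, negated so that constriction is
negative, and z-standardized. z-scoring uses the population SD (denominator
$n$), so a standardized series has root-mean-square exactly 1; this makes
the closed-form checks in the test-suite exact (for example, a flat
prediction against any standardized target has RMSE exactly 1).

## From video to event traces

Frames are treated as 8-bit sRGB. Each frame is converted to CIELAB (D65
white point) and the L\* channel -- perceptual lightness on a 0--255 scale
-- is mapped to physical luminance through the display's power-law transfer
function `max_luminance * (L/255)^gamma` (defaults: 212 cd/m² at full
drive, gamma 2.2, typical for a large OLED panel). The display's native
primaries are not modeled; the sRGB assumption is standard practice when no
display characterization is available.

The luminance change at frame $t$ is the difference between the per-region
mean luminance at $t$ and at $t-2$: a lag-2 sliding difference, which at
25 Hz compares frames 80 ms apart -- approximating the integration time of
the visual system -- while still emitting one value per frame. The first
two frames are referenced against a homogeneously black image, so a movie's
onset itself is a (large) event. The lag is a configuration option
(`event_config(lag = ...)`) because a coarser every-other-frame variant is
equally defensible; the dense per-frame trace is the default as it keeps
the event trace aligned with the frame clock.

The visual field is tiled into a 6 x 8 grid of equal rectangles (boundaries
are equal blocks of `floor(size/k)` pixels with the last row/column
absorbing any remainder, so any resolution is handled deterministically).
The 48 regions map onto six weight groups: top/bottom crossed with
central/middle/peripheral eccentricity rings defined by column distance
from the vertical midline. W1 (top-central) is fixed to 1 -- after
z-scoring, a common scale on all weights is unidentifiable -- and W2--W6
are free parameters when regional weighting is enabled.

With an eye-tracking recording, events are extracted **gaze-contingently**:
each frame is placed on a black canvas 1.5 times the screen size so that
the gaze position coincides with the canvas center, approximating the
retinal image (the dark surround of a dimly lit room is luminance 0).
Content leaving the canvas is cropped; off-screen gaze samples are clamped
to the screen edge, and missing samples are carried forward (screen center
before the first valid sample). Gaze is downsampled to the frame rate by
averaging the valid samples inside each frame interval; the mean (rather
than nearest-sample) convention was chosen because it is the natural
low-pass reduction of a 500-Hz signal to 25 Hz.

## Fitting protocol

Free parameters (shape and peak time per enabled RF, the contrast weight,
optionally W2--W6) are estimated by Nelder--Mead simplex search on the
pooled RMSE between z-scored predicted and observed traces. Parameters are
box-bounded through a logistic transform -- shape in $[0.5, 40]$, peak time
in $[0.05, 2]$ s, weights in $[0, 10]$ -- bounds wide enough to be inert in
practice while keeping kernels well-formed. Initial values (luminance RF
$n = 10$, $t_{max} = 0.3$ s; contrast RF $n = 3$, $t_{max} = 0.5$ s;
contrast weight 0.5; weights 1) sit near typical fitted values for
naturalistic viewing. The simplex is restarted once from its incumbent by
default (`n_restarts`), which rebuilds the simplex and guards against
premature collapse; the higher-dimensional regional model benefits from
one or two extra restarts.

Trials are split into training (70%) and testing (30%) sets at random,
independently `n_folds = 5` times; reported metrics are test-set values
pooled within a fold and summarized across folds, and reported parameters
are across-fold means. The split is seeded and the optimizer is
deterministic, so a fit is exactly reproducible from its configuration.
Observed traces are interpolated onto the event timestamps; invalid pupil
samples (blinks, track loss) are bridged linearly when the gap is at most
500 ms and otherwise masked out of the loss -- standard pupillometry
practice, declared here rather than inferred from any source.

Model comparison uses $R^2 = 1 - SS_{res}/SS_{tot}$ on z-scored series,
the Pearson correlation, the RMSE, and the Gaussian BIC
$n \ln(rss/n) + k \ln n$ computed on the pooled test samples of each fold
with $k$ the number of free parameters. Note that this $R^2$ is not the
squared correlation: an uninformative unit-variance prediction scores
$-1$, not 0.

An `amplitude` switch (`fit_config(fit_amplitude = TRUE)`) adds a common
response gain to the free parameters. Because both sides of the loss are
z-scored the gain is unidentifiable there; it exists for workflows that
need un-standardized predictions, and is off by default.

## Benchmark pipelines

Two reference approaches are included for comparison with the temporally
continuous fit:

* `polynomial_benchmark()` fits one degree-5 polynomial in within-trial
  time jointly to all trials -- a prior-less model with as many parameters
  as the contrast-response model. On dynamic stimuli it explains almost
  nothing, which is the point of the comparison.
* The **discrete (epoch) pipeline**: `detect_events()` keeps luminance
  changes of at least 3 cd/m² and greedily drops events within 1 s of the
  previously kept one (earliest-first; greedy pruning is declared because
  "drop both" or "keep larger" would change event counts);
  `extract_epochs()` cuts 3-s segments at the pupil sampling rate, subtracts
  the mean of the first 250 ms (the pupil has not yet responded there), and
  scales all epochs by their pooled SD; `bin_by_magnitude()` groups events
  at the 20/40/60/80th magnitude percentiles (ties go to the lower bin);
  and `fit_korn_bach()` fits the sustained RF through its cumulative to the
  dilation grand mean, a second transient RF to the constriction-minus-
  inverted-dilation difference, and a scalar LTI2 weight on the
  reconstruction. RF amplitudes are profiled out in closed form (ordinary
  least squares given the shape), which makes the two-parameter simplex
  search fast and robust. Epochs are kept at full length; the 1-s
  separation rule already limits crosstalk between consecutive events.

On well-separated synthetic events the two pipelines recover the same
kernel timing (the test suite requires agreement of the fitted peak times
within 0.1 s).

## What the synthetic generator emulates

`random_video_spec()` + `generate_video()` produce piecewise-constant
videos: luminance steps at jittered, near-equally spaced times (at least
2 s apart by default, so discrete and continuous pipelines are both
exercised cleanly), with gray levels drawn uniformly from 20--235 either
screen-wide or independently per region. `generate_gaze()` yields
fixations or a smoothed drifting gaze at an eye-tracker rate (500 Hz), with
injectable validity gaps. `generate_pupil()` runs the forward model under a
declared `simulation_truth()` and adds i.i.d. Gaussian noise in z units,
then resamples to a 100-Hz pupil clock. The truth defaults -- Erlang
luminance RF $n = 13.7$, $t_{max} = 0.28$ s; contrast RF $n = 3.0$,
$t_{max} = 0.53$ s; contrast weight 0.42 -- are representative fitted
values for naturalistic movie viewing and make recovered parameters easy to
sanity-check.

What the generator deliberately does **not** emulate: naturalistic image
statistics (gradual motion, texture, color), autocorrelated measurement
noise, blink/saccade kinematics, or cognitive pupil dilations. Passing
parameter-recovery tests therefore demonstrates that the estimation
machinery is correct and well-conditioned under the model's own
assumptions -- not that the model captures every property of real
recordings, where misspecification (non-LTI adaptation, cognitive events)
necessarily lowers explained variance.

## Problem sizes and numerical choices

The test-suite and the acceptance script use 64 x 48 px, 25-Hz, 60-s clips
with 10 luminance steps and six trials per condition -- small enough to run
interactively, large enough that all parameters are identifiable (mixed
brightening/darkening steps decorrelate the luminance and contrast
regressors; per-region sampling decorrelates the regional weights).
Convolution uses direct summation in C (`stats::filter`), exact to double
precision against an $O(n^2)$ oracle. Erlang kernels are evaluated in log
space so large shape values cannot overflow. Degenerate cases are defined,
not accidental: zero-variance traces z-score to zeros with a flag, an
all-zero kernel refuses to normalize, a constriction trace that is exactly
the mirrored dilation yields an LTI2 weight of 0.

## Known limitations

The regional grid is rectangular and shared between the luminance and
contrast components; elliptical visual-field models, cortical
magnification, foreshortening-error correction of measured pupil size,
saccade- and depth-related pupil changes, and auditory or cognitive event
streams are out of scope. Gaze-contingent extraction assumes the display
subtends the modeled field and the surround is dark. The simplex search is
local: with the regional weights enabled the objective has shallow valleys,
and the restart mechanism (not a global optimizer) is the mitigation.

## A short worked example

```{r, eval = FALSE}
truth <- simulation_truth(noise_sd = 0.5)
trials <- simulate_trials(n_trials = 6, truth = truth, seed = 1,
                          n_steps = 10, duration = 60)
f <- fit(trials, model_spec(), fit_config(n_folds = 5, seed = 7))
print(f)
write_parameters_csv(f, "sim", "demo")
```

The printed summary lists the across-fold mean parameters (which should
bracket the truth values above) and the pooled test-set metrics; the same
quantities are what `scripts/acceptance.R` recomputes from scratch.
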