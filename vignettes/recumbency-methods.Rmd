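---
title: "Detecting group recumbency from camera-derived group velocity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting group recumbency from camera-derived group velocity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recumbency)
```

## The problem

Weaned pigs communicate a great deal through their resting behaviour: a
pen that is too cold, too warm or unsettled shows it first in when and
how the group lies down. Periods in which *every* pig in a pen is
recumbent ("group recumbency") are therefore a useful welfare and
climate indicator, but scoring them by watching video does not scale.
Overhead tracking cameras offer a shortcut: a tracker detects each pig,
flags whether it is standing, and reports positions over time. From
these the *cumulative group velocity* can be computed, and a simple
cutoff on that one number separates "all pigs lying" from "at least one
pig up".

`recumbency` implements that chain end to end — and, because real farm
recordings are rarely shareable, it ships a synthetic generator that
reproduces the statistical structure the analysis relies on, so every
stage is testable without animal data.

## The velocity signal

For one pen, let animal $i$ have position $p_{i,t} \in \mathbb{R}^2$
(metres, pen coordinates) at frame time $t$, and let $S_t$ be the set of
animals flagged *standing* at $t$. The group velocity of the frame pair
$(t-\Delta t, t)$ is

$$ v_t \;=\; \frac{\sum_{i \in S_t} \lVert p_{i,t} - p_{i,t-\Delta t}
\rVert}{\Delta t} \qquad [\mathrm{m/s}], $$

i.e. $v = \Delta p / \Delta t$ with $\Delta p$ the summed displacement of
standing-flagged animals. Three conventions are deliberate and pinned by
unit tests:

* the standing flag is taken from the **later** frame of each pair;
* an animal missing from either frame contributes zero (and is counted);
* per-pair velocities are averaged arithmetically over half-open
  5-minute windows `[start, start + 300 s)` aligned to the stream's
  first timestamp, giving the 5-min average velocity. Windows without
  any frame pair are kept with `n_frame_pairs = 0` and a missing value
  rather than silently dropped.

The phrase "average sum of distance changes" admits a second reading
(additionally averaging over animals); we sum over animals and average
over frame pairs, which reproduces both the per-pair formula and the
5-minute averaging, and we note the alternative as a sensitivity
question rather than implementing both.

Velocities stay in SI m/s even though typical values are of order
$10^{-4}$; any mm/s display is cosmetic only.

## Blur quality control

Lens soiling (dust, flies) blurs frames and silently destroys the
velocity signal's meaning, so images pass a sharpness gate first. The
score is the variance of the discrete Laplacian: the image is convolved
with the 3×3 kernel (centre −4, edge neighbours +1, corners 0) and the
population variance of the response is the score. Two numerical choices
matter and are pinned by tests:

* **border convention** — the variance is taken over valid interior
  pixels only. Padding (zero, replicate or circular) injects spurious
  edge responses and changes the score; the paperless choice here is "no
  padding", and a unit test freezes it.
* **arithmetic** — intensities are promoted to floating point before
  convolution; the −4 centre tap overflows 8-bit arithmetic otherwise.

The score is invariant to adding a constant intensity and scales with
$k^2$ when intensities are multiplied by $k$; both properties are
tested, as is monotonicity along a synthetic Gaussian-blur ladder.

An image is kept iff its score is **at least** the cutoff (default
1000); strictly lower means blurred and excluded. The cutoff is tied to
this exact scoring configuration (kernel, border mode, 0–255 intensity
scale) and should be re-tuned if any of those change — it is a
configuration value, not a portable constant. Frames showing people, or
pens without animals, are excluded upstream via an explicit pre-filter
list; that is a manual privacy/curation step, not image analysis.

## Behaviour coding and consensus

Behaviour is coded at group level on sampled still images (every 20 min
by default): code 0 when every pig is recumbent, code 1 when at least
one pig is standing, moving or sitting. Two observers code
independently; percent intercoder agreement is
$100 \cdot \#\{\text{matching codes}\}/\#\{\text{keys}\}$ over identical
(pen, timestamp) keys. Discrepant keys are resolved through an explicit
adjudication table — the package deliberately does *not* auto-resolve
disagreements, because the real process is a discussion between
observers that cannot be computed. The convention that a pig lying on
top of others in a half-standing posture still counts as recumbent is a
labelling rule for human coders; it has no computational counterpart
here. No chance-corrected agreement (kappa) is computed: raw percent
agreement is the reported statistic.

## The threshold classifier

A sample is classified *standing* iff $v > \tau$. The boundary
$v = \tau$ goes to recumbency: the system's purpose is to surface
only images in which all animals lie, so false positives are the error
to suppress. Three fitters produce $\tau$:

1. **Exhaustive** (`fit_threshold_exhaustive`, the canonical one):
   candidates are the midpoints between consecutive distinct sorted
   velocities plus one candidate below the minimum and one above the
   maximum; the candidate maximising training accuracy wins. Ties break
   toward higher sensitivity, then the smaller cutoff. Candidates are
   clamped at zero — a velocity cutoff cannot be negative — which means
   that on data containing exact zero velocities the "everything is
   standing" classification is unreachable under the strict `>` rule;
   the brute-force oracle in the tests enumerates the same nonnegative
   family, keeping the equivalence meaningful.
2. **Stepwise loop** (`fit_threshold_loop`): a literal transcription of
   the narrative procedure — raise the cutoff by a fixed step while the
   count of code-1 samples above it keeps falling, record, and restart
   from the highest code-0 velocity if the recorded value lies below
   it. Its step size and stopping detail are under-specified by the
   narrative, so it is retained as a faithful secondary method and is
   never allowed to beat the exhaustive optimum (a tested property).
3. **Mean + SD** (`fit_threshold_mean_sd`): the screening rule
   $\tau = \bar v_0 + s_0$ over recumbent-coded velocities.

Whether the loop tests thresholds on a grid or at observed velocities is
likewise unstated in the narrative; both are reachable through the
`step` argument, and the exhaustive fitter is the default everywhere.

## Evaluation

With standing as the positive class: sensitivity $TP/(TP+FN)$,
specificity $TN/(TN+FP)$, accuracy $(TP+TN)/n$, all in percent at full
precision, rounded only for display. A metric whose denominator is zero
is *undefined* (`NA`), never zero. 10-fold cross-validation shuffles
samples with a fixed seed into folds whose sizes differ by at most one,
fits on nine folds, scores the tenth, and averages per-fold metrics
**unweighted**; undefined fold metrics are excluded from their average
and counted. The class-difference test on velocity is a Welch (unequal
variance) two-sample t-test: the two classes are grossly unbalanced and
heteroscedastic, so the pooled-variance variant would be wrong more
often than right. An "efficiency" metric sometimes quoted alongside
these has no standard definition and is not implemented.

Cross-language RNG equivalence with other statistical environments is
not attempted; the seed recorded in every report guarantees
reproducibility within this package only.

## What the synthetic generator does (and does not) emulate

The generator works at the group level, mirroring the unit of analysis:
a schedule of `all_recumbent` / `some_active` episodes drives all pigs
in a pen. It emulates:

* a 2.55 m × 3.20 m pen with 18 animals (defaults), positions in
  continuous pen coordinates with the origin at a corner;
* *detection jitter*: recumbent pigs are reported with small
  frame-to-frame apparent speeds (truncated normal, default mean
  5×10⁻⁴ m/s) — measured velocity during true recumbency is small but
  nonzero, exactly as a tracker behaves;
* *false detections*: each recumbent pig is falsely flagged standing
  with a configurable per-frame rate (default 0.05). Whether a fully
  recumbent pen yields an empty standing set is thus a configuration
  choice (`false_detection_rate = 0`), not a hard assumption;
* during active episodes, exactly `n_active` pigs (redrawn each
  episode) move with speeds from the active distribution and are
  flagged standing;
* images on a sharpness ladder spanning the blur cutoff, built from a
  seeded rectangle scene blurred by a separable Gaussian with
  replicated edges;
* two coders: A equals ground truth; B disagrees either Bernoulli-wise
  (`disagreement_rate`) or on an exactly seeded count
  (`n_disagreements`).

Boundary handling is a deliberate deviation from the obvious choice.
Hard-clipping out-of-pen positions makes walls absorbing and biases
measured speed downward; reflective folding shortens every
wall-crossing step by twice the overshoot, biasing speed down by
$\approx \mathrm{step}^2(1/2W + 1/2H)$ — enough to break parameter
recovery at test precision. Instead each animal redraws its heading
until the step stays inside the pen ("pigs turn away from walls"),
which preserves the drawn step length exactly; a clamp with a logged
count remains as a safety net for pathological step lengths. Per-frame
speeds are truncated at zero, and the tests' expected cluster means use
the closed-form truncated-normal mean rather than the raw configured
mean.

The generator does **not** render pig shapes, model occlusion beyond
the false-detection rate, re-identify animals across tracking gaps, or
emulate camera optics. Passing tests therefore demonstrate that the
*analysis chain* is correct under the stated statistical structure —
two separable velocity populations, blur monotone in lens soiling —
not that any particular tracker meets that structure on a real farm.

## Study conditions used by the tests and acceptance script

Problem sizes are chosen so a full run stays light while estimates
remain stable: trajectory tests use single pens at 1–5 s frame
intervals over tens of minutes to a few hours; the coding worked
example uses the full 9634-label scale (cheap, since labels are
per-minute); parameter recovery uses n = 4000 velocity samples at the
study's ≈90:10 standing:recumbent imbalance, with recumbent jitter
$|N(0, 2\times10^{-4})|$ m/s and active movement
$N(0.02, 3\times10^{-3})$ m/s — separated populations, as the
two-population histogram of the motivating data shows, with the
population-optimal cutoff (≈6.7×10⁻⁴ m/s by density crossing) lying
between the recumbent 99th and active 1st percentiles. The pipeline
demo simulates four pens for six hours at 1 s frames. The default seed
is 123.

## Known limitations

* The blur cutoff's absolute scale is configuration-dependent;
  cross-system comparisons of raw Laplacian variances are meaningless
  without fixing kernel, border mode and intensity scale.
* The stepwise loop fitter inherits the ambiguity of its narrative
  source; treat it as a historical reference implementation.
* With heavy class imbalance, specificity estimates from small test
  folds are noisy and occasionally undefined; the report flags and
  excludes them rather than imputing.
* Real-data performance depends on tracker quality (occlusion, identity
  switches), which is outside this package's scope.
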