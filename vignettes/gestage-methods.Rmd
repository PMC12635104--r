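---
title: "Estimating gestational age from non-targeted ultrasound: model, fusion and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gestational age from non-targeted ultrasound: model, fusion and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestage)
```

## The problem

Gestational age (GA) anchors almost every decision in prenatal care, yet
measuring it by fetal biometry requires standard planes, calipers and a
trained sonographer. `gestage` implements an alternative: a regression model
that maps *any* fetal ultrasound frame to a GA estimate together with an
input-dependent uncertainty, plus a static one-dimensional Kalman filter
that fuses a stream of per-frame estimates from a video into a single
confident prediction. Uninformative frames — probe off the abdomen, Doppler
overlays, unreadable views — are screened out automatically by their
predicted uncertainty.

Clinical image archives cannot be redistributed, so the package also ships
a phantom simulator that generates labelled ultrasound-like frames and
full-length scan videos. Every stage of the pipeline is developed and
tested end-to-end against these phantoms.

## The heteroscedastic regression model

GA in days is strictly positive, so the model works in log space:
labels are $y = \ln(\mathrm{GA}_{\text{days}})$. A trunk network
$f: x \mapsto z \in \mathbb{R}^d$ maps a canonical frame to a
representation; a mean head $\mu(z) \in \mathbb{R}$ and a variance head
$\sigma(z) \in \mathbb{R}^+$ read the estimate and its uncertainty off that
representation. Training minimises, summed over the batch,

$$
\mathcal{L} = \sum_{(x,y)}
  \frac{\lvert y - \mu(f(x))\rvert^2}{2}
  \;-\; \ln \mathcal{N}\!\bigl(y \,\big|\, \mathrm{sg}[\mu(f(x))],\,
                                \sigma(\mathrm{sg}[f(x)])\bigr),
$$

where $\mathrm{sg}[\cdot]$ is a stop-gradient. The squared-error term
trains the trunk and the mean head; the Gaussian negative log-likelihood
trains **only** the variance head, because both its mean argument and its
feature input are gradient-stopped. The split matters: if the NLL reached
the trunk, the network could trade residual error against inflated
variance. With the split, the variance head solves a pure calibration
problem — for a fixed residual $r$ the NLL is minimised exactly at
$\sigma^\ast = \lvert r \rvert$ — so $\sigma$ learns to predict the size of
the error the mean head will make on that kind of image. That is what makes
$\sigma$ usable as a frame-quality screen downstream.

Training is phased: phase 1 freezes the variance head and optimises trunk +
mean head; phase 2 finetunes everything from the phase-1 optimum under a
fresh schedule. Each phase runs under Adam ($\epsilon = 10^{-8}$,
$\beta_1 = 0.9$, $\beta_2 = 0.999$) with a learning rate that warms up
linearly from 0 and then follows cosine annealing back to 0 by the final
epoch. Defaults (100 epochs per phase, 10 warmup, peak rate $3\times
10^{-4}$, batch 32) are recorded in `schedule_config()`; desk-scale runs in
this package use shorter schedules, stated below. Whether the loss should
be summed or averaged over the batch is a free choice absorbed by the
learning rate; we sum.

### The surrogate trunk

A production-scale convolutional trunk (e.g. a ConvNeXt with $d = 768$)
needs GPU-scale training and millions of images; nothing about the loss,
the phased schedule or the fusion logic depends on it. The trunk shipped
here is a deliberately small surrogate with one structural idea:

1. average-pool the 384×576 frame in 8×8 blocks (48×72 block means);
2. **rank-pool**: sort the block means in decreasing order and keep the top
   512;
3. standardise (statistics estimated from the training set, stored in the
   model);
4. one trainable dense ReLU layer to $d = 64$, then linear mean and
   log-variance heads (`sigma = exp(s)` floored at $10^{-4}$ log-days for
   strict positivity).

Rank pooling makes the features invariant to *where* the fetal structure
sits in the frame, which is what lets a few hundred training images
suffice: the sorted intensity profile encodes how many blocks the bright
structure covers, i.e. its area, which is the GA cue. Without it
(position-specific block features) the same training set yields a model
that memorises positions and fails on held-out frames. The cost is that the
trunk is blind to shape and texture detail a convolutional trunk would
see — acceptable for phantoms whose only GA cue is size.

## Fusing video frames: the static 1D Kalman filter

A video yields a stream of per-frame predictions $(\mu_i, \sigma_i)$ in
log-GA space. GA is constant over a scan (minutes against weeks), so the
filter is *static*: state mean $p$ and standard deviation $q$, updated per
accepted frame by

$$
K_i = \frac{q_{i-1}^2}{q_{i-1}^2 + \sigma_i^2}, \qquad
p_i = p_{i-1} + K_i(\mu_i - p_{i-1}), \qquad
q_i = \sqrt{(1 - K_i)\, q_{i-1}^2 + \varepsilon}.
$$

* **Initialisation**: $p_0 = 4.94$ ($e^{4.94} \approx 140$ days, the middle
  of pregnancy) and $q_0 = 0.35$, whose 95% interval
  $e^{4.94 \pm 1.96 \times 0.35} \approx (70, 278)$ days spans the whole
  plausible range — an intentionally weak prior. These constants force the
  whole filter into log space.
* **Gain form**: the gain above is the textbook static-filter gain built
  from the prior *variance* $q^2$. A variant that squares the state *mean*
  $p$ in the gain is sometimes written down; with $p \approx 5$ and
  $\sigma \leq 0.1$ it saturates $K > 0.999$ for every frame, making each
  new frame overwrite the state, which contradicts both the variance update
  and the weak-prior initialisation. The variance form is the default; the
  mean-squared variant is kept behind `gain_form = "as-printed"` so the
  behavioural difference is auditable rather than silently resolved.
* **Process noise** $\varepsilon = 0.001$ log-days² is added per accepted
  update. It bounds $q \geq \sqrt{\varepsilon} \approx 0.0316$, keeping the
  filter minimally responsive forever. With $\varepsilon = 0$ the filter is
  *exactly* the conjugate-normal Bayesian posterior (tests verify agreement
  to $10^{-10}$ over a thousand random streams) and is therefore exactly
  invariant to the order of the accepted frames — the mechanism behind the
  shuffle-robustness property checked in the evaluation battery.
* **Screening**: frames with $\sigma_i > \Sigma = 0.1$ are excluded before
  the update (strict inequality; the boundary is accepted). On trained
  phantoms, junk frames sit far above this threshold and fetal frames far
  below it.
* **Subsampling**: successive video frames violate the filter's
  independent-noise assumption, so inference samples 1 frame per second.
  Synthetic scans are generated at 5 fps precisely so this stage is
  observable.
* **Stopping**: the filter emits as soon as $q < \tau$ and ignores the rest
  of the video. The confidence threshold is a design choice; because
  $q$ can never fall below $\sqrt{\varepsilon} \approx 0.0316$, any
  $\tau \leq 0.0316$ is unreachable and the filter would run every video to
  the end (the constructor warns about such configurations). The default is
  $\tau = 0.035$ log-days, just above the floor: confidence is declared
  once enough high-quality frames have been fused to exhaust what the
  process noise allows. If the stream ends first, the final state is
  emitted flagged as not confident; if every frame is rejected, the prior
  is returned flagged `prior_only` (140 days under the defaults).

One consequence on phantoms deserves a flag: trained per-frame sigmas are
around 0.01 — phantoms are far easier than clinical frames — so a single
accepted frame already drives $q$ to the floor and the filter typically
stops on the first usable frame. On real data, where sigma sits nearer
$\Sigma$, reaching $\tau$ requires fusing tens of frames; both regimes run
the same code path, but time-to-prediction distributions measured on
phantoms say nothing about clinical time-to-prediction.

## Reference GA

* **Biometry dating** (second/third trimester), measurements in mm:
  $\mathrm{GA}_{\text{days}} = 7\,(10.85 + 0.0006\,HC \cdot FL +
  0.067\,BPD + 0.0168\,AC)$, monotone in each measurement.
* **CRL dating** (first trimester): the default curve is
  Robinson–Fleming, $\mathrm{GA}_{\text{days}} = 8.052\sqrt{CRL} + 23.73$;
  the curve is a pluggable function because dating charts differ between
  centres. CRL outside 2–95 mm warns but still evaluates.
* **Gold-standard propagation**: GA at any later examination is the
  dating-scan GA plus elapsed days; only dating scans between 9+0 and 13+6
  weeks (63–97 days) are eligible, and before 14 weeks CRL dating is by
  definition the reference, so biometry comparison is meaningful only from
  14 weeks on.

## The phantom generator

What it emulates: a bright ellipse-like structure whose *equivalent
diameter* follows the monotone growth law
$D(\mathrm{ga}) = 2.0\,\mathrm{ga}^{0.6}$ px (≈25–55 px over 9–36 weeks, a
biometry-like power law that fits the frame), at random position and
orientation over a dim low-frequency background, under multiplicative
log-normal speckle (sd 0.15, mean one — a first-order mimic of ultrasound
texture). Junk frames are structured noise with streaks and no ellipse.
Scan videos are synthesised at 5 fps with junk periods arranged in
persistent runs (two-state Markov chain, 0.9 s-to-s persistence), because
real probe-off periods are contiguous, not i.i.d. frames.

The reference study conditions used by the tests and the acceptance script,
chosen once: 90 subjects, GA uniform on [70, 250] days, 15% junk frames,
3–10 images per subject (~500 training frames), subject-level 90:10 split,
and a 25+25-epoch schedule with 3 warmup epochs at peak rate
$3\times10^{-3}$ — small enough to train on one CPU in seconds, large
enough to recover GA far below the constant-predictor baseline.

What the phantoms do *not* model: anatomy, probe geometry, shadowing,
multiple pregnancies, anomalies, or any realistic image statistics. Passing
tests on phantoms demonstrates that the loss trains what it should, that
sigma calibrates to frame quality, and that fusion, screening and the
statistics are correct — it says nothing about clinical accuracy, which
requires the real archives and a production trunk.

## Augmentation

`apply_augment()` implements a RandAugment-style policy: per image, N is
drawn uniformly from `n_range` (default [1, 3]), N distinct transforms are
sampled from {rotation, re-scaling, horizontal flip, blur,
brightness/contrast jitter, pixel-wise multiplicative noise, grid
distortion}, each applied at a random magnitude. Default magnitudes are
mild (rotation ±20°, re-scale ×[0.9, 1.1], blur σ ≤ 1.5 px, jitter ±15%,
multiplicative noise σ = 0.05, grid distortion ≤ 5%), geometric fills are
black to match the ultrasound background. One unresolved tension is kept
narrow rather than resolved: re-scaling perturbs the apparent structure
size, which is exactly the cue that predicts GA; the ±10% default bounds
the label noise this injects at roughly ±10%/0.6 ≈ ±17% GA in the worst
case for the phantom growth law, and training the surrogate does not use
re-scaling by default.

## Evaluation battery

* **Banded MAE**: mean absolute error of predicted vs reference GA within
  half-open `[lo, hi)` bands of reference GA (the convention has to be
  picked; half-open keeps bands a partition). Overall MAE is exactly the
  band-count-weighted mean.
* **Paired Wilcoxon signed-rank** on absolute errors (model vs biometry),
  two-sided (one-sidedness is a reporting choice we do not presume), zeros
  dropped. Exact distribution for n ≤ 25 tie-free samples; with ties or
  larger n, the normal approximation with continuity correction. Tests
  verify agreement with exhaustive $2^n$ sign enumeration for all n ≤ 8.
* **Bland–Altman**: mean difference and mean ± 1.96 sd limits of agreement,
  with a plot-ready per-point payload.
* **Time-to-prediction**: empirical CDF over seconds; videos that never
  reach confidence are right-censored — they stay in the denominator and
  are never counted as reached, so the CDF may plateau below 1 and the
  median can be undefined.
* **Shuffle consistency**: fraction of re-shuffled clip pairs whose two GA
  estimates differ by strictly less than 3 days.

The unit throughout is the scan: one record per scan, since subjects
contribute whole scans and tables count scans.

## Numerical and degenerate-input choices

* Resizing is bilinear, stretching (not letterboxing) to 384×576; colour
  collapses by Rec. 601 luminance; preprocessing is idempotent.
* `sigma` is floored at $10^{-4}$ log-days; a floored sigma contributes no
  variance-head gradient.
* Non-finite training loss aborts with a diagnostic rather than continuing.
* Empty prediction streams return the flagged prior; empty MAE bands report
  n = 0 with an absent estimate; Bland–Altman limits are undefined below
  n = 3; all-zero Wilcoxon differences report p = 1 with a degeneracy flag.
* All stochastic operations take explicit integer seeds and restore the
  caller's RNG state.

## Known limitations

* The surrogate trunk reads only a sorted intensity profile; it cannot
  learn shape, texture or pose cues, and its accuracy on phantoms
  (sub-day MAE) reflects phantom simplicity, not clinical performance.
* Videos are handled as synthetic scan objects or directories of numbered
  PNG frames; containerised video (MP4) ingestion is out of scope.
* The stopping threshold is meaningful only relative to the process noise;
  configurations with $\tau \leq \sqrt{\varepsilon}$ never stop (warned).
* CRL dating defaults to one specific curve; centres using other charts
  must plug in their own.
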