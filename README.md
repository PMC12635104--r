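# gestage

Gestational age (GA) estimation from non-targeted fetal ultrasound images
and video, for researchers studying automated pregnancy dating and for
anyone who needs a fully testable desk-scale implementation of the method:
a heteroscedastic regression network fused over video frames by a static 1D
Kalman filter, compared against biometry- and CRL-based reference dating.

## The method

**Per-frame model.** GA is modelled in log space
(y = ln GA_days). A trunk network f maps a canonical 384×576 greyscale
frame to a representation; a mean head μ and a variance head σ read off a
per-frame estimate and its uncertainty. The training loss, summed over the
batch, is

    L = Σ  |y − μ(f(x))|²/2  −  ln N(y | sg[μ(f(x))], σ(sg[f(x)]))

with sg[·] a stop-gradient: the squared error trains trunk + mean head, the
Gaussian negative log-likelihood trains only the variance head, so σ learns
to predict the magnitude of the mean head's error (for a fixed residual r
the NLL is minimised exactly at σ = |r|). Training is phased — variance
head frozen first, then full finetuning — under Adam with linear warmup and
cosine annealing.

**Video fusion.** Per-frame predictions (μᵢ, σᵢ), subsampled at 1 fps, are
fused by a static scalar Kalman filter on the log-GA state (p, q):

    Kᵢ = q²ᵢ₋₁ / (q²ᵢ₋₁ + σᵢ²)
    pᵢ = pᵢ₋₁ + Kᵢ (μᵢ − pᵢ₋₁)
    qᵢ = sqrt((1 − Kᵢ) q²ᵢ₋₁ + ε)

initialised at p₀ = 4.94 (≈140 days), q₀ = 0.35 (95% prior interval ≈
70–278 days), ε = 0.001. Frames with σᵢ > Σ = 0.1 are screened out; the
filter stops and emits as soon as q drops below a confidence threshold.
With ε = 0 the filter is exactly the conjugate-normal posterior and is
order-invariant — the mechanism behind the shuffle-robustness evaluation.

**Reference GA.** Biometry dating
GA_days = 7·(10.85 + 0.0006·HC·FL + 0.067·BPD + 0.0168·AC) (mm), CRL
dating GA_days = 8.052·√CRL + 23.73 (pluggable curve), and gold-standard
propagation (dating-scan GA + elapsed days, eligibility 9+0–13+6 weeks).

**Evaluation.** Banded MAE, paired Wilcoxon signed-rank on absolute errors,
Bland–Altman limits of agreement, time-to-prediction CDF with right
censoring, and shuffle-consistency of re-shuffled 3-minute clips (36
shuffled 5-s subsegments per clip).

Real clinical archives are restricted, so the package includes a phantom
simulator (ellipse size follows a monotone growth law in GA, multiplicative
speckle, junk frames, full-length scan videos) that exercises every stage
end-to-end. See `vignettes/gestage-methods.Rmd` for the full methods
account, including what phantom results do and do not demonstrate.

## Worked example

```r
library(gestage)

# a labelled phantom cohort, split by subject, surrogate model trained
man   <- generate_cohort(n_subjects = 20, ga_range = c(70, 250),
                         junk_fraction = 0.15, seed = 1)
man   <- split_by_subject(man, 0.9, seed = 1)
model <- train_ga_model(man, config = ga_model_config(seed = 1),
                        schedule = schedule_config(25, 3, 3e-3), seed = 1)

# one held-out fetal frame: mean, uncertainty, day scale
i <- which(man$split == "val" & man$is_fetal)[1]
p <- predict_frame(model, cohort_image(man, i)$pixels)
#> mu = 5.2475, sigma = 0.0146  ->  ga = 190.1 days (true 188.9)

# a junk frame: uncertainty far above the screening threshold 0.1
pj <- predict_frame(model, cohort_image(man, which(!man$is_fetal)[1])$pixels)
#> sigma = 0.277   (rejected by the filter)

# a shuffled 3-minute clip from a 4-minute scan at true GA 161 days
scan <- make_synthetic_scan("demo", ga_days = 161, duration_s = 240,
                            frame_rate = 5, junk_fraction = 0.2, seed = 4)
est  <- predict_video(splice_shuffled_clip(scan, seed = 9), model)
#> ga = 160.9 days, 95% interval (150.3, 172.2), stopped after 1 s,
#> frames used = 2, rejected = 0

# reference dating
biometry_ga(biometry_set(bpd_mm = 50, hc_mm = 180, ac_mm = 160, fl_mm = 35))
#> 144.676
propagate_gold_standard(crl_to_ga(55), days_elapsed = 62)
#> 145.4452
```

The numbers above mean: the per-frame model dates a held-out phantom to
within ~1 day and knows when a frame is unusable; the filter fuses a
shuffled clip to a sub-day error with a calibrated interval; and the
reference formulas give the comparison dating a clinician would compute
from biometry or a first-trimester CRL.

A command-line interface wrapping the same functions is installed at
`inst/cli/gestage` (subcommands `simulate`, `train`, `predict-image`,
`predict-video`, `compare-biometry`, `evaluate`).

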