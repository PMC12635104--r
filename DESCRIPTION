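Package: gestage
Title: Gestational Age Estimation from Ultrasound Images and Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates fetal gestational age (GA) directly from non-targeted
    ultrasound frames using heteroscedastic regression in log-GA space (a
    trunk network with a mean head and a variance head trained with a
    stop-gradient composite loss), and fuses per-frame estimates over video
    with a static one-dimensional Kalman filter that screens uninformative
    frames by their predicted uncertainty. Includes reference GA computation
    from fetal biometry (BPD/HC/AC/FL) and first-trimester crown-rump length
    dating, an ultrasound phantom simulator for end-to-end testing without
    clinical data, RandAugment-style training augmentation, and the
    evaluation battery (banded mean absolute error, paired Wilcoxon
    signed-rank comparison, Bland-Altman agreement, time-to-prediction
    distributions, and shuffle-consistency analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    EBImage,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
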