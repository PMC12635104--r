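cfg0 <- function(...) filter_config(...)

test_that("kalman gain matches direct arithmetic and its limits", {
  st <- filter_init(cfg0())
  expect_equal(kalman_gain(st, 0.1), 0.1225 / 0.1325, tolerance = 1e-10)
  expect_equal(kalman_gain(st, st$q), 0.5)                 # sigma = q_prev
  expect_lt(kalman_gain(st, 1e6), 1e-10)                   # no information
  for (s in c(0.01, 0.1, 1, 10)) {
    K <- kalman_gain(st, s)
    expect_gt(K, 0); expect_lt(K, 1)
  }
  expect_error(kalman_gain(st, 0), "positive")
  expect_error(kalman_gain(st, -1), "positive")
})

test_that("the as-printed gain form is available and behaves as printed", {
  cfg <- suppressWarnings(filter_config(gain_form = "as-printed"))
  st <- filter_init(cfg)
  expect_equal(kalman_gain(st, 0.1, cfg), 4.94^2 / (4.94^2 + 0.01),
               tolerance = 1e-12)
  # with p ~ 5 the printed form saturates K toward 1 for any plausible sigma
  expect_gt(kalman_gain(st, 0.35, cfg), 0.99)
})

test_that("one update reproduces the worked example", {
  st <- kalman_update(filter_init(), list(mu = 5.00, sigma = 0.1),
                      cfg0(process_noise = 0.001))
  K <- 0.1225 / 0.1325
  expect_equal(st$p, 4.94 + K * 0.06, tolerance = 1e-12)       # = 4.99547
  expect_equal(st$q, sqrt((1 - K) * 0.1225 + 0.001),
               tolerance = 1e-12)                              # = 0.10122
  expect_equal(round(st$p, 5), 4.99547)
  expect_equal(round(st$q, 5), 0.10122)
  expect_equal(st$n_used, 1L)
})

test_that("zero innovation leaves the mean fixed while q shrinks", {
  st0 <- filter_init()
  st <- kalman_update(st0, list(mu = st0$p, sigma = 0.1), cfg0())
  expect_equal(st$p, st0$p)
  expect_lt(st$q, st0$q)
})

test_that("with zero process noise the filter is the conjugate-normal posterior", {
  cfg <- cfg0(process_noise = 0, stop_threshold = 1e-9)
  # three identical observations: closed-form precision 1/q0^2 + 3/sigma^2
  st <- filter_init(cfg)
  for (i in 1:3) st <- kalman_update(st, list(mu = 5.0, sigma = 0.1), cfg)
  # posterior precision 1/0.35^2 + 3/0.1^2 = 308.16327:
  # p = (4.94/0.35^2 + 3*5/0.1^2)/308.16327, q = 308.16327^(-1/2)
  expect_equal(st$p, 4.998411, tolerance = 1e-6)
  expect_equal(st$q, 0.0569651, tolerance = 1e-5)
  oracle <- conjugate_posterior(4.94, 0.35, rep(5.0, 3), rep(0.1, 3))
  expect_equal(st$p, oracle$p, tolerance = 1e-12)
  expect_equal(st$q, oracle$q, tolerance = 1e-12)

  # random streams, including sequential-update vs closed-form agreement
  set.seed(2024)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    mu <- rnorm(n, 5, 0.3)
    sg <- runif(n, 0.02, 0.09)
    preds <- data.frame(time_s = seq_len(n) - 1, mu = mu, sigma = sg)
    est <- run_filter(preds, cfg)
    oracle <- conjugate_posterior(4.94, 0.35, mu, sg)
    expect_equal(est$p, oracle$p, tolerance = 1e-10)
    expect_equal(est$q, oracle$q, tolerance = 1e-10)
    # exact permutation invariance of the accepted-observation multiset
    perm <- sample.int(n)
    est_p <- run_filter(data.frame(time_s = seq_len(n) - 1,
                                   mu = mu[perm], sigma = sg[perm]), cfg)
    expect_equal(est_p$p, est$p, tolerance = 1e-10)
    expect_equal(est_p$q, est$q, tolerance = 1e-10)
  }
})

test_that("process noise bounds q below by sqrt(eps)", {
  cfg <- cfg0(process_noise = 0.001)
  st <- filter_init(cfg)
  for (i in 1:30) {
    st <- kalman_update(st, list(mu = 5, sigma = 0.02), cfg)
    expect_gte(st$q, sqrt(0.001))
  }
})

test_that("frame screening applies a strict > threshold", {
  cfg <- cfg0(screen_threshold = 0.1)
  expect_false(screen_frame(list(sigma = 0.15), cfg))
  expect_true(screen_frame(list(sigma = 0.05), cfg))
  expect_true(screen_frame(list(sigma = 0.1), cfg))   # boundary accepted
})

test_that("an all-rejected or empty stream returns the prior, flagged", {
  cfg <- cfg0()
  bad <- data.frame(time_s = 0:9, mu = 5, sigma = 0.5)
  est <- run_filter(bad, cfg)
  expect_true(est$prior_only)
  expect_equal(est$frames_rejected, 10L)
  expect_equal(est$ga_days, exp(4.94))
  expect_equal(round(est$ga_days), 140)

  est0 <- run_filter(data.frame(time_s = numeric(), mu = numeric(),
                                sigma = numeric()), cfg)
  expect_true(est0$prior_only)
})

test_that("stopping index matches the zero-noise closed form", {
  sigma <- 0.05; tau <- 0.0125
  cfg <- cfg0(process_noise = 0, stop_threshold = tau)
  # smallest n with (1/q0^2 + n/sigma^2)^(-1/2) < tau
  n_star <- ceiling((1 / tau^2 - 1 / 0.35^2) * sigma^2 + 1e-12)
  if ((1 / 0.35^2 + n_star / sigma^2)^(-0.5) >= tau) n_star <- n_star + 1
  preds <- data.frame(time_s = 0:29, mu = 5, sigma = sigma)
  est <- run_filter(preds, cfg)
  expect_true(est$stopped)
  expect_equal(est$frames_used, n_star)
  expect_equal(est$time_to_prediction_s, n_star - 1)  # 1 fps timestamps
})

test_that("a stream ending before confidence is flagged, not stopped", {
  cfg <- cfg0(process_noise = 0, stop_threshold = 1e-6)
  est <- run_filter(data.frame(time_s = 0:4, mu = 5, sigma = 0.05), cfg)
  expect_false(est$stopped)
  expect_true(is.na(est$time_to_prediction_s))
  expect_equal(est$frames_used, 5L)
})

test_that("the estimate never extrapolates beyond the observed range", {
  cfg <- cfg0(process_noise = 0, stop_threshold = 1e-9)
  set.seed(77)
  for (rep in 1:20) {
    mu <- runif(15, 4.94 - 5 * 0.35, 4.94 + 5 * 0.35)
    est <- run_filter(data.frame(time_s = 0:14, mu = mu,
                                 sigma = runif(15, 0.02, 0.09)), cfg)
    expect_gt(est$ga_days, exp(4.94 - 5 * 0.35))
    expect_lt(est$ga_days, exp(4.94 + 5 * 0.35))
  }
})

test_that("unreachable stopping configurations are warned about", {
  expect_warning(filter_config(process_noise = 0.001, stop_threshold = 0.0125),
                 "never stop")
  expect_silent(filter_config(process_noise = 0, stop_threshold = 0.0125))
})

test_that("interval95 brackets the fused estimate", {
  est <- run_filter(data.frame(time_s = 0:5, mu = 5, sigma = 0.05), cfg0())
  expect_lt(est$interval95[1], est$ga_days)
  expect_gt(est$interval95[2], est$ga_days)
})
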