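# Static 1D Kalman fusion of per-frame (mu, sigma) predictions in log-GA
# space. The state is (p, q): posterior mean and standard deviation of
# log-GA, assumed constant over the scan. Frames whose predicted sigma
# exceeds the screening threshold are discarded; the filter stops and emits
# as soon as q falls below the confidence threshold.
#
# Note on the gain: the published update is sometimes written with the state
# *mean* squared in the gain numerator; with p around 5 that would force
# K ~= 1 for every frame and contradict both the variance update and the
# declared initialisation. The default here is the textbook static-filter
# gain built from the prior *variance* q^2; the mean-squared form is kept
# behind `gain_form = "as-printed"` for auditability.

#' Filter configuration
#'
#' Defaults are the published operating point: prior `p0 = 4.94` log-days
#' (exp(4.94) ~ 140 days) with `q0 = 0.35` (95% prior interval ~ 70–278
#' days), process noise `eps = 0.001`, and screening threshold
#' `Sigma = 0.1`. The stopping threshold is a design choice: with process
#' noise `eps` the state sd can never fall below `sqrt(eps)` (~0.0316 here),
#' so the default `tau = 0.035` log-days sits just above that floor —
#' confidence is declared once a couple of high-quality frames have been
#' fused. Any `tau <= sqrt(process_noise)` makes stopping unreachable; a
#' warning is emitted for such configurations.
#'
#' @param p0,q0 prior state mean and standard deviation, log-days.
#' @param process_noise variance added per accepted update (log-days^2).
#' @param screen_threshold reject frames with `sigma > screen_threshold`.
#' @param stop_threshold emit once `q < stop_threshold`.
#' @param frame_rate sampling rate of the incoming stream, frames/second.
#' @param gain_form `"variance"` (default) or `"as-printed"` (see note
#'   above).
#' @return A `filter_config` object.
#' @export
filter_config <- function(p0 = 4.94, q0 = 0.35, process_noise = 0.001,
                          screen_threshold = 0.1, stop_threshold = 0.035,
                          frame_rate = 1,
                          gain_form = c("variance", "as-printed")) {
  gain_form <- match.arg(gain_form)
  stopifnot(q0 > 0, process_noise >= 0, screen_threshold > 0,
            stop_threshold > 0, frame_rate > 0)
  if (process_noise > 0 && stop_threshold <= sqrt(process_noise)) {
    warning(sprintf(
      "stop_threshold (%.4g) <= sqrt(process_noise) (%.4g): the filter can never stop",
      stop_threshold, sqrt(process_noise)), call. = FALSE)
  }
  structure(list(p0 = p0, q0 = q0, process_noise = process_noise,
                 screen_threshold = screen_threshold,
                 stop_threshold = stop_threshold, frame_rate = frame_rate,
                 gain_form = gain_form),
            class = "filter_config")
}

#' Initial filter state
#'
#' @param config a [filter_config()].
#' @return A `filter_state`: `p`, `q`, `n_used`, `elapsed` (seconds).
#' @export
filter_init <- function(config = filter_config()) {
  structure(list(p = config$p0, q = config$q0, n_used = 0L, elapsed = 0),
            class = "filter_state")
}

#' Kalman gain for one observation
#'
#' `K = q_prev^2 / (q_prev^2 + sigma^2)`, strictly inside (0, 1) for finite
#' positive inputs: low-noise frames pull the state hard, uninformative ones
#' barely move it.
#'
#' @param state a `filter_state`.
#' @param sigma_i observation standard deviation, log-days; must be > 0.
#' @param config a [filter_config()] (controls the gain form).
#' @return The gain K.
#' @export
kalman_gain <- function(state, sigma_i, config = filter_config()) {
  if (!is.numeric(sigma_i) || sigma_i <= 0) {
    stop("sigma_i must be strictly positive", call. = FALSE)
  }
  num <- if (config$gain_form == "as-printed") state$p^2 else state$q^2
  num / (num + sigma_i^2)
}

#' Screen a frame prediction by its uncertainty
#'
#' Frames with `sigma > screen_threshold` carry no usable fetal content
#' (or are too far out of distribution) and are excluded from fusion; the
#' boundary `sigma == threshold` is accepted (the rule is a strict `>`).
#'
#' @param obs a `frame_prediction` (anything with `sigma`).
#' @param config a [filter_config()].
#' @return `TRUE` to accept, `FALSE` to reject.
#' @export
screen_frame <- function(obs, config = filter_config()) {
  obs$sigma <= config$screen_threshold
}

#' One filter update with an accepted observation
#'
#' Applies `p <- p + K (mu - p)` and `q <- sqrt((1 - K) q^2 + eps)`; the
#' process noise keeps the filter minimally responsive, bounding q below by
#' `sqrt(eps)`.
#'
#' @param state a `filter_state`.
#' @param obs a `frame_prediction` (`mu`, `sigma`).
#' @param config a [filter_config()].
#' @return Updated `filter_state` with `n_used` incremented.
#' @export
kalman_update <- function(state, obs, config = filter_config()) {
  K <- kalman_gain(state, obs$sigma, config)
  state$p <- state$p + K * (obs$mu - state$p)
  state$q <- sqrt((1 - K) * state$q^2 + config$process_noise)
  state$n_used <- state$n_used + 1L
  state
}

#' Run the filter over a prediction stream
#'
#' Sequentially screens and fuses timestamped per-frame predictions,
#' stopping as soon as the state standard deviation drops below the
#' confidence threshold and ignoring the rest of the stream. If the stream
#' ends first, the final state is emitted and flagged as not having reached
#' confidence; if every frame is rejected (or the stream is empty) the prior
#' is returned, flagged `prior_only`, which evaluates to exp(4.94) ~ 140
#' days under the defaults.
#'
#' @param predictions data.frame with columns `time_s`, `mu`, `sigma`,
#'   ordered by time.
#' @param config a [filter_config()].
#' @return A `fused_estimate`: `ga_days`, `interval95` (days),
#'   `time_to_prediction_s` (`NA` when not reached), `frames_used`,
#'   `frames_rejected`, `stopped`, `prior_only`, and the final `p`, `q`.
#' @export
run_filter <- function(predictions, config = filter_config()) {
  state <- filter_init(config)
  rejected <- 0L
  stopped <- FALSE
  t_stop <- NA_real_
  n <- if (is.null(predictions)) 0L else nrow(predictions)
  if (n > 0) {
    for (i in seq_len(n)) {
      obs <- list(mu = predictions$mu[i], sigma = predictions$sigma[i])
      state$elapsed <- predictions$time_s[i]
      if (!screen_frame(obs, config)) {
        rejected <- rejected + 1L
        next
      }
      state <- kalman_update(state, obs, config)
      if (state$q < config$stop_threshold) {
        stopped <- TRUE
        t_stop <- predictions$time_s[i]
        break
      }
    }
  }
  structure(list(
    ga_days = exp(state$p),
    interval95 = exp(state$p + c(-1, 1) * 1.96 * state$q),
    time_to_prediction_s = t_stop,
    frames_used = state$n_used,
    frames_rejected = rejected,
    stopped = stopped,
    prior_only = state$n_used == 0L,
    p = state$p, q = state$q), class = "fused_estimate")
}

#' Predict GA from a video
#'
#' End-to-end video inference: subsample the video at the configured rate,
#' run each sampled frame through the model, screen and fuse with the
#' filter, and halt as soon as confidence is reached — later frames are
#' never rendered or scored.
#'
#' @param video anything accepted by [as_video()].
#' @param model a trained `ga_model`.
#' @param config a [filter_config()].
#' @param frame_rate native frame rate, when the source needs it.
#' @return A `fused_estimate` (see [run_filter()]).
#' @export
predict_video <- function(video, model, config = filter_config(),
                          frame_rate = NULL) {
  stream <- sample_frames(video, rate = config$frame_rate,
                          frame_rate = frame_rate)
  state <- filter_init(config)
  rejected <- 0L
  stopped <- FALSE
  t_stop <- NA_real_
  if (stream$n > 0) {
    for (k in seq_len(stream$n)) {
      pred <- predict_frame(model, stream$get(k))
      state$elapsed <- stream$time_s[k]
      if (!screen_frame(pred, config)) {
        rejected <- rejected + 1L
        next
      }
      state <- kalman_update(state, pred, config)
      if (state$q < config$stop_threshold) {
        stopped <- TRUE
        t_stop <- stream$time_s[k]
        break
      }
    }
  }
  structure(list(
    ga_days = exp(state$p),
    interval95 = exp(state$p + c(-1, 1) * 1.96 * state$q),
    time_to_prediction_s = t_stop,
    frames_used = state$n_used,
    frames_rejected = rejected,
    stopped = stopped,
    prior_only = state$n_used == 0L,
    p = state$p, q = state$q), class = "fused_estimate")
}
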