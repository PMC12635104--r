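# Heteroscedastic GA regression in log space.
#
# The network is trunk -> (mean head, variance head). Targets are natural
# logs of GA in days. The composite loss per example is
#
#     |y - mu(f(x))|^2 / 2  -  ln N(y | sg(mu(f(x))), sigma(sg(f(x))))
#
# where sg() is a stop-gradient: the squared-error term trains the trunk and
# the mean head; the Gaussian negative log-likelihood trains only the
# variance head (both its mean argument and its feature input are
# gradient-stopped). Training is phased: phase 1 freezes the variance head,
# phase 2 finetunes everything, each phase under Adam with linear warmup
# followed by cosine annealing to zero.
#
# The trunk here is a desk-scale surrogate: an 8x8 average-pool feature map
# followed by a rank-pooling stage (block intensities sorted in decreasing
# order and truncated), standardisation, and one trainable dense ReLU layer.
# Rank pooling makes the features invariant to where the fetal structure
# lies in the frame, which is what lets a small trunk generalise from a few
# hundred images. The loss, stop-gradient semantics, phased schedule and
# fusion logic are all trunk-agnostic; a GPU-scale convolutional trunk would
# slot into the same contract.

#' Model configuration
#'
#' @param trunk_kind `"small-surrogate"` (the only trunk built here; the
#'   configuration records the contract for larger trunks).
#' @param hidden_dim dimension d of the representation vector.
#' @param pool integer average-pooling factor applied to the canonical frame
#'   before rank pooling (8 gives a 48 x 72 block map).
#' @param keep_top number of sorted block intensities retained by the
#'   rank-pooling stage (the dimmer tail is uninformative background).
#' @param sigma_floor lower clamp on predicted sigma, log-days.
#' @param seed integer seed for weight initialisation.
#' @return A `ga_model_config` object.
#' @export
ga_model_config <- function(trunk_kind = "small-surrogate", hidden_dim = 64L,
                            pool = 8L, keep_top = 512L, sigma_floor = 1e-4,
                            seed = 1L) {
  stopifnot(hidden_dim >= 1, pool >= 1,
            CANONICAL_ROWS %% pool == 0, CANONICAL_COLS %% pool == 0,
            keep_top >= 1,
            keep_top <= (CANONICAL_ROWS %/% pool) * (CANONICAL_COLS %/% pool),
            sigma_floor > 0)
  structure(list(trunk_kind = trunk_kind, hidden_dim = as.integer(hidden_dim),
                 pool = as.integer(pool), keep_top = as.integer(keep_top),
                 sigma_floor = sigma_floor,
                 seed = as.integer(seed)),
            class = "ga_model_config")
}

#' Optimiser and schedule configuration
#'
#' Adam with the stated hyperparameters; per phase, the learning rate warms
#' up linearly from 0 over `warmup_epochs` and then follows cosine annealing
#' back to 0 by the final epoch.
#'
#' @param epochs_per_phase epochs in each of the two phases.
#' @param warmup_epochs linear warmup length, epochs.
#' @param max_learning_rate peak learning rate.
#' @param adam_eps,beta1,beta2 Adam constants.
#' @param batch_size minibatch size.
#' @return A `schedule_config` object.
#' @export
schedule_config <- function(epochs_per_phase = 100L, warmup_epochs = 10L,
                            max_learning_rate = 3e-4, adam_eps = 1e-8,
                            beta1 = 0.9, beta2 = 0.999, batch_size = 32L) {
  stopifnot(warmup_epochs >= 1, warmup_epochs < epochs_per_phase,
            max_learning_rate > 0)
  structure(list(epochs_per_phase = as.integer(epochs_per_phase),
                 warmup_epochs = as.integer(warmup_epochs),
                 max_learning_rate = max_learning_rate,
                 adam_eps = adam_eps, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size)),
            class = "schedule_config")
}

#' Learning rate at a given (0-based) epoch of one phase
#'
#' `lr(0) = 0`, `lr(warmup_epochs) = max_learning_rate`, and the final epoch
#' (`epochs_per_phase - 1`) returns exactly 0.
#'
#' @param epoch 0-based epoch index within the phase.
#' @param schedule a [schedule_config()].
#' @return Learning rate.
#' @export
learning_rate_at <- function(epoch, schedule) {
  w <- schedule$warmup_epochs
  e_max <- schedule$epochs_per_phase - 1L
  ifelse(epoch <= w,
         schedule$max_learning_rate * epoch / w,
         schedule$max_learning_rate * 0.5 *
           (1 + cos(pi * (epoch - w) / (e_max - w))))
}

#' Initialise an untrained model
#'
#' @param config a [ga_model_config()].
#' @return A `ga_model` object (He-initialised dense layer, zero heads, unit
#'   feature standardisation until training data fixes it).
#' @export
init_ga_model <- function(config = ga_model_config()) {
  n_feat <- config$keep_top
  d <- config$hidden_dim
  pars <- withr::with_seed(config$seed, {
    list(W1 = matrix(stats::rnorm(n_feat * d, 0, sqrt(2 / n_feat)), n_feat, d),
         b1 = numeric(d),
         w_mu = numeric(d), b_mu = 5.0,   # ln(148) ~ centre of the GA range
         w_s = numeric(d), b_s = log(0.35))
  })
  structure(list(config = config, n_feat = n_feat, pars = pars,
                 feat_mean = numeric(n_feat), feat_sd = rep(1, n_feat),
                 trained = FALSE),
            class = "ga_model")
}

# Raw trunk features for one frame: average-pooled block intensities,
# rank-pooled (sorted decreasing) and truncated.
raw_features <- function(im, pool, keep_top) {
  v <- sort(as.numeric(block_pool(assert_canonical(im), pool)),
            decreasing = TRUE)
  v[seq_len(keep_top)]
}

# Pooled, rank-pooled, standardised feature vector(s). `images` is a single
# canonical frame or a list of them; returns an n x n_feat matrix.
model_features <- function(model, images) {
  if (is.matrix(images)) images <- list(images)
  X <- t(vapply(images, function(im) {
    raw_features(im, model$config$pool, model$config$keep_top)
  }, numeric(model$n_feat)))
  sweep(sweep(X, 2, model$feat_mean), 2, model$feat_sd, "/")
}

# Forward pass on a feature matrix; returns mu, sigma and intermediates.
model_forward_features <- function(model, X) {
  p <- model$pars
  H <- sweep(X %*% p$W1, 2, p$b1, "+")
  Z <- pmax(H, 0)
  mu <- as.numeric(Z %*% p$w_mu) + p$b_mu
  s <- as.numeric(Z %*% p$w_s) + p$b_s
  sigma <- pmax(exp(s), model$config$sigma_floor)
  list(mu = mu, sigma = sigma, H = H, Z = Z)
}

#' Predict (mu, sigma) for a single frame
#'
#' @param model a trained (or untrained) `ga_model`.
#' @param image canonical frame.
#' @return A `frame_prediction`: `mu` (log-days) and `sigma` (log-days,
#'   strictly positive). Deterministic given the model parameters.
#' @export
predict_frame <- function(model, image) {
  stopifnot(inherits(model, "ga_model"))
  fw <- model_forward_features(model, model_features(model, image))
  structure(list(mu = fw$mu[1], sigma = fw$sigma[1]), class = "frame_prediction")
}

#' Convert a frame prediction (or raw mu/sigma) to GA in days
#'
#' @param prediction a `frame_prediction`, or any list with `mu` and
#'   optionally `sigma` in log-days.
#' @param level coverage of the prediction interval (default 0.95).
#' @return List with `ga_days = exp(mu)` and, when sigma is available,
#'   `interval` = exp(mu -/+ z*sigma).
#' @export
to_ga_days <- function(prediction, level = 0.95) {
  mu <- prediction$mu
  out <- list(ga_days = exp(mu))
  if (!is.null(prediction$sigma)) {
    z <- stats::qnorm(1 - (1 - level) / 2)
    out$interval <- exp(mu + c(-1, 1) * z * prediction$sigma)
  }
  out
}

#' Composite loss with stop-gradient semantics
#'
#' Returns the summed loss over the batch, its two components, and exact
#' analytic gradients honouring the stop-gradients: `sq` (squared error / 2)
#' back-propagates into the trunk and mean head; `nll` (Gaussian negative
#' log-likelihood) contributes gradients only to the variance head.
#'
#' @param model a `ga_model`.
#' @param images list of canonical frames (or a pre-computed feature matrix
#'   with `features = TRUE`).
#' @param y numeric labels in log-days.
#' @param features if `TRUE`, `images` is already a standardised feature
#'   matrix.
#' @return List `total`, `sq`, `nll`, and `grads` (named like the parameter
#'   list; gradients of `nll` appear only in `w_s`, `b_s`).
#' @export
ga_loss <- function(model, images, y, features = FALSE) {
  X <- if (features) images else model_features(model, images)
  stopifnot(nrow(X) == length(y), all(is.finite(y)))
  p <- model$pars
  fw <- model_forward_features(model, X)
  r <- fw$mu - y
  sq <- sum(r^2) / 2
  nll <- sum(0.5 * log(2 * pi) + log(fw$sigma) + r^2 / (2 * fw$sigma^2))

  act <- (fw$H > 0) * 1
  # squared-error term -> trunk + mean head
  d_mu <- r
  g_w_mu <- as.numeric(t(fw$Z) %*% d_mu)
  g_b_mu <- sum(d_mu)
  dZ <- outer(d_mu, p$w_mu) * act
  g_W1 <- t(X) %*% dZ
  g_b1 <- colSums(dZ)
  # NLL term -> variance head only (mu and features gradient-stopped);
  # where sigma sits on the floor the clamp kills the gradient
  live <- (exp(as.numeric(fw$Z %*% p$w_s) + p$b_s) > model$config$sigma_floor) * 1
  d_s <- (1 - r^2 / fw$sigma^2) * live
  g_w_s <- as.numeric(t(fw$Z) %*% d_s)
  g_b_s <- sum(d_s)

  list(total = sq + nll, sq = sq, nll = nll,
       grads = list(W1 = g_W1, b1 = g_b1, w_mu = g_w_mu, b_mu = g_b_mu,
                    w_s = g_w_s, b_s = g_b_s))
}

adam_init <- function(pars) {
  list(m = lapply(pars, function(p) p * 0),
       v = lapply(pars, function(p) p * 0), t = 0L)
}

adam_step <- function(pars, grads, state, lr, schedule, which_pars) {
  state$t <- state$t + 1L
  b1 <- schedule$beta1; b2 <- schedule$beta2
  for (nm in which_pars) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + schedule$adam_eps)
  }
  list(pars = pars, state = state)
}

run_phase <- function(model, Xtr, ytr, Xval, yval, schedule, phase,
                      which_pars, seed, log_rows, verbose) {
  n <- nrow(Xtr)
  state <- adam_init(model$pars)
  for (epoch in seq_len(schedule$epochs_per_phase) - 1L) {
    lr <- learning_rate_at(epoch, schedule)
    ord <- withr::with_seed(seed + 7919L * phase + epoch,
                            sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
    tr_loss <- 0
    for (bi in batches) {
      ls <- ga_loss(model, Xtr[bi, , drop = FALSE], ytr[bi], features = TRUE)
      if (!is.finite(ls$total)) {
        stop(sprintf("training diverged (non-finite loss, phase %d epoch %d)",
                     phase, epoch), call. = FALSE)
      }
      tr_loss <- tr_loss + ls$total
      if (lr > 0) {
        st <- adam_step(model$pars, ls$grads, state, lr, schedule, which_pars)
        model$pars <- st$pars
        state <- st$state
      }
    }
    val_loss <- if (!is.null(Xval) && nrow(Xval) > 0) {
      ga_loss(model, Xval, yval, features = TRUE)$total / nrow(Xval)
    } else NA_real_
    log_rows[[length(log_rows) + 1]] <-
      data.frame(phase = phase, epoch = epoch, lr = lr,
                 train_loss = tr_loss / n, val_loss = val_loss)
    if (verbose && epoch %% 10 == 0) {
      message(sprintf("phase %d epoch %3d  lr %.2e  train %.4f  val %.4f",
                      phase, epoch, lr, tr_loss / n, val_loss))
    }
  }
  list(model = model, log_rows = log_rows)
}

#' Train the heteroscedastic GA model (two phases)
#'
#' Phase 1 freezes the variance head and optimises trunk + mean head; phase 2
#' finetunes all parameters from the phase-1 optimum under a fresh schedule.
#' Labels are taken as natural logs of GA in days. Feature standardisation
#' statistics are estimated once from the training images and stored in the
#' model. A fixed seed reproduces the run bit-for-bit.
#'
#' @param images list of canonical frames, or a cohort manifest data.frame
#'   carrying a `split` column (frames are rendered via [cohort_image()] or
#'   read from `path`).
#' @param ga_days numeric GA labels in days (ignored when `images` is a
#'   manifest, which carries its own).
#' @param val_images,val_ga_days optional validation set (ignored for
#'   manifests).
#' @param config a [ga_model_config()].
#' @param schedule a [schedule_config()].
#' @param seed integer seed for minibatch shuffling.
#' @param verbose print per-epoch progress every 10 epochs.
#' @return A trained `ga_model`; the per-epoch log (phase, epoch, lr,
#'   train_loss, val_loss) is attached as `model$log`.
#' @export
train_ga_model <- function(images, ga_days = NULL, val_images = NULL,
                           val_ga_days = NULL, config = ga_model_config(),
                           schedule = schedule_config(), seed = 1L,
                           verbose = FALSE) {
  if (is.data.frame(images)) {
    manifest <- images
    if (is.null(manifest$split)) {
      stop("manifest must carry a 'split' column; see split_by_subject()",
           call. = FALSE)
    }
    fetch <- function(ix) lapply(ix, function(i) {
      if (nzchar(manifest$path[i] %||% "")) preprocess_image(manifest$path[i])
      else cohort_image(manifest, i)$pixels
    })
    tr <- which(manifest$split == "train")
    va <- which(manifest$split == "val")
    images <- fetch(tr); ga_days <- manifest$ga_days[tr]
    val_images <- fetch(va); val_ga_days <- manifest$ga_days[va]
  }
  stopifnot(length(images) == length(ga_days), all(ga_days > 0))
  model <- init_ga_model(config)

  raw <- t(vapply(images, function(im) {
    raw_features(im, config$pool, config$keep_top)
  }, numeric(model$n_feat)))
  model$feat_mean <- colMeans(raw)
  model$feat_sd <- pmax(apply(raw, 2, stats::sd), 1e-6)
  Xtr <- model_features(model, images)
  ytr <- log(ga_days)
  Xval <- if (length(val_images)) model_features(model, val_images) else NULL
  yval <- if (length(val_ga_days)) log(val_ga_days) else NULL

  log_rows <- list()
  trunk_mean <- c("W1", "b1", "w_mu", "b_mu")
  all_pars <- c(trunk_mean, "w_s", "b_s")
  ph1 <- run_phase(model, Xtr, ytr, Xval, yval, schedule, 1L, trunk_mean,
                   seed, log_rows, verbose)
  ph2 <- run_phase(ph1$model, Xtr, ytr, Xval, yval, schedule, 2L, all_pars,
                   seed, ph1$log_rows, verbose)
  model <- ph2$model
  model$trained <- TRUE
  model$log <- do.call(rbind, ph2$log_rows)
  model
}

#' Save / load a model checkpoint
#'
#' Single-file serialisation with the configuration embedded.
#'
#' @param model a `ga_model`.
#' @param path file path.
#' @return `load_ga_model` returns the model; `save_ga_model` returns `path`
#'   invisibly.
#' @export
save_ga_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ga_model
#' @export
load_ga_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "ga_model"))
  model
}
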