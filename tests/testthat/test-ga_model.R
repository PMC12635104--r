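# A zero-feature design isolates the heads: with X = 0 the representation is
# relu(b1) = 0, so mu = b_mu and sigma = exp(b_s) exactly.
heads_only_model <- function(b_mu = 5, b_s = 0, d = 4L) {
  m <- init_ga_model(ga_model_config(hidden_dim = d, seed = 2))
  m$pars$b_mu <- b_mu
  m$pars$b_s <- b_s
  m
}

test_that("loss reduces to the Gaussian normaliser at zero residual, unit sigma", {
  m <- heads_only_model(b_mu = 5, b_s = 0)
  X <- matrix(0, 1, m$n_feat)
  ls <- ga_loss(m, X, y = 5, features = TRUE)
  expect_equal(ls$total, 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(ls$sq, 0)
})

test_that("the NLL term is minimised at sigma = |residual|", {
  r <- 0.2
  m <- heads_only_model(b_mu = 5, b_s = log(r))
  X <- matrix(0, 1, m$n_feat)
  # analytic gradient wrt the variance-head bias vanishes at sigma = |r|
  ls <- ga_loss(m, X, y = 5 - r, features = TRUE)
  expect_equal(ls$grads$b_s, 0, tolerance = 1e-12)
  # independent 1-D numeric minimisation of the Gaussian NLL
  sigma_star <- stats::optimize(
    function(s) -stats::dnorm(5 - r, mean = 5, sd = s, log = TRUE),
    c(1e-3, 2))$minimum
  expect_equal(sigma_star, r, tolerance = 1e-4)
  nll_at <- function(s) {
    mm <- heads_only_model(b_mu = 5, b_s = log(s))
    ga_loss(mm, X, y = 5 - r, features = TRUE)$nll
  }
  expect_lt(nll_at(r), nll_at(r * 1.05))
  expect_lt(nll_at(r), nll_at(r * 0.95))
})

test_that("stop-gradients route the loss terms to the right parameters", {
  set.seed(31)
  cfg <- ga_model_config(hidden_dim = 6, seed = 3)
  m <- init_ga_model(cfg)
  m$pars$w_mu <- rnorm(6, 0, 0.3)
  m$pars$w_s <- rnorm(6, 0, 0.3)
  n <- 5
  X <- matrix(rnorm(n * m$n_feat, 0, 0.5), n, m$n_feat)
  y <- rnorm(n, 5, 0.3)
  ls <- ga_loss(m, X, y, features = TRUE)

  term <- function(model, which) ga_loss(model, X, y, features = TRUE)[[which]]
  h <- 1e-6
  idx <- cbind(c(1L, 7L, 20L), c(1L, 3L, 6L))
  for (k in seq_len(nrow(idx))) {
    mp <- m; mp$pars$W1[idx[k, 1], idx[k, 2]] <- mp$pars$W1[idx[k, 1], idx[k, 2]] + h
    mn <- m; mn$pars$W1[idx[k, 1], idx[k, 2]] <- mn$pars$W1[idx[k, 1], idx[k, 2]] - h
    fd_sq <- (term(mp, "sq") - term(mn, "sq")) / (2 * h)
    fd_nll <- (term(mp, "nll") - term(mn, "nll")) / (2 * h)
    # the returned trunk gradient is the squared-error term's gradient...
    expect_equal(ls$grads$W1[idx[k, 1], idx[k, 2]], fd_sq, tolerance = 1e-4)
    # ...even though the NLL term does vary with trunk parameters: the
    # stop-gradient drops a genuinely non-zero contribution
    if (abs(fd_nll) > 1e-3) {
      expect_false(isTRUE(all.equal(ls$grads$W1[idx[k, 1], idx[k, 2]],
                                    fd_sq + fd_nll, tolerance = 1e-6)))
    }
  }
  # mean-head gradient comes from the squared error only
  hp <- m; hp$pars$b_mu <- hp$pars$b_mu + h
  hn <- m; hn$pars$b_mu <- hn$pars$b_mu - h
  expect_equal(ls$grads$b_mu, (term(hp, "sq") - term(hn, "sq")) / (2 * h),
               tolerance = 1e-4)
})

test_that("learning-rate schedule: zero start, peak at warmup end, zero finish", {
  sch <- schedule_config(epochs_per_phase = 100, warmup_epochs = 10,
                         max_learning_rate = 3e-4)
  expect_equal(learning_rate_at(0, sch), 0)
  expect_equal(learning_rate_at(10, sch), 3e-4)
  expect_equal(learning_rate_at(99, sch), 0, tolerance = 1e-18)
  expect_equal(learning_rate_at(5, sch), 1.5e-4)             # linear warmup
  mid <- learning_rate_at(54.5, sch)                          # cosine midpoint
  expect_equal(mid, 1.5e-4, tolerance = 1e-6)
  expect_error(schedule_config(epochs_per_phase = 5, warmup_epochs = 5))
})

test_that("phase 1 leaves the variance head bit-identical", {
  set.seed(11)
  cfg <- ga_model_config(hidden_dim = 4, seed = 5)
  m <- init_ga_model(cfg)
  n <- 24
  X <- matrix(rnorm(n * m$n_feat), n, m$n_feat)
  y <- rnorm(n, 5, 0.2)
  sch <- schedule_config(epochs_per_phase = 4, warmup_epochs = 1,
                         max_learning_rate = 1e-3, batch_size = 8)
  out <- gestage:::run_phase(m, X, y, NULL, NULL, sch, 1L,
                             c("W1", "b1", "w_mu", "b_mu"), 1L, list(), FALSE)
  expect_identical(out$model$pars$w_s, m$pars$w_s)
  expect_identical(out$model$pars$b_s, m$pars$b_s)
  expect_false(identical(out$model$pars$W1, m$pars$W1))
})

test_that("forward passes are deterministic and sigma is strictly positive", {
  m <- init_ga_model(ga_model_config(seed = 9))
  img <- generate_phantom_image(phantom_spec(150, seed = 4))$pixels
  p1 <- predict_frame(m, img)
  p2 <- predict_frame(m, img)
  expect_identical(p1, p2)
  expect_gt(p1$sigma, 0)
})

test_that("log-space inversion reproduces the day scale and intervals", {
  expect_equal(to_ga_days(list(mu = log(140)))$ga_days, 140)
  expect_equal(round(to_ga_days(list(mu = 4.94))$ga_days), 140)
  iv <- to_ga_days(list(mu = 4.94, sigma = 0.35))$interval
  expect_equal(round(iv), c(70, 278))
})

test_that("training is seed-reproducible", {
  man <- generate_cohort(n_subjects = 6, ga_range = c(80, 240), seed = 17)
  imgs <- lapply(seq_len(nrow(man)), function(i) cohort_image(man, i)$pixels)
  sch <- schedule_config(epochs_per_phase = 3, warmup_epochs = 1,
                         max_learning_rate = 1e-3, batch_size = 8)
  m1 <- train_ga_model(imgs, man$ga_days, config = ga_model_config(seed = 1),
                       schedule = sch, seed = 1)
  m2 <- train_ga_model(imgs, man$ga_days, config = ga_model_config(seed = 1),
                       schedule = sch, seed = 1)
  expect_identical(m1$pars, m2$pars)
  expect_equal(nrow(m1$log), 6)         # 3 epochs x 2 phases
  expect_true(all(c("phase", "epoch", "lr", "train_loss", "val_loss")
                  %in% names(m1$log)))
})

test_that("the trained surrogate recovers GA and calibrates uncertainty", {
  fit <- trained_surrogate()
  fet <- fit$val_fetal
  ga_hat <- exp(fit$val_mu)
  mae <- mean(abs(ga_hat[fet] - fit$val_ga[fet]))
  baseline <- mean(abs(exp(fit$train_log_ga_mean) - fit$val_ga[fet]))
  expect_lt(mae, baseline / 5)
  slope <- unname(stats::coef(stats::lm(ga_hat[fet] ~ fit$val_ga[fet]))[2])
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
  # uncertainty separates junk from fetal content
  expect_gt(mean(fit$val_sigma[!fet]), mean(fit$val_sigma[fet]))
  expect_gt(min(fit$val_sigma[!fet]), stats::median(fit$val_sigma[fet]))
  # phase-1 training loss trends downward
  ph1 <- fit$model$log[fit$model$log$phase == 1, ]
  trend <- unname(stats::coef(stats::lm(ph1$train_loss ~ ph1$epoch))[2])
  expect_lt(trend, 0)
})

test_that("checkpoints round-trip through a single file", {
  fit <- trained_surrogate()
  path <- withr::local_tempfile(fileext = ".rds")
  save_ga_model(fit$model, path)
  back <- load_ga_model(path)
  expect_identical(back$pars, fit$model$pars)
  expect_identical(back$config, fit$model$config)
})
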