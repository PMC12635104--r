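# One surrogate model is trained per test run and shared across the tests
# that need it. The training conditions are the package's reference study:
# 90 subjects with GA uniform on [70, 250] days, 15% junk frames, ~500
# training images, 25 + 25 epochs.

.trained_cache <- new.env(parent = emptyenv())

trained_surrogate <- function() {
  if (!is.null(.trained_cache$fit)) return(.trained_cache$fit)
  manifest <- generate_cohort(n_subjects = 90, ga_range = c(70, 250),
                              junk_fraction = 0.15, seed = 42)
  manifest <- split_by_subject(manifest, 0.9, seed = 42)
  images <- lapply(seq_len(nrow(manifest)),
                   function(i) cohort_image(manifest, i)$pixels)
  tr <- which(manifest$split == "train")
  va <- which(manifest$split == "val")
  model <- train_ga_model(images[tr], manifest$ga_days[tr],
                          config = ga_model_config(seed = 42),
                          schedule = schedule_config(
                            epochs_per_phase = 25, warmup_epochs = 3,
                            max_learning_rate = 3e-3, batch_size = 32),
                          seed = 42)
  preds <- lapply(images[va], function(im) predict_frame(model, im))
  .trained_cache$fit <- list(
    model = model,
    manifest = manifest,
    val_idx = va,
    val_mu = vapply(preds, `[[`, numeric(1), "mu"),
    val_sigma = vapply(preds, `[[`, numeric(1), "sigma"),
    val_ga = manifest$ga_days[va],
    val_fetal = manifest$is_fetal[va],
    train_log_ga_mean = mean(log(manifest$ga_days[tr])))
  .trained_cache$fit
}
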