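test_that("configuration validates its arguments", {
  expect_error(stdpgcn_config(M = 4), "odd")
  expect_error(stdpgcn_config(gcn_layers = 2), "single")
  expect_error(stdpgcn_config(dropout = 1), "dropout")
  expect_error(stdpgcn_config(discriminator_dims = c(450, 10, 3)), "end in 2")
  cfg <- stdpgcn_config()
  expect_equal(cfg$feature_dim_out, 450)
  expect_equal(cfg$n_classes, 5)
})

test_that("extracted features have the configured width and are deterministic", {
  ds <- tiny_dataset(n_subjects = 2, epochs_per_subject = 8, seed = 13)
  cfg <- desk_config(epochs = 3, adversarial = FALSE)
  fit <- stdpgcn(ds, config = cfg, seed = 2)
  X1 <- extract_features(fit, ds)
  X2 <- extract_features(fit, ds)
  expect_equal(dim(X1), c(16, 450))
  expect_identical(X1, X2)  # evaluation mode: no dropout
  # generic inputs give distinct features
  expect_gt(max(abs(X1[1, ] - X1[9, ])), 0)
})

test_that("predictions align with epochs and probabilities form a simplex", {
  ds <- tiny_dataset(n_subjects = 2, epochs_per_subject = 10, seed = 14)
  fit <- stdpgcn(ds, config = desk_config(epochs = 3, adversarial = FALSE),
                 seed = 2)
  pr <- predict(fit, ds, type = "prob")
  expect_equal(dim(pr), c(20, 5))
  expect_equal(rowSums(pr), rep(1, 20), tolerance = 1e-9)
  cl <- predict(fit, ds)
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), stage_levels())
  expect_equal(as.integer(cl), unname(apply(pr, 1, which.max)))
})

test_that("the model fits a power-separable two-class problem", {
  # two stages distinguished only by per-channel signal power; 200 samples
  specs <- list(
    Wake = coupling_spec(NULL, noise_sd = 0.1),
    N1   = coupling_spec(NULL, noise_sd = 1.5),
    N2   = coupling_spec(NULL, noise_sd = 0.1),
    N3   = coupling_spec(NULL, noise_sd = 0.1),
    REM  = coupling_spec(NULL, noise_sd = 0.1)
  )
  tm <- matrix(0, 5, 5)
  tm[, 1] <- 0.5
  tm[, 2] <- 0.5
  ds <- generate_stage_dataset(2, 100, stage_specs = specs,
                               transition_matrix = tm, subject_shift_sd = 0,
                               n_channels = 6, n_samples = 600,
                               sampling_rate = 50, seed = 19)
  expect_setequal(as.character(unique(ds$labels)), c("Wake", "N1"))
  fit <- stdpgcn(ds, config = desk_config(epochs = 200, adversarial = FALSE),
                 seed = 3, verbose = FALSE)
  expect_gte(evaluate(fit, ds)$accuracy, 0.95)
})

test_that("training histories have one row per epoch and print methods work", {
  ds <- tiny_dataset(n_subjects = 2, epochs_per_subject = 8, seed = 23)
  cfg <- desk_config(epochs = 7, adversarial = FALSE)
  fit <- stdpgcn(ds, config = cfg, seed = 1)
  expect_equal(nrow(fit$history), 7)
  expect_true(all(is.finite(fit$history$class_loss)))
  expect_output(print(fit), "sleep stager")
  expect_output(summary(fit), "parameters")
  expect_named(coef(fit), names(fit$par))
  expect_silent(grDevices::pdf(NULL))
  plot(fit)
  grDevices::dev.off()
})

test_that("fitting warns when the adversarial branch has no target domain", {
  ds <- tiny_dataset(n_subjects = 2, epochs_per_subject = 6, seed = 29)
  expect_warning(stdpgcn(ds, config = desk_config(epochs = 2), seed = 1),
                 "target")
})
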