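test_that("metrics follow the FVAF definition", {
  obs <- c(0, 1, 2, 3); pred <- c(0, 0, 2, 2)
  m <- evaluate_predictions(pred, obs)
  expect_equal(m$fvaf, 1 - 0.5 / 1.25)  # = 0.6
  expect_equal(m$rmse^2, 0.5)

  expect_equal(evaluate_predictions(obs, obs)$fvaf, 1)
  expect_equal(evaluate_predictions(obs, obs)$spearman_rho, 1)
  expect_equal(evaluate_predictions(obs, obs)$rmse, 0)
  # mean predictor scores exactly zero
  expect_equal(evaluate_predictions(rep(mean(obs), 4), obs)$fvaf, 0)

  expect_error(evaluate_predictions(1:3, 1:4), "mismatch")
  expect_error(evaluate_predictions(c(1, 2), c(5, 5)), "variance")
})

test_that("training recovers a noiseless additive landscape", {
  truth <- make_truth(positions = tiny_positions, effect_sd = 1.5,
                      intercept = -1, pairwise = NULL, seed = 3)
  fit <- fit_tiny_model(truth, seed = 3, epochs = 400, hidden = c(64, 32),
                        batch_size = 8, patience = 60)
  ev <- evaluate_predictions(predict(fit$model, fit$enc[fit$val_idx, ]),
                             fit$y[fit$val_idx])
  expect_gt(ev$fvaf, 0.95)
})

test_that("training is deterministic given the seed and stops early", {
  truth <- tiny_truth(seed = 5)
  f1 <- fit_tiny_model(truth, seed = 11, epochs = 30)
  f2 <- fit_tiny_model(truth, seed = 11, epochs = 30)
  expect_equal(predict(f1$model, f1$enc), predict(f2$model, f2$enc),
               tolerance = 1e-12)

  # early stopping: pure-noise validation targets stop improving quickly
  enc <- f1$enc[1:64, ]
  set.seed(2)
  y_noise <- runif(64)
  m <- mlp_train(enc, y_noise, f1$enc[65:96, ], runif(32),
                 mlp_config(hidden = c(8), max_epochs = 200, patience = 5,
                            dropout = 0, seed = 1))
  expect_lt(nrow(m$history), 200)
  expect_identical(which.min(m$history$val_mse), as.integer(m$best_epoch))
})

test_that("prediction is row-independent, repeatable and shape-checked", {
  truth <- tiny_truth()
  fit <- fit_tiny_model(truth, epochs = 10)
  p1 <- predict(fit$model, fit$enc)
  expect_length(p1, 256)
  expect_identical(p1, predict(fit$model, fit$enc))
  perm <- sample.int(256)
  expect_equal(predict(fit$model, fit$enc[perm, ]), p1[perm],
               tolerance = 1e-12)
  bad <- fit$enc[, 1:12]
  expect_error(predict(fit$model, bad), "feature mismatch")
})

test_that("cross-validation trains one model per rotation", {
  truth <- tiny_truth(seed = 2)
  oracle <- truth_oracle(truth)
  enc <- one_hot_encode(oracle$sequence, truth$positions)
  rot <- stratified_rotations(oracle$efficiency, k = 4, n_bins = 4,
                              seed = 1)
  cfg <- mlp_config(hidden = c(8), max_epochs = 10, dropout = 0, seed = 7)
  cv <- cross_validate(cfg, rot, enc, oracle$efficiency)
  expect_identical(nrow(cv), 4L)
  expect_true(all(is.finite(cv$val_fvaf)))
  # identical configs give identical metrics (shared seeds)
  cv2 <- cross_validate(list(cfg, cfg), rot, enc, oracle$efficiency,
                        n_rotations = 2)
  expect_equal(cv2$val_fvaf[cv2$config == 1], cv2$val_fvaf[cv2$config == 2],
               tolerance = 1e-12)
})

test_that("residual analysis relates model error to replicate spread", {
  pred <- c(0.1, 0.5, 0.9)
  same <- cbind(c(0.1, 0.4, 0.8), c(0.1, 0.4, 0.8))
  ra <- residual_analysis(pred, same)
  expect_equal(ra$replicate_sd, c(0, 0, 0))
  expect_equal(ra$residual, pred - same[, 1])
  expect_error(residual_analysis(pred, same[, 1, drop = FALSE]),
               "2 replicates")

  # noisy replicates: |residual| tracks replicate sd on synthetic data
  truth <- make_truth(seed = 4)
  sim <- simulate_counts(truth, replicates = 3, seed = 4)
  lib <- enumerate_library()
  targets <- sapply(sort(unique(sim$replicate)), function(r) {
    minmax_normalize(complete_with_zeros(
      sim[sim$replicate == r, ], lib))$target
  })
  oracle <- truth_oracle(truth)
  scaled <- oracle$efficiency / max(oracle$efficiency)
  ra <- residual_analysis(scaled, targets)
  expect_gt(ra$rho_sd_abs_residual, 0.3)
})

test_that("models persist through JSON round-trip", {
  truth <- tiny_truth()
  fit <- fit_tiny_model(truth, epochs = 5)
  path <- withr::local_tempfile(fileext = ".json")
  save_mlp(fit$model, path)
  back <- load_mlp(path)
  expect_equal(predict(back, fit$enc), predict(fit$model, fit$enc),
               tolerance = 1e-12)
  expect_identical(back$feature_names, fit$model$feature_names)
})
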