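# small prepared datasets for fast training tests
local_tiny_data <- function(n = 24, seed = 50, L = 256L) {
  ds <- generate_dataset(sim_config("hard", n_curves = n, seed = seed))
  prepare_dataset(ds$curves, L = L)
}

test_that("split_dataset partitions reproducibly with the stated sizes", {
  curves <- as.list(1:10)
  sp <- split_dataset(curves, 0.3, seed = 1)
  expect_length(sp$train, 7)
  expect_length(sp$val, 3)
  expect_setequal(c(sp$idx_train, sp$idx_val), 1:10)
  sp2 <- split_dataset(curves, 0.3, seed = 1)
  expect_identical(sp$idx_train, sp2$idx_train)
  sp3 <- split_dataset(curves, 0.3, seed = 2)
  expect_false(identical(sp$idx_train, sp3$idx_train))
  spm <- split_dataset(as.list(1:2), 0.5, seed = 1)
  expect_length(spm$train, 1); expect_length(spm$val, 1)
  expect_error(split_dataset(as.list(1:10), 0.999, seed = 1),
               class = "fp_validation_error")
  expect_error(split_dataset(list(1), 0.5), class = "fp_validation_error")
})

test_that("a single epoch yields a one-row history with best_epoch 1", {
  dat <- local_tiny_data(8, seed = 51)
  sp <- list(x = dat$x[1:6, ], y = dat$y[1:6],
             transforms = dat$transforms[1:6], zc = dat$zc[1:6])
  va <- list(x = dat$x[7:8, ], y = dat$y[7:8],
             transforms = dat$transforms[7:8], zc = dat$zc[7:8])
  fit <- train_model(tiny_convnet(256L), sp, va,
                     train_config(epochs = 1, batch_size = 4, seed = 1))
  expect_identical(nrow(fit$history), 1L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("returned weights reproduce the recorded minimum validation loss", {
  dat <- local_tiny_data(24, seed = 52)
  tr <- lapply(dat, function(v) if (is.matrix(v)) v[1:18, ] else v[1:18])
  va <- lapply(dat, function(v) if (is.matrix(v)) v[19:24, ] else v[19:24])
  fit <- train_model(tiny_convnet(256L, seed = 2), tr, va,
                     train_config(epochs = 6, batch_size = 8, lr = 1e-3,
                                  seed = 3))
  pred <- forcepoint:::model_predict_norm(fit$model, va$x)
  expect_equal(mean((pred - va$y)^2), min(fit$history$val_mse),
               tolerance = 1e-12)
  expect_identical(fit$best_epoch, which.min(fit$history$val_mse))
})

test_that("validation curves never contribute gradients", {
  dat <- local_tiny_data(20, seed = 53)
  tr <- lapply(dat, function(v) if (is.matrix(v)) v[1:14, ] else v[1:14])
  va <- lapply(dat, function(v) if (is.matrix(v)) v[15:20, ] else v[15:20])
  poisoned <- va
  poisoned$y <- rev(va$y) * 0.5 + 0.25
  f1 <- train_model(tiny_convnet(256L, seed = 4), tr, va,
                    train_config(epochs = 3, batch_size = 8, seed = 5),
                    keep_last = TRUE)
  f2 <- train_model(tiny_convnet(256L, seed = 4), tr, poisoned,
                    train_config(epochs = 3, batch_size = 8, seed = 5),
                    keep_last = TRUE)
  expect_identical(f1$weights_last, f2$weights_last)
})

test_that("training reduces the loss on an easy scaled-down problem", {
  dat <- local_tiny_data(40, seed = 54)
  tr <- lapply(dat, function(v) if (is.matrix(v)) v[1:30, ] else v[1:30])
  va <- lapply(dat, function(v) if (is.matrix(v)) v[31:40, ] else v[31:40])
  fit <- train_model(tiny_convnet(256L, seed = 6), tr, va,
                     train_config(epochs = 20, batch_size = 10, lr = 1e-3,
                                  seed = 7))
  expect_lt(min(fit$history$val_mse), 0.5 * fit$history$val_mse[1])
  expect_lt(fit$history$train_mse[20], fit$history$train_mse[1])
})

test_that("training is reproducible for a fixed seed pair", {
  dat <- local_tiny_data(16, seed = 55)
  tr <- lapply(dat, function(v) if (is.matrix(v)) v[1:12, ] else v[1:12])
  va <- lapply(dat, function(v) if (is.matrix(v)) v[13:16, ] else v[13:16])
  f1 <- train_model(tiny_convnet(256L, seed = 8), tr, va,
                    train_config(epochs = 2, batch_size = 6, seed = 9))
  f2 <- train_model(tiny_convnet(256L, seed = 8), tr, va,
                    train_config(epochs = 2, batch_size = 6, seed = 9))
  expect_identical(f1$history, f2$history)
  expect_identical(get_weights(f1$model), get_weights(f2$model))
})

test_that("fit objects expose the standard modelling methods", {
  dat <- local_tiny_data(16, seed = 56)
  tr <- lapply(dat, function(v) if (is.matrix(v)) v[1:12, ] else v[1:12])
  va <- lapply(dat, function(v) if (is.matrix(v)) v[13:16, ] else v[13:16])
  fit <- train_model(tiny_convnet(256L, seed = 1), tr, va,
                     train_config(epochs = 2, batch_size = 6, seed = 2))
  expect_output(print(fit), "trained convnet1d")
  s <- summary(fit)
  expect_s3_class(s, "summary.fp_fit")
  expect_identical(s$n_val, 4L)
  expect_length(residuals(fit), 4)
  lc <- generate_hard_curve(hard_surface_params(), acquisition_params(),
                            seed = 3)
  pr <- predict(fit, lc)
  expect_length(pr, 1)
  expect_true(is.finite(pr))
})
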