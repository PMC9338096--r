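test_that("both architectures map a batch to one output per signal", {
  m <- tiny_convnet(256L)
  x <- matrix(runif(3 * 256), 3, 256)
  out <- model_forward(m, x)
  expect_length(out, 3)
  expect_true(all(is.finite(out)))
  mr <- build_resnet50_1d(resnet_spec(stage_block_counts = c(1, 1),
                                      base_filters = 4),
                          input_length = 128, seed = 2)
  xr <- matrix(runif(2 * 128), 2, 128)
  expect_length(model_forward(mr, xr), 2)
  expect_error(model_forward(m, matrix(0, 2, 100)),
               class = "fp_validation_error")
})

test_that("spec list-length mismatches are rejected", {
  expect_error(convnet_spec(n_blocks = 3L, filters = c(16L, 32L)),
               class = "fp_spec_error")
  expect_error(convnet_spec(pool_sizes = c(4L, 4L)),
               class = "fp_spec_error")
})

test_that("model construction is deterministic under seed", {
  m1 <- tiny_convnet(256L, seed = 11)
  m2 <- tiny_convnet(256L, seed = 11)
  expect_identical(get_weights(m1), get_weights(m2))
  expect_identical(n_params(m1), n_params(m2))
  m3 <- tiny_convnet(256L, seed = 12)
  expect_false(identical(get_weights(m1), get_weights(m3)))
})

test_that("L2 penalty is zero exactly when the coefficient is zero", {
  m0 <- tiny_convnet(256L, l2 = 0)
  expect_identical(forcepoint:::l2_penalty(m0$layers), 0)
  m1 <- tiny_convnet(256L, l2 = 1e-4)
  expect_gt(forcepoint:::l2_penalty(m1$layers), 0)
})

test_that("a zeroed residual block with identity shortcut is relu(x)", {
  set.seed(3)
  blk <- forcepoint:::make_block(8L, 2L, stride = 1L)   # cin == 4*cmid
  expect_null(blk$shortcut)
  for (ly in blk$main) {
    if (ly$type == "conv") { ly$W[] <- 0; if (!is.null(ly$b)) ly$b[] <- 0 }
    if (ly$type == "bn") { ly$gamma[] <- 0; ly$beta[] <- 0 }
  }
  x <- matrix(rnorm(2 * 16 * 8), 2 * 16, 8)
  out <- forcepoint:::fwd_block(blk, x, B = 2L, L = 16L, training = TRUE)$out
  expect_equal(out, pmax(x, 0), tolerance = 1e-12)
})

test_that("the deep residual network matches its bottleneck plan", {
  m <- build_resnet50_1d(resnet_spec(), input_length = 256, seed = 0)
  cen <- layer_census(m)
  expect_identical(cen$n_blocks_per_stage, c(3L, 4L, 6L, 3L))
  expect_identical(cen$n_bottleneck_convs, 3L * (3L + 4L + 6L + 3L))
  expect_identical(cen$n_projection_shortcuts, 4L)
  expect_true(cen$stem)
  expect_identical(cen$head_units, 1L)
  # constant across builds
  expect_identical(layer_census(build_resnet50_1d(resnet_spec(),
                                                  input_length = 256,
                                                  seed = 9)), cen)
})

test_that("inference is a pure function of weights and input", {
  mr <- build_resnet50_1d(resnet_spec(stage_block_counts = c(1, 1),
                                      base_filters = 4),
                          input_length = 128, seed = 5)
  x <- matrix(runif(2 * 128), 2, 128)
  o1 <- model_forward(mr, x)
  o2 <- model_forward(mr, x)
  expect_identical(o1, o2)
  # training mode updates bn running stats, inference must not
  w0 <- get_weights(mr)
  invisible(model_forward(mr, x, training = FALSE))
  expect_identical(get_weights(mr), w0)
})

test_that("gradients match finite differences on micro networks", {
  fd_worst <- function(model, B = 3L, eps = 1e-6) {
    L <- model$input_length
    set.seed(7)
    x <- matrix(runif(B * L), B, L)
    y <- runif(B)
    x0 <- matrix(as.vector(t(x)), B * L, 1L)
    loss <- function() {
      fw <- forcepoint:::seq_forward(model$layers, x0, B, L, training = TRUE)
      mean((drop(fw$out) - y)^2) + forcepoint:::l2_penalty(model$layers)
    }
    fw <- forcepoint:::seq_forward(model$layers, x0, B, L, training = TRUE)
    dout <- matrix(2 * (drop(fw$out) - y) / B, B, 1L)
    forcepoint:::seq_backward(model$layers, fw$caches, dout, B)
    worst <- 0
    for (r in forcepoint:::param_refs(model$layers)) {
      g <- r$e[[paste0("g", r$n)]]
      for (ii in sample(length(g), min(3, length(g)))) {
        w0 <- r$e[[r$n]][ii]
        r$e[[r$n]][ii] <- w0 + eps; lp <- loss()
        r$e[[r$n]][ii] <- w0 - eps; lm <- loss()
        r$e[[r$n]][ii] <- w0
        fd <- (lp - lm) / (2 * eps)
        if (abs(fd) < 1e-7 && abs(g[ii]) < 1e-7) next  # degenerate params
        worst <- max(worst, abs(fd - g[ii]) / (abs(fd) + abs(g[ii])))
      }
    }
    worst
  }
  m <- build_convnet1d(convnet_spec(n_blocks = 2, filters = c(3, 4),
                                    kernel_sizes = c(5, 3),
                                    pool_sizes = c(4, 4), dense_units = 6,
                                    l2_strength = 0),
                       input_length = 64, seed = 1)
  expect_lt(fd_worst(m), 1e-6)
  ml2 <- build_convnet1d(convnet_spec(n_blocks = 2, filters = c(3, 4),
                                      kernel_sizes = c(5, 3),
                                      pool_sizes = c(4, 4), dense_units = 6,
                                      l2_strength = 1e-3),
                         input_length = 64, seed = 1)
  expect_lt(fd_worst(ml2), 1e-5)
  mr <- build_resnet50_1d(resnet_spec(stage_block_counts = c(1, 1),
                                      base_filters = 2),
                          input_length = 32, seed = 2)
  expect_lt(fd_worst(mr), 1e-5)
})

test_that("gradients reach the stem of the residual network", {
  mr <- build_resnet50_1d(resnet_spec(stage_block_counts = c(1, 1),
                                      base_filters = 4),
                          input_length = 128, seed = 4)
  B <- 2L; L <- 128L
  set.seed(1)
  x0 <- matrix(runif(B * L), B * L, 1L)
  fw <- forcepoint:::seq_forward(mr$layers, x0, B, L, training = TRUE)
  dout <- matrix(2 * (drop(fw$out) - c(0.3, 0.7)) / B, B, 1L)
  forcepoint:::seq_backward(mr$layers, fw$caches, dout, B)
  stem <- mr$layers[[1]]
  expect_identical(stem$type, "conv")
  expect_gt(sqrt(sum(stem$gW^2)), 0)
})

test_that("architecture specs round-trip through YAML", {
  dir <- withr::local_tempdir()
  sp <- convnet_spec(n_blocks = 2L, filters = c(4L, 8L),
                     kernel_sizes = c(7L, 5L), pool_sizes = c(4L, 4L),
                     dense_units = 16L, l2_strength = 1e-3)
  p1 <- file.path(dir, "conv.yaml")
  write_spec(sp, p1)
  expect_equal(read_spec(p1), sp)
  rs <- resnet_spec(l2_strength = 1e-5)
  p2 <- file.path(dir, "res.yaml")
  write_spec(rs, p2)
  expect_equal(read_spec(p2), rs)
})

test_that("models survive a save/load round trip", {
  dir <- withr::local_tempdir()
  m <- tiny_convnet(256L, seed = 6)
  x <- matrix(runif(2 * 256), 2, 256)
  path <- file.path(dir, "m.rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(model_forward(back, x), model_forward(m, x))
})
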