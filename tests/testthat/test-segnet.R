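# Segmentation network: reference convolution semantics, sub-pixel
# upsampling, model construction, prediction and training.

test_that("1-D dilated convolution matches its defining sum", {
  expect_equal(dilated_conv_1d(1:5, c(1, 1), rate = 1), c(5, 7, 9))
  expect_equal(dilated_conv_1d(1:5, c(1, 1), rate = 2), 8)
  # single-tap kernel shifts the signal by the rate
  x <- rnorm(20)
  expect_equal(dilated_conv_1d(x, 1, rate = 3), x[4:20])
  expect_error(dilated_conv_1d(1:4, c(1, 1, 1), rate = 2), "shorter")
  # 100 random instances against an independent double loop
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    K <- sample(1:4, 1)
    r <- sample(1:3, 1)
    if (n - r * K < 1) next
    x <- rnorm(n)
    w <- rnorm(K)
    expect_equal(dilated_conv_1d(x, w, r), brute_dilated_1d(x, w, r),
                 tolerance = 1e-10)
  }
})

test_that("2-D dilated convolution is centered, padded and linear", {
  set.seed(32)
  f <- matrix(rnorm(25), 5, 5)
  kern <- matrix(rnorm(9), 3, 3)
  # rate 1 equals brute-force ordinary convolution
  expect_equal(dilated_conv_2d(f, kern, 1), brute_dilated_2d(f, kern, 1),
               tolerance = 1e-12)
  # higher rates against the same oracle
  f2 <- matrix(rnorm(81), 9, 9)
  expect_equal(dilated_conv_2d(f2, kern, 2), brute_dilated_2d(f2, kern, 2),
               tolerance = 1e-12)
  # delta kernel is the identity at any rate
  delta <- matrix(0, 3, 3)
  delta[2, 2] <- 1
  for (r in c(1, 2, 4)) expect_equal(dilated_conv_2d(f2, delta, r), f2)
  # linearity in the input
  g2 <- matrix(rnorm(81), 9, 9)
  expect_equal(dilated_conv_2d(2 * f2 + 3 * g2, kern, 2),
               2 * dilated_conv_2d(f2, kern, 2) +
                 3 * dilated_conv_2d(g2, kern, 2),
               tolerance = 1e-10)
  expect_error(dilated_conv_2d(f, matrix(0, 2, 2), 1), "even kernel")
})

test_that("sub-pixel upsampling is the stated bijective rearrangement", {
  # the defining example: one coarse pixel, r = 2
  f <- array(c(10, 20, 30, 40), c(1, 1, 4))
  up <- multichannel_upsample(f, 2)
  expect_equal(up[, , 1], matrix(c(10, 20, 30, 40), 2, 2, byrow = TRUE))
  # r = 1 is the identity
  g <- array(rnorm(3 * 5 * 6), c(3, 5, 6))
  expect_equal(multichannel_upsample(g, 1), g)
  # shape arithmetic
  h <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
  expect_equal(dim(multichannel_upsample(h, 2)), c(6, 10, 2))
  # bijection: inverse . forward = identity; entries conserved
  set.seed(33)
  for (i in 1:5) {
    r <- sample(1:4, 1)
    cc <- sample(1:3, 1)
    hh <- sample(1:4, 1)
    ww <- sample(1:4, 1)
    x <- array(rnorm(hh * ww * r * r * cc), c(hh, ww, r * r * cc))
    y <- multichannel_upsample(x, r)
    expect_equal(multichannel_downsample(y, r), x)
    expect_equal(sum(y), sum(x))
    expect_equal(sort(as.vector(y)), sort(as.vector(x)))
  }
  expect_error(multichannel_upsample(array(0, c(2, 2, 3)), 2), "divisible")
})

test_that("model construction honours shapes, seeds and presets", {
  cfg <- model_config("tiny", seed = 4)
  m <- build_model(cfg)
  img <- array(runif(96 * 96 * 3, 0, 255), c(96, 96, 3))
  out <- predict_patch(m, img, return_scores = TRUE)
  expect_equal(dim(out$scores), c(96, 96, 3))
  expect_equal(dim(out$mask), c(96, 96))
  # same config + seed gives identical parameters and outputs
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)
  expect_identical(predict_patch(m2, img), out$mask)
  # full preset has more parameters than tiny
  expect_gt(n_params(build_model(model_config("full"))), n_params(m))
  # input not divisible by the output stride is rejected
  expect_error(predict_patch(m, array(0, c(95, 96, 3))), "divisible")
  expect_error(model_config(decoder_rates = c(1, 2)), "4 parallel")
})

test_that("prediction is the argmax of the returned scores", {
  cfg <- model_config("tiny", seed = 4)
  m <- build_model(cfg)
  img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
  out <- predict_patch(m, img, return_scores = TRUE)
  s <- matrix(out$scores, 32 * 32, 3)
  expect_equal(as.vector(out$mask), max.col(s, ties.method = "first") - 1L)
  # constant bias forcing class 2 makes everything stroma
  forced <- m
  for (d in 1:4) {
    nm <- paste0("dec", d)
    b <- forced$params[[nm]]$b
    ncls <- 3
    r2 <- cfg$r^2
    # channel blocks are laid out with the class as the slowest index
    b[seq((ncls - 1) * r2 + 1, ncls * r2)] <- 1e6
    forced$params[[nm]]$b <- b
  }
  expect_true(all(predict_patch(forced, img) == 2L))
})

test_that("training overfits one sample and zero epochs is a no-op", {
  ds <- generate_patch_dataset(1, 64, 64, c(0.4, 0.6), seed = 21)
  m <- build_model(model_config("tiny", seed = 3))
  fit0 <- train_model(m, ds, train_config(epochs = 0, seed = 1))
  expect_identical(fit0$model$params, m$params)
  expect_equal(nrow(fit0$history), 0)
  fit <- train_model(m, ds, train_config(epochs = 60, lr = 0.05,
                                         mirror = FALSE, seed = 1))
  acc <- mean(predict_patch(fit$model, ds[[1]]$image) == ds[[1]]$mask)
  expect_gte(acc, 0.95)
  # same seed reproduces the same trained parameters
  fit2 <- train_model(m, ds, train_config(epochs = 60, lr = 0.05,
                                          mirror = FALSE, seed = 1))
  expect_identical(fit$model$params, fit2$model$params)
  expect_error(train_model(m, list(), train_config()), "empty")
})

test_that("mirroring a left-right symmetric sample leaves the loss unchanged", {
  ds <- generate_patch_dataset(1, 32, 32, c(0.5, 0.5), seed = 8)
  img <- ds[[1]]$image
  mask <- ds[[1]]$mask
  # symmetrize the sample about the vertical axis
  img_sym <- (img + img[, 32:1, , drop = FALSE]) / 2
  mask_sym <- mask
  mask_sym[, 17:32] <- mask_sym[, 16:1]
  m <- build_model(model_config("tiny", seed = 3))
  loss_of <- function(im, mk) {
    fwd <- epistroma:::segnet_forward(m, im)
    epistroma:::softmax_ce(fwd$logits, mk)$loss
  }
  expect_equal(loss_of(img_sym, mask_sym),
               loss_of(img_sym[, 32:1, , drop = FALSE],
                       mask_sym[, 32:1, drop = FALSE]),
               tolerance = 1e-10)
})

test_that("cross-validation partitions the dataset into disjoint folds", {
  ds <- generate_patch_dataset(4, 32, 32, c(0.3, 0.7), seed = 5)
  cv <- cross_validate(ds, model_config("tiny", seed = 2),
                       train_config(epochs = 1, folds = 2, seed = 9))
  test_sets <- lapply(cv$folds, `[[`, "test_idx")
  expect_setequal(unlist(test_sets), 1:4)
  expect_length(intersect(test_sets[[1]], test_sets[[2]]), 0)
  expect_error(cross_validate(ds, model_config("tiny"),
                              train_config(folds = 5)), "folds")
})
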