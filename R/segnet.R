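# Dilated-convolution encoder-decoder segmentation network.
#
# The encoder is a small convolutional stem (stride-2 convolutions, total
# stride r) followed by dilated residual blocks, each block a sequence of
# ResUnits y = relu(x + conv_rate(x)) with per-unit dilation rates. The
# decoder applies four parallel dilated convolutions, each producing
# r^2 * n_classes channels, rearranges each with sub-pixel (multi-channel)
# upsampling back to full resolution, and sums the four branches pixelwise
# to obtain class scores. Training minimises mean per-pixel softmax
# cross-entropy with SGD + momentum; forward/backward passes run on
# compiled im2col kernels.

#' Dilated convolution of a 1-D signal (reference semantics)
#'
#' Literal valid-mode dilated convolution:
#' `y[i] = sum_{k=1..K} x[i + r*k] * w[k]` for every `i` with all taps in
#' range. This is the reference semantics against which the network's 2-D
#' layers are checked; no padding, no centering.
#'
#' @param x Numeric input signal.
#' @param w Numeric kernel of length `K`.
#' @param rate Positive integer sampling stride `r` between kernel taps.
#' @return Numeric vector of length `length(x) - rate * length(w)`.
#' @export
dilated_conv_1d <- function(x, w, rate = 1L) {
  stopifnot(is.numeric(x), is.numeric(w), length(w) >= 1,
            rate >= 1, rate == round(rate))
  n <- length(x)
  K <- length(w)
  n_out <- n - rate * K
  if (n_out < 1) stop("input shorter than the kernel span")
  y <- numeric(n_out)
  i <- seq_len(n_out)
  for (k in seq_len(K)) y <- y + x[i + rate * k] * w[k]
  y
}

#' Centered zero-padded 2-D dilated convolution
#'
#' Dimension-preserving dilated convolution of a single-channel image with
#' an odd square kernel: the kernel is centered on each pixel with taps
#' `rate` pixels apart and out-of-image taps read as zero. At `rate = 1`
#' this is ordinary (cross-correlation-convention) convolution; the
#' effective span per axis is `K + (K-1)*(rate-1)`.
#'
#' @param f Numeric matrix.
#' @param kernel Odd-sized square numeric matrix.
#' @param rate Positive integer dilation rate.
#' @return Matrix of the same dimensions as `f`.
#' @export
dilated_conv_2d <- function(f, kernel, rate = 1L) {
  stopifnot(is.matrix(f), is.matrix(kernel),
            nrow(kernel) == ncol(kernel), rate >= 1)
  k <- nrow(kernel)
  if (k %% 2 == 0) stop("even kernel sizes are rejected: centering undefined")
  pad <- as.integer(rate * (k - 1) / 2)
  .conv2d_fwd(array(f, c(dim(f), 1)),
              matrix(as.vector(kernel), ncol = 1), 0,
              as.integer(k), as.integer(rate), 1L, pad)[, , 1]
}

#' Sub-pixel (multi-channel) upsampling
#'
#' Pure rearrangement of a `h x w x (r^2 * c)` feature map into
#' `(h*r) x (w*r) x c`: the channel block `(p, q)` (row-major, 0-based) of
#' pixel `(i, j)` moves to output pixel `(i*r + p, j*r + q)`. Each coarse
#' pixel's `r^2 * c` channels therefore populate a fixed `r x r` output
#' area. The map is a bijection of entries; [multichannel_downsample()] is
#' its inverse.
#'
#' @param f Numeric array `h x w x (r^2 * c)`.
#' @param r Positive integer upsampling rate.
#' @return Numeric array `(h*r) x (w*r) x c`.
#' @export
multichannel_upsample <- function(f, r) {
  stopifnot(is.array(f), length(dim(f)) == 3, r >= 1, r == round(r))
  r <- as.integer(r)
  h <- dim(f)[1]
  w <- dim(f)[2]
  ch <- dim(f)[3]
  if (ch %% (r * r) != 0) {
    stop("channel count ", ch, " is not divisible by r^2 = ", r * r)
  }
  cc <- ch %/% (r * r)
  a <- array(f, c(h, w, r, r, cc))          # dims: i, j, q, p, c
  array(aperm(a, c(4, 1, 3, 2, 5)), c(h * r, w * r, cc))
}

#' Inverse of sub-pixel upsampling
#'
#' @param y Numeric array `(h*r) x (w*r) x c`.
#' @param r Positive integer rate used for the forward rearrangement.
#' @return Numeric array `h x w x (r^2 * c)`.
#' @export
multichannel_downsample <- function(y, r) {
  stopifnot(is.array(y), length(dim(y)) == 3, r >= 1)
  r <- as.integer(r)
  if (any(dim(y)[1:2] %% r != 0)) {
    stop("spatial dimensions must be divisible by r")
  }
  h <- dim(y)[1] %/% r
  w <- dim(y)[2] %/% r
  cc <- dim(y)[3]
  a <- array(y, c(r, h, r, w, cc))          # dims: p, i, q, j, c
  array(aperm(a, c(2, 4, 3, 1, 5)), c(h, w, r * r * cc))
}

#' Configure the segmentation network
#'
#' Two presets. `"tiny"` (output stride r = 4): a two-convolution stem, one
#' dilated block of four ResUnits with rates (1, 2, 4, 8) at 12 channels,
#' and decoder branch rates (1, 2, 4, 8); it forward-passes a 96 x 96 patch
#' on one CPU in well under a second and is the preset the test-scale
#' experiments use. `"full"` (r = 8): a three-convolution stem and six
#' dilated blocks of four ResUnits each at 64 channels, mirroring a
#' residual-backbone encoder with a multi-scale dilated decoder. All pieces
#' are overridable.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param n_classes Number of output classes (3: background, epithelium,
#'   stroma).
#' @param stem List of stem layers, each `list(k, out, stride)`.
#' @param block_rates List of numeric vectors, one per dilated block, giving
#'   each ResUnit's dilation rate.
#' @param channels Channel width of the dilated blocks.
#' @param decoder_rates Exactly four decoder branch dilation rates.
#' @param seed Seed for parameter initialization.
#' @return An object of class `"segnet_config"`.
#' @export
model_config <- function(preset = c("tiny", "full"), n_classes = 3L,
                         stem = NULL, block_rates = NULL, channels = NULL,
                         decoder_rates = c(1L, 2L, 4L, 8L), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    if (is.null(stem)) {
      stem <- list(list(k = 3L, out = 8L, stride = 2L),
                   list(k = 3L, out = 12L, stride = 2L))
    }
    if (is.null(block_rates)) block_rates <- list(c(1, 2, 4, 8))
    if (is.null(channels)) channels <- 12L
  } else {
    if (is.null(stem)) {
      stem <- list(list(k = 7L, out = 32L, stride = 2L),
                   list(k = 3L, out = 48L, stride = 2L),
                   list(k = 3L, out = 64L, stride = 2L))
    }
    if (is.null(block_rates)) block_rates <- rep(list(c(1, 2, 4, 8)), 6)
    if (is.null(channels)) channels <- 64L
  }
  if (length(decoder_rates) != 4) {
    stop("the decoder has exactly 4 parallel branches")
  }
  r <- prod(vapply(stem, `[[`, numeric(1), "stride"))
  if (stem[[length(stem)]]$out != channels) {
    stem[[length(stem)]]$out <- as.integer(channels)
  }
  structure(list(preset = preset, n_classes = as.integer(n_classes),
                 stem = stem, block_rates = block_rates,
                 channels = as.integer(channels),
                 decoder_rates = as.integer(decoder_rates),
                 r = as.integer(r), seed = as.integer(seed)),
            class = "segnet_config")
}

init_conv <- function(k, cin, cout, scheme = c("he", "xavier")) {
  scheme <- match.arg(scheme)
  n <- k * k * cin * cout
  w <- if (scheme == "he") {
    rnorm(n, 0, sqrt(2 / (k * k * cin)))
  } else {
    lim <- sqrt(6 / (k * k * cin + k * k * cout))
    runif(n, -lim, lim)
  }
  list(w = array(w, c(k, k, cin, cout)), b = numeric(cout))
}

#' Build the segmentation network
#'
#' Initializes all parameters deterministically from `config$seed`: stem
#' and block convolutions with He-scaled Gaussian weights (or, optionally,
#' weights loaded from an external file), decoder branches with the Xavier
#' uniform scheme. The model maps an `H x W x 3` RGB patch (dimensions
#' divisible by `config$r`) to `H x W x n_classes` scores.
#'
#' @param config A [model_config()].
#' @param weights_file Optional path to an RDS file of pre-trained
#'   parameters (named as in `model$params`); entries with matching
#'   dimensions replace the random initialization.
#' @return An object of class `"segnet_model"`.
#' @export
build_model <- function(config, weights_file = NULL) {
  stopifnot(inherits(config, "segnet_config"))
  params <- list()
  with_seed(config$seed, {
    cin <- 3L
    for (i in seq_along(config$stem)) {
      s <- config$stem[[i]]
      params[[paste0("stem", i)]] <- c(init_conv(s$k, cin, s$out, "he"),
                                       list(k = s$k, rate = 1L,
                                            stride = s$stride,
                                            pad = (s$k - 1L) %/% 2L))
      cin <- s$out
    }
    ch <- config$channels
    for (b in seq_along(config$block_rates)) {
      for (u in seq_along(config$block_rates[[b]])) {
        rate <- as.integer(config$block_rates[[b]][u])
        params[[sprintf("b%du%d", b, u)]] <-
          c(init_conv(3L, ch, ch, "he"),
            list(k = 3L, rate = rate, stride = 1L, pad = rate))
      }
    }
    cout <- config$r^2 * config$n_classes
    for (d in 1:4) {
      rate <- config$decoder_rates[d]
      params[[paste0("dec", d)]] <-
        c(init_conv(3L, ch, cout, "xavier"),
          list(k = 3L, rate = rate, stride = 1L, pad = rate))
    }
  })
  if (!is.null(weights_file)) {
    pre <- readRDS(weights_file)
    for (nm in intersect(names(pre), names(params))) {
      if (!identical(dim(pre[[nm]]$w), dim(params[[nm]]$w))) {
        stop("pre-trained weights for ", nm, " have incompatible shape")
      }
      params[[nm]]$w <- pre[[nm]]$w
      params[[nm]]$b <- pre[[nm]]$b
    }
  }
  structure(list(config = config, params = params), class = "segnet_model")
}

#' @export
print.segnet_model <- function(x, ...) {
  cat(sprintf(
    "segmentation network (%s preset): %d blocks, r = %d, %d parameters\n",
    x$config$preset, length(x$config$block_rates), x$config$r, n_params(x)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model A [build_model()] network.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

layer_fwd <- function(x, p) {
  .conv2d_fwd(x, matrix(p$w, ncol = dim(p$w)[4]), p$b,
              as.integer(p$k), as.integer(p$rate), as.integer(p$stride),
              as.integer(p$pad))
}

# Forward pass; input raw 0-255 RGB. Returns logits and (optionally) the
# caches needed for backprop.
segnet_forward <- function(model, img, want_cache = FALSE) {
  cfg <- model$config
  if (any(dim(img)[1:2] %% cfg$r != 0)) {
    stop("patch dimensions must be divisible by the output stride r = ",
         cfg$r)
  }
  x <- img / 255 - 0.5   # center: stain contrasts, not brightness, carry signal
  cache <- list()
  for (i in seq_along(cfg$stem)) {
    nm <- paste0("stem", i)
    z <- layer_fwd(x, model$params[[nm]])
    if (want_cache) cache[[nm]] <- list(xin = x, pre = z)
    x <- pmax(z, 0)
  }
  for (b in seq_along(cfg$block_rates)) {
    for (u in seq_along(cfg$block_rates[[b]])) {
      nm <- sprintf("b%du%d", b, u)
      z <- layer_fwd(x, model$params[[nm]])
      a <- x + z
      if (want_cache) cache[[nm]] <- list(xin = x, pre = a)
      x <- pmax(a, 0)
    }
  }
  logits <- 0
  for (d in 1:4) {
    nm <- paste0("dec", d)
    z <- layer_fwd(x, model$params[[nm]])
    logits <- logits + multichannel_upsample(z, cfg$r)
  }
  if (want_cache) cache[["enc_out"]] <- x
  list(logits = logits, cache = cache)
}

# Mean per-pixel softmax cross-entropy and its gradient w.r.t. the logits.
softmax_ce <- function(logits, mask) {
  n <- prod(dim(logits)[1:2])
  L <- matrix(logits, n, dim(logits)[3])
  L <- L - apply(L, 1, max)
  e <- exp(L)
  p <- e / rowSums(e)
  y <- as.vector(mask) + 1L
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = array(g / n, dim(logits)),
       pred = max.col(p, ties.method = "first") - 1L)
}

layer_bwd <- function(p, xin, gout) {
  .conv2d_bwd(xin, matrix(p$w, ncol = dim(p$w)[4]), gout,
              as.integer(p$k), as.integer(p$rate), as.integer(p$stride),
              as.integer(p$pad))
}

# Backward pass: gradient of the loss w.r.t. every parameter.
segnet_backward <- function(model, fwd, dlogits) {
  cfg <- model$config
  grads <- list()
  x_enc <- fwd$cache[["enc_out"]]
  g <- 0
  for (d in 1:4) {
    nm <- paste0("dec", d)
    gz <- multichannel_downsample(dlogits, cfg$r)
    bw <- layer_bwd(model$params[[nm]], x_enc, gz)
    grads[[nm]] <- list(w = array(bw$gw, dim(model$params[[nm]]$w)),
                        b = as.numeric(bw$gb))
    g <- g + bw$gx
  }
  for (b in rev(seq_along(cfg$block_rates))) {
    for (u in rev(seq_along(cfg$block_rates[[b]]))) {
      nm <- sprintf("b%du%d", b, u)
      cc <- fwd$cache[[nm]]
      ga <- g * (cc$pre > 0)
      bw <- layer_bwd(model$params[[nm]], cc$xin, ga)
      grads[[nm]] <- list(w = array(bw$gw, dim(model$params[[nm]]$w)),
                          b = as.numeric(bw$gb))
      g <- ga + bw$gx
    }
  }
  for (i in rev(seq_along(cfg$stem))) {
    nm <- paste0("stem", i)
    cc <- fwd$cache[[nm]]
    gz <- g * (cc$pre > 0)
    bw <- layer_bwd(model$params[[nm]], cc$xin, gz)
    grads[[nm]] <- list(w = array(bw$gw, dim(model$params[[nm]]$w)),
                        b = as.numeric(bw$gb))
    g <- bw$gx
  }
  grads
}

#' Segment a patch
#'
#' Runs the network on an RGB patch and returns the per-pixel argmax over
#' the class scores, ties broken toward the lower class index
#' (0 = background, 1 = epithelium, 2 = stroma).
#'
#' @param model A [build_model()] network.
#' @param patch Numeric H x W x 3 RGB array (0-255) with H and W divisible
#'   by the output stride.
#' @param return_scores Also return the raw class scores.
#' @return Integer label matrix; if `return_scores`, a list
#'   `list(mask, scores)`.
#' @export
predict_patch <- function(model, patch, return_scores = FALSE) {
  stopifnot(inherits(model, "segnet_model"))
  check_rgb(patch, "patch")
  logits <- segnet_forward(model, patch)$logits
  h <- dim(logits)[1]
  w <- dim(logits)[2]
  idx <- max.col(matrix(logits, h * w, dim(logits)[3]),
                 ties.method = "first")
  mask <- matrix(as.integer(idx - 1L), h, w)
  if (return_scores) list(mask = mask, scores = logits) else mask
}

#' Training configuration
#'
#' @param epochs Passes over the training set.
#' @param lr,momentum SGD learning rate and momentum.
#' @param crop Random square crop size (pixels, divisible by the output
#'   stride), or `NULL` to train on full patches. For large annotated
#'   regions a 600 x 600 crop bounds the memory of a training step.
#' @param mirror Random horizontal mirroring.
#' @param folds Number of cross-validation folds (used by
#'   [cross_validate()]).
#' @param seed Seed for shuffling, augmentation, and fold assignment.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(epochs = 6L, lr = 0.02, momentum = 0.9,
                         crop = NULL, mirror = TRUE, folds = 5L, seed = 1L) {
  stopifnot(epochs >= 0, lr > 0, momentum >= 0, momentum < 1, folds >= 2)
  structure(list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
                 crop = if (!is.null(crop)) as.integer(crop), mirror = mirror,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "train_config")
}

augment_sample <- function(img, mask, tc, r) {
  if (isTRUE(tc$mirror) && runif(1) < 0.5) {
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (!is.null(tc$crop) && (tc$crop < nrow(mask) || tc$crop < ncol(mask))) {
    if (tc$crop %% r != 0) stop("crop size must be divisible by r")
    if (tc$crop > nrow(mask) || tc$crop > ncol(mask)) {
      stop("crop larger than the training patch")
    }
    r0 <- sample.int(nrow(mask) - tc$crop + 1L, 1) - 1L
    c0 <- sample.int(ncol(mask) - tc$crop + 1L, 1) - 1L
    img <- img[(r0 + 1):(r0 + tc$crop), (c0 + 1):(c0 + tc$crop), ,
               drop = FALSE]
    mask <- mask[(r0 + 1):(r0 + tc$crop), (c0 + 1):(c0 + tc$crop),
                 drop = FALSE]
  }
  list(image = img, mask = mask)
}

#' Train the segmentation network
#'
#' Minimises mean per-pixel softmax cross-entropy over the three classes by
#' SGD with momentum, one patch per step, with random mirror / random crop
#' augmentation. Deterministic given `tc$seed`. With `epochs = 0` the model
#' is returned unchanged.
#'
#' @param model A [build_model()] network.
#' @param dataset Non-empty list of `list(image, mask)` pairs (e.g. from
#'   [generate_patch_dataset()]).
#' @param tc A [train_config()].
#' @return List with the trained `model` and a `history` data frame of
#'   per-epoch mean loss and training pixel accuracy.
#' @export
train_model <- function(model, dataset, tc = train_config()) {
  stopifnot(inherits(model, "segnet_model"), inherits(tc, "train_config"))
  if (length(dataset) == 0) stop("empty training dataset")
  if (tc$epochs == 0) {
    return(list(model = model,
                history = data.frame(epoch = integer(0), loss = numeric(0),
                                     accuracy = numeric(0))))
  }
  vel <- lapply(model$params, function(p)
    list(w = array(0, dim(p$w)), b = numeric(length(p$b))))
  history <- data.frame(epoch = seq_len(tc$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample(length(dataset))
      tot_loss <- 0
      tot_correct <- 0
      tot_px <- 0
      for (s in ord) {
        smp <- augment_sample(dataset[[s]]$image, dataset[[s]]$mask, tc,
                              model$config$r)
        fwd <- segnet_forward(model, smp$image, want_cache = TRUE)
        ce <- softmax_ce(fwd$logits, smp$mask)
        grads <- segnet_backward(model, fwd, ce$grad)
        for (nm in names(model$params)) {
          vel[[nm]]$w <- tc$momentum * vel[[nm]]$w - tc$lr * grads[[nm]]$w
          vel[[nm]]$b <- tc$momentum * vel[[nm]]$b - tc$lr * grads[[nm]]$b
          model$params[[nm]]$w <- model$params[[nm]]$w + vel[[nm]]$w
          model$params[[nm]]$b <- model$params[[nm]]$b + vel[[nm]]$b
        }
        tot_loss <- tot_loss + ce$loss
        tot_correct <- tot_correct + sum(ce$pred == as.vector(smp$mask))
        tot_px <- tot_px + length(smp$mask)
      }
      history$loss[ep] <- tot_loss / length(dataset)
      history$accuracy[ep] <- tot_correct / tot_px
    }
  })
  list(model = model, history = history)
}

#' Cross-validate the segmentation network
#'
#' Seeded partition of the dataset into `tc$folds` disjoint folds; each fold
#' is held out once, the network is trained from scratch on the rest, and
#' held-out pixels are scored (pooled pixel accuracy plus the full
#' confusion-metric suite for each tissue class as the positive label).
#'
#' @param dataset List of `list(image, mask)` pairs, at least `tc$folds`
#'   long.
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @return List with per-fold results (`fold`, `test_idx`, `accuracy`,
#'   `metrics_epi`, `metrics_stro`) and `mean_accuracy`.
#' @export
cross_validate <- function(dataset, config, tc = train_config()) {
  n <- length(dataset)
  if (n < tc$folds) stop("more folds than samples")
  fold_id <- with_seed(tc$seed, sample(rep_len(seq_len(tc$folds), n)))
  res <- lapply(seq_len(tc$folds), function(f) {
    test_idx <- which(fold_id == f)
    fit <- train_model(build_model(config), dataset[-test_idx],
                       train_config(epochs = tc$epochs, lr = tc$lr,
                                    momentum = tc$momentum, crop = tc$crop,
                                    mirror = tc$mirror, folds = tc$folds,
                                    seed = tc$seed + f))
    correct <- 0
    total <- 0
    conf_epi <- conf_stro <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (i in test_idx) {
      pred <- predict_patch(fit$model, dataset[[i]]$image)
      truth <- dataset[[i]]$mask
      correct <- correct + sum(pred == truth)
      total <- total + length(truth)
      ce <- confusion(pred, truth, positive_label = 1L)
      cs <- confusion(pred, truth, positive_label = 2L)
      conf_epi <- conf_epi + unlist(ce)[names(conf_epi)]
      conf_stro <- conf_stro + unlist(cs)[names(conf_stro)]
    }
    list(fold = f, test_idx = test_idx, accuracy = correct / total,
         metrics_epi = compute_metrics(as.list(conf_epi)),
         metrics_stro = compute_metrics(as.list(conf_stro)))
  })
  acc <- vapply(res, `[[`, numeric(1), "accuracy")
  list(folds = res, mean_accuracy = mean(acc))
}

#' Save / load a trained network
#'
#' Serializes the model (parameters plus embedded configuration) to a
#' single portable file.
#'
#' @param model A [build_model()] network.
#' @param path File path.
#' @return `load_model()` returns the `"segnet_model"`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "segnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "segnet_model")) stop("not a serialized segnet model")
  m
}
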