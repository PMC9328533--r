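test_that("per-pixel probabilities normalise for random weights and inputs", {
  for (i in 1:3) {
    m <- build_unet(unet_spec(depth = 2, base_filters = 4), seed = i)
    set.seed(i)
    img <- array(runif(32 * 32 * 3) * 255, c(32, 32, 3))
    pr <- predict_mask(m, img)
    sums <- apply(pr$probs, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_true(all(unique(as.integer(pr$mask)) %in% 0:2))
  }
})

test_that("encoder feature sizes mirror the decoder level-for-level", {
  sz <- unet_feature_sizes(unet_spec(depth = 4), 64)
  expect_identical(sz$encoder, c(64, 32, 16, 8, 4))
  expect_identical(sz$decoder, rev(sz$encoder))
})

test_that("incompatible input sides raise a shape error", {
  expect_error(unet_feature_sizes(unet_spec(depth = 4), 60), "divisible")
  m <- build_unet(unet_spec(depth = 4, base_filters = 2), seed = 1)
  img <- array(runif(60 * 60 * 3), c(60, 60, 3))
  expect_error(predict_mask(m, img), "divisible")
})

test_that("zero logits break argmax ties toward the lowest class id", {
  m <- build_unet(unet_spec(depth = 2, base_filters = 4), seed = 1)
  zero <- function(p) { p$W[] <- 0; p$b[] <- 0; p }
  m$params$head <- zero(m$params$head)     # uniform output probabilities
  img <- tiny_scene(seed = 1, h = 32, w = 32)$image
  pr <- predict_mask(m, img)
  expect_true(all(pr$mask == 0L))
  expect_equal(max(abs(pr$probs - 1 / 3)), 0, tolerance = 1e-12)
})

test_that("a short training run reduces the training loss", {
  tr <- make_pairs(12, h = 32, w = 32, seed0 = 100)
  va <- make_pairs(3, h = 32, w = 32, seed0 = 900)
  m <- build_unet(unet_spec(depth = 2, base_filters = 6,
                            dropout_rate = 0.2), seed = 2)
  res <- train_model(m, tr, va,
                     train_config(batch_size = 4, learning_rate = 2e-3,
                                  optimizer = "adam", max_epochs = 5,
                                  early_stop_patience = 4, seed = 2))
  h <- res$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  expect_identical(nrow(h), attr(h, "stopped_epoch"))
  expect_identical(names(h), c("epoch", "train_loss", "val_loss",
                               "train_acc", "val_acc"))
})

test_that("training stops early when validation loss cannot improve", {
  tr <- make_pairs(4, h = 32, w = 32, seed0 = 200)
  va <- make_pairs(2, h = 32, w = 32, seed0 = 950)
  m <- build_unet(unet_spec(depth = 2, base_filters = 4,
                            dropout_rate = 0), seed = 3)
  # a vanishing learning rate makes every epoch a non-improvement
  res <- train_model(m, tr, va,
                     train_config(batch_size = 4, learning_rate = 1e-12,
                                  optimizer = "sgd", momentum = 0,
                                  max_epochs = 30, early_stop_patience = 2,
                                  seed = 3))
  expect_lt(attr(res$history, "stopped_epoch"), 30)
  expect_lte(attr(res$history, "stopped_epoch"), 1 + 2)
})

test_that("training is reproducible for a fixed seed", {
  tr <- make_pairs(4, h = 32, w = 32, seed0 = 300)
  va <- make_pairs(2, h = 32, w = 32, seed0 = 960)
  cfg <- train_config(batch_size = 2, learning_rate = 1e-3,
                      optimizer = "adam", max_epochs = 2,
                      early_stop_patience = 1, seed = 5)
  m <- build_unet(unet_spec(depth = 2, base_filters = 4,
                            dropout_rate = 0.3), seed = 5)
  r1 <- train_model(m, tr, va, cfg)
  r2 <- train_model(m, tr, va, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("dropout-active training neither crashes nor produces NaN", {
  tr <- make_pairs(4, h = 32, w = 32, seed0 = 400)
  va <- make_pairs(2, h = 32, w = 32, seed0 = 970)
  m <- build_unet(unet_spec(depth = 2, base_filters = 4,
                            dropout_rate = 0.5), seed = 7)
  res <- train_model(m, tr, va,
                     train_config(batch_size = 4, learning_rate = 1e-3,
                                  optimizer = "adam", max_epochs = 3,
                                  early_stop_patience = 2, seed = 7))
  expect_true(all(is.finite(unlist(res$history[2:5]))))
})

test_that("analytic conv gradients match finite differences", {
  # independent oracle: central finite differences on the loss
  set.seed(9)
  x <- array(runif(8 * 8 * 2), c(8, 8, 2))
  par <- list(W = array(rnorm(3 * 3 * 2 * 3, 0, 0.5), c(3, 3, 2, 3)),
              b = rnorm(3))
  y <- array(runif(8 * 8 * 3), c(8, 8, 3))
  loss_of <- function(p) {
    out <- svimon:::.conv_fwd(x, p, relu = TRUE)$out
    sum((out - y)^2) / 2
  }
  fw <- svimon:::.conv_fwd(x, par, relu = TRUE)
  bw <- svimon:::.conv_bwd(fw$out - y, fw$cache, par)
  eps <- 1e-5
  for (idx in list(c(1, 1, 1, 1), c(2, 3, 2, 2), c(3, 1, 1, 3))) {
    pp <- par; pm <- par
    pp$W[matrix(idx, 1)] <- pp$W[matrix(idx, 1)] + eps
    pm$W[matrix(idx, 1)] <- pm$W[matrix(idx, 1)] - eps
    num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(bw$dW[matrix(idx, 1)], num, tolerance = 1e-5)
  }
  pb <- par; pb$b[2] <- pb$b[2] + eps
  mb <- par; mb$b[2] <- mb$b[2] - eps
  expect_equal(bw$db[2], (loss_of(pb) - loss_of(mb)) / (2 * eps),
               tolerance = 1e-5)
})

test_that("model checkpoints round-trip", {
  m <- build_unet(unet_spec(depth = 2, base_filters = 4), seed = 1)
  p <- tempfile(fileext = ".rds")
  on.exit(unlink(p))
  save_model(m, p)
  expect_identical(load_model(p), m)
})
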