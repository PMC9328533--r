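#' Training hyperparameter bundle
#'
#' Defaults follow the published configuration: batch size 16, learning
#' rate 1e-4, categorical cross-entropy loss, stochastic gradient
#' descent, up to 200 epochs. `nms_threshold` is recorded for fidelity
#' with that configuration but has no role in semantic segmentation and
#' is never used. Early stopping watches validation loss and restores
#' the best weights.
#'
#' @param batch_size minibatch size.
#' @param learning_rate optimizer step size.
#' @param loss only `"categorical_crossentropy"` is supported.
#' @param optimizer `"sgd"` (with `momentum`) or `"adam"`.
#' @param momentum SGD momentum coefficient.
#' @param max_epochs epoch cap.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (must be < `max_epochs`).
#' @param nms_threshold recorded, unused (see Details).
#' @param seed seed controlling shuffling, dropout and initialisation of
#'   optimizer state.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, learning_rate = 1e-4,
                         loss = "categorical_crossentropy",
                         optimizer = c("sgd", "adam"), momentum = 0.9,
                         max_epochs = 200L, early_stop_patience = 15L,
                         nms_threshold = 0.45, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (loss != "categorical_crossentropy")
    stop("unsupported loss: ", loss, call. = FALSE)
  .assert_scalar_num(batch_size, "batch_size", 1)
  .assert_scalar_num(learning_rate, "learning_rate", 1e-12)
  .assert_scalar_num(max_epochs, "max_epochs", 1)
  .assert_scalar_num(early_stop_patience, "early_stop_patience", 1)
  if (early_stop_patience >= max_epochs)
    stop("`early_stop_patience` must be < `max_epochs`", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 optimizer = optimizer, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 nms_threshold = nms_threshold, seed = as.integer(seed)),
            class = "train_config")
}

.one_hot <- function(mask, n_classes) {
  d <- dim(mask)
  y <- array(0, c(d[1], d[2], n_classes))
  for (k in seq_len(n_classes)) y[, , k] <- (mask == (k - 1L)) * 1
  y
}

# apply an update rule leaf-by-leaf over the nested param/grad trees
.walk_update <- function(params, grads, fn, state, path = "p") {
  if (is.list(params) && !is.null(params$W)) {
    res <- fn(params, grads, state[[path]])
    state[[path]] <- res$state
    return(list(params = res$params, state = state))
  }
  idx <- if (!is.null(names(params)) && all(nzchar(names(params))))
    names(params) else seq_along(params)
  for (i in idx) {
    r <- .walk_update(params[[i]], grads[[i]], fn, state,
                      paste0(path, ".", i))
    params[[i]] <- r$params
    state <- r$state
  }
  list(params = params, state = state)
}

.add_grads <- function(a, b) {
  if (is.list(a) && !is.null(a$dW))
    return(list(dW = a$dW + b$dW, db = a$db + b$db))
  idx <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a) else
    seq_along(a)
  for (i in idx) a[[i]] <- .add_grads(a[[i]], b[[i]])
  a
}

.scale_grads <- function(a, f) {
  if (is.list(a) && !is.null(a$dW))
    return(list(dW = a$dW * f, db = a$db * f))
  idx <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a) else
    seq_along(a)
  for (i in idx) a[[i]] <- .scale_grads(a[[i]], f)
  a
}

#' Train a segmentation model
#'
#' Minibatch gradient descent on pixel-wise categorical cross-entropy.
#' Stops at `max_epochs` or when validation loss has not improved for
#' `early_stop_patience` epochs; the returned model carries the weights
#' of the best validation epoch. Reproducible for a given
#' `config$seed` on a fixed platform.
#'
#' @param model an untrained (or warm) `unet_model`.
#' @param train_pairs,val_pairs non-empty lists of [scene_pair()]
#'   objects; all frames must share one side compatible with the model.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return `list(model =, history =)`; `history` is a `train_history`
#'   data.frame with columns `epoch`, `train_loss`, `val_loss`,
#'   `train_acc`, `val_acc` and attribute `stopped_epoch`.
#' @export
train_model <- function(model, train_pairs, val_pairs, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "train_config"))
  if (length(train_pairs) == 0 || length(val_pairs) == 0)
    stop("training and validation sets must be non-empty", call. = FALSE)
  nc <- model$spec$n_classes
  prep <- function(p) list(x = p$image / 255, y = .one_hot(p$mask, nc),
                           mask = p$mask)
  tr <- lapply(train_pairs, prep)
  va <- lapply(val_pairs, prep)
  .check_side(model$spec, dim(tr[[1]]$x)[1:2])

  lr <- config$learning_rate
  opt_state <- list()
  adam_t <- 0L
  update_fn <- if (config$optimizer == "adam") {
    function(par, gr, st) {
      if (is.null(st)) st <- list(mW = par$W * 0, vW = par$W * 0,
                                  mb = par$b * 0, vb = par$b * 0)
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      st$mW <- b1 * st$mW + (1 - b1) * gr$dW
      st$vW <- b2 * st$vW + (1 - b2) * gr$dW^2
      st$mb <- b1 * st$mb + (1 - b1) * gr$db
      st$vb <- b2 * st$vb + (1 - b2) * gr$db^2
      c1 <- 1 - b1^adam_t; c2 <- 1 - b2^adam_t
      par$W <- par$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
      par$b <- par$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
      list(params = par, state = st)
    }
  } else {
    function(par, gr, st) {
      if (is.null(st)) st <- list(vW = par$W * 0, vb = par$b * 0)
      st$vW <- config$momentum * st$vW - lr * gr$dW
      st$vb <- config$momentum * st$vb - lr * gr$db
      par$W <- par$W + st$vW
      par$b <- par$b + st$vb
      list(params = par, state = st)
    }
  }

  eval_set <- function(set) {
    loss <- 0; acc <- 0; npx <- 0
    for (s in set) {
      fw <- .unet_forward(model, s$x, training = FALSE)
      d <- dim(s$x)
      p <- pmax(fw$probs, 1e-12)
      loss <- loss - sum(s$y * log(p))
      pm <- base::matrix(fw$probs, d[1] * d[2], nc)
      ids <- max.col(pm, ties.method = "first") - 1L
      acc <- acc + sum(ids == as.integer(s$mask))
      npx <- npx + d[1] * d[2]
    }
    c(loss = loss / npx, acc = acc / npx)
  }

  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), train_acc = numeric(),
                     val_acc = numeric())
  best_loss <- Inf; best_params <- model$params; best_epoch <- 0L
  wait <- 0L
  # seeded but isolated from the caller's RNG stream
  had_rs <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_rs) old_rs <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_rs) assign(".Random.seed", old_rs, envir = globalenv()),
          add = TRUE)
  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(seq_along(tr))
    ep_loss <- 0; ep_acc <- 0; ep_npx <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      grads <- NULL
      adam_t <- adam_t + 1L
      for (i in bs) {
        s <- tr[[i]]
        fw <- .unet_forward(model, s$x, training = TRUE)
        d <- dim(s$x)
        npix <- d[1] * d[2]
        p <- pmax(fw$probs, 1e-12)
        ep_loss <- ep_loss - sum(s$y * log(p))
        pm <- base::matrix(fw$probs, npix, nc)
        ids <- max.col(pm, ties.method = "first") - 1L
        ep_acc <- ep_acc + sum(ids == as.integer(s$mask))
        ep_npx <- ep_npx + npix
        dlogits <- (fw$probs - s$y) / npix
        g <- .unet_backward(model, dlogits, fw$caches)
        grads <- if (is.null(grads)) g else .add_grads(grads, g)
      }
      grads <- .scale_grads(grads, 1 / length(bs))
      upd <- .walk_update(model$params, grads, update_fn, opt_state)
      model$params <- upd$params
      opt_state <- upd$state
    }
    ve <- eval_set(va)
    hist[epoch, ] <- list(epoch, ep_loss / ep_npx, ve["loss"],
                          ep_acc / ep_npx, ve["acc"])
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f/%.4f  acc %.4f/%.4f", epoch,
                      hist$train_loss[epoch], hist$val_loss[epoch],
                      hist$train_acc[epoch], hist$val_acc[epoch]))
    if (ve["loss"] < best_loss - 1e-9) {
      best_loss <- ve["loss"]; best_params <- model$params
      best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  model$params <- best_params
  attr(hist, "stopped_epoch") <- nrow(hist)
  attr(hist, "best_epoch") <- best_epoch
  class(hist) <- c("train_history", "data.frame")
  list(model = model, history = hist)
}

#' Write a training history as CSV (and optionally a curve plot)
#'
#' @param history a `train_history`.
#' @param csv_path output CSV path (epoch, train_loss, val_loss,
#'   train_acc, val_acc).
#' @param plot_path optional PNG path for loss/accuracy curves (requires
#'   a PNG-capable graphics device).
#' @return `csv_path` invisibly.
#' @export
export_history <- function(history, csv_path, plot_path = NULL) {
  utils::write.csv(as.data.frame(history), csv_path, row.names = FALSE)
  if (!is.null(plot_path) && isTRUE(capabilities("png")[[1]])) {
    grDevices::png(plot_path, width = 800, height = 400)
    op <- graphics::par(mfrow = c(1, 2))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot(history$epoch, history$train_loss, type = "l",
                   xlab = "epoch", ylab = "loss", main = "loss",
                   ylim = range(c(history$train_loss, history$val_loss)))
    graphics::lines(history$epoch, history$val_loss, lty = 2)
    graphics::plot(history$epoch, history$train_acc, type = "l",
                   xlab = "epoch", ylab = "accuracy", main = "accuracy",
                   ylim = c(0, 1))
    graphics::lines(history$epoch, history$val_acc, lty = 2)
  }
  invisible(csv_path)
}
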