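# Encoder-decoder segmentation network (U-Net) implemented natively:
# 3x3 "same" convolutions via Rcpp im2col + BLAS matmul, 2x2 max
# pooling, nearest-neighbour upsampling, skip concatenations, bottleneck
# dropout, and a softmax pixel classifier. A skip-free variant serves as
# the FCN comparison baseline.

#' U-Net architecture specification
#'
#' One 3x3 convolution + ReLU per encoder level, 2x2 max pooling between
#' levels, a bottleneck convolution with optional dropout, and a decoder
#' that mirrors the encoder level-for-level: nearest-neighbour 2x
#' upsampling, concatenation of the matching encoder features (the skip
#' connection), and a 3x3 convolution. A 1x1 convolution + softmax head
#' yields per-pixel class probabilities.
#'
#' @param depth number of pooling levels (input side must be divisible
#'   by `2^depth`).
#' @param base_filters channels of the first encoder level; doubled per
#'   level (16 is the desk-scale default, 64 a full-size setting).
#' @param n_classes output classes (default 3: other/vegetation/sky).
#' @param dropout_rate bottleneck dropout rate in \[0, 1), training only.
#' @param skip keep the skip connections (`FALSE` gives the skip-free
#'   FCN baseline).
#' @param in_channels input image channels.
#' @return an object of class `unet_spec`.
#' @export
unet_spec <- function(depth = 4L, base_filters = 16L, n_classes = 3L,
                      dropout_rate = 0.5, skip = TRUE, in_channels = 3L) {
  .assert_scalar_num(depth, "depth", 1, 6)
  .assert_scalar_num(base_filters, "base_filters", 1)
  .assert_scalar_num(dropout_rate, "dropout_rate", 0, 1 - 1e-9)
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate, skip = isTRUE(skip),
                 in_channels = as.integer(in_channels)),
            class = "unet_spec")
}

#' Encoder/decoder feature-map sides for an input
#'
#' @param spec a [unet_spec()].
#' @param side input side in pixels.
#' @return `list(encoder =, decoder =)` of feature-map sides; the
#'   encoder path (including the bottleneck) mirrors the decoder path.
#' @export
unet_feature_sizes <- function(spec, side) {
  .check_side(spec, side)
  enc <- side / 2^(0:spec$depth)
  list(encoder = enc, decoder = rev(enc))
}

.check_side <- function(spec, side) {
  if (any(side %% 2^spec$depth != 0))
    stop(sprintf("input side %s is not divisible by 2^depth = %d",
                 paste(side, collapse = "x"), 2^spec$depth), call. = FALSE)
  invisible(side)
}

.conv_init <- function(k, cin, cout) {
  list(W = array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

#' Build an untrained U-Net model
#'
#' Weights use He initialisation under `seed`.
#'
#' @param spec a [unet_spec()].
#' @param seed RNG seed for the weight draw.
#' @return an object of class `unet_model`.
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  stopifnot(inherits(spec, "unet_spec"))
  with_seed(seed, {
    nf <- spec$base_filters * 2^(0:(spec$depth))    # per-level channels
    enc <- vector("list", spec$depth)
    cin <- spec$in_channels
    for (l in seq_len(spec$depth)) {
      enc[[l]] <- .conv_init(3, cin, nf[l])
      cin <- nf[l]
    }
    bott <- .conv_init(3, cin, nf[spec$depth + 1])
    dec <- vector("list", spec$depth)
    cup <- nf[spec$depth + 1]
    for (l in rev(seq_len(spec$depth))) {
      cin_dec <- cup + if (spec$skip) nf[l] else 0L
      dec[[l]] <- .conv_init(3, cin_dec, nf[l])
      cup <- nf[l]
    }
    head <- .conv_init(1, cup, spec$n_classes)
    structure(list(spec = spec,
                   params = list(enc = enc, bott = bott, dec = dec,
                                 head = head)),
              class = "unet_model")
  })
}

#' Build the skip-free FCN comparison baseline
#'
#' Identical encoder-decoder to [build_unet()] but without skip
#' concatenations, so all spatial detail must pass the bottleneck.
#'
#' @inheritParams build_unet
#' @param ... passed to [unet_spec()] (except `skip`).
#' @export
build_fcn <- function(seed = 1L, ...) {
  build_unet(unet_spec(..., skip = FALSE), seed = seed)
}

# ---- layer primitives ------------------------------------------------------

.conv_fwd <- function(x, par, relu = TRUE) {
  d <- dim(x)
  k <- dim(par$W)[1]
  col <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], k)
  Wm <- base::matrix(par$W, k * k * d[3], dim(par$W)[4])
  pre <- crossprod(Wm, col) + par$b          # Cout x HW (b recycles by row)
  act <- if (relu) pmax(pre, 0) else pre
  out <- array(t(act), c(d[1], d[2], dim(par$W)[4]))
  list(out = out,
       cache = list(col = col, pre = pre, dim_in = d, k = k, relu = relu))
}

.conv_bwd <- function(dout, cache, par) {
  d <- cache$dim_in
  cout <- dim(par$W)[4]
  dmat <- t(base::matrix(dout, d[1] * d[2], cout))     # Cout x HW
  if (cache$relu) dmat <- dmat * (cache$pre > 0)
  dW <- array(cache$col %*% t(dmat), dim(par$W))
  db <- rowSums(dmat)
  Wm <- base::matrix(par$W, cache$k^2 * d[3], cout)
  dcol <- Wm %*% dmat
  dx <- array(cpp_col2im(dcol, d[1], d[2], d[3], cache$k), d)
  list(dx = dx, dW = dW, db = db)
}

.maxpool_fwd <- function(x) {
  d <- dim(x)
  oy <- seq(1, d[1], 2); ey <- oy + 1
  ox <- seq(1, d[2], 2); ex <- ox + 1
  a <- x[oy, ox, , drop = FALSE]; b <- x[ey, ox, , drop = FALSE]
  c_ <- x[oy, ex, , drop = FALSE]; dd <- x[ey, ex, , drop = FALSE]
  m <- pmax(a, b, c_, dd)
  wa <- a >= m
  wb <- !wa & b >= m
  wc <- !wa & !wb & c_ >= m
  wd <- !(wa | wb | wc)
  list(out = m, cache = list(wa = wa, wb = wb, wc = wc, wd = wd, dim = d))
}

.maxpool_bwd <- function(dout, cache) {
  d <- cache$dim
  dx <- array(0, d)
  oy <- seq(1, d[1], 2); ox <- seq(1, d[2], 2)
  dx[oy, ox, ] <- dout * cache$wa
  dx[oy + 1, ox, ] <- dout * cache$wb
  dx[oy, ox + 1, ] <- dout * cache$wc
  dx[oy + 1, ox + 1, ] <- dout * cache$wd
  dx
}

.upsample_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

.upsample_bwd <- function(dout) {
  d <- dim(dout)
  oy <- seq(1, d[1], 2); ox <- seq(1, d[2], 2)
  dout[oy, ox, , drop = FALSE] + dout[oy + 1, ox, , drop = FALSE] +
    dout[oy, ox + 1, , drop = FALSE] + dout[oy + 1, ox + 1, , drop = FALSE]
}

.concat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

.softmax3 <- function(logits) {
  d <- dim(logits)
  m <- base::matrix(logits, d[1] * d[2], d[3])
  m <- exp(m - apply(m, 1, max))
  array(m / rowSums(m), d)
}

# Full forward pass; caches everything needed for backprop when
# `training = TRUE`. Dropout mask is drawn from the current RNG stream.
.unet_forward <- function(model, x, training = FALSE) {
  sp <- model$spec
  pr <- model$params
  caches <- list(enc = list(), pool = list(), dec = list())
  skips <- list()
  a <- x
  for (l in seq_len(sp$depth)) {
    cv <- .conv_fwd(a, pr$enc[[l]])
    skips[[l]] <- cv$out
    caches$enc[[l]] <- cv$cache
    pl <- .maxpool_fwd(cv$out)
    caches$pool[[l]] <- pl$cache
    a <- pl$out
  }
  cv <- .conv_fwd(a, pr$bott)
  caches$bott <- cv$cache
  a <- cv$out
  if (training && sp$dropout_rate > 0) {
    mask <- (array(runif(length(a)), dim(a)) >= sp$dropout_rate) /
      (1 - sp$dropout_rate)
    a <- a * mask
    caches$dropmask <- mask
  }
  for (l in rev(seq_len(sp$depth))) {
    a <- .upsample_fwd(a)
    if (sp$skip) {
      caches$upch[[l]] <- dim(a)[3]
      a <- .concat3(a, skips[[l]])
    }
    cv <- .conv_fwd(a, pr$dec[[l]])
    caches$dec[[l]] <- cv$cache
    a <- cv$out
  }
  cv <- .conv_fwd(a, pr$head, relu = FALSE)
  caches$head <- cv$cache
  probs <- .softmax3(cv$out)
  list(probs = probs, caches = caches)
}

# Backward pass from dlogits; returns gradients shaped like params.
.unet_backward <- function(model, dlogits, caches) {
  sp <- model$spec
  pr <- model$params
  g <- list(enc = vector("list", sp$depth), dec = vector("list", sp$depth))
  bh <- .conv_bwd(dlogits, caches$head, pr$head)
  g$head <- bh[c("dW", "db")]
  da <- bh$dx
  dskip <- vector("list", sp$depth)
  for (l in seq_len(sp$depth)) {          # decoder, innermost-first order
    bd <- .conv_bwd(da, caches$dec[[l]], pr$dec[[l]])
    g$dec[[l]] <- bd[c("dW", "db")]
    dx <- bd$dx
    if (sp$skip) {
      upch <- caches$upch[[l]]
      dskip[[l]] <- dx[, , (upch + 1):dim(dx)[3], drop = FALSE]
      dx <- dx[, , seq_len(upch), drop = FALSE]
    }
    da <- .upsample_bwd(dx)
  }
  if (!is.null(caches$dropmask)) da <- da * caches$dropmask
  bb <- .conv_bwd(da, caches$bott, pr$bott)
  g$bott <- bb[c("dW", "db")]
  da <- bb$dx
  for (l in rev(seq_len(sp$depth))) {     # encoder, deepest-first
    dup <- .maxpool_bwd(da, caches$pool[[l]])
    if (sp$skip) dup <- dup + dskip[[l]]
    be <- .conv_bwd(dup, caches$enc[[l]], pr$enc[[l]])
    g$enc[[l]] <- be[c("dW", "db")]
    da <- be$dx
  }
  g
}

#' Predict a class-id mask for an image
#'
#' Runs the network in evaluation mode (dropout off). The class id at
#' each pixel is the argmax over class probabilities with ties broken
#' toward the lowest id.
#'
#' @param model a `unet_model` (trained or not).
#' @param image H x W x 3 array with 8-bit values (0..255); H and W must
#'   be divisible by `2^depth`.
#' @return `list(mask = H x W integer matrix of ids 0..n_classes-1,
#'   probs = H x W x n_classes probability array)`.
#' @export
predict_mask <- function(model, image) {
  stopifnot(inherits(model, "unet_model"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != model$spec$in_channels)
    stop("image must be H x W x ", model$spec$in_channels, call. = FALSE)
  .check_side(model$spec, d[1:2])
  fw <- .unet_forward(model, image / 255, training = FALSE)
  pm <- base::matrix(fw$probs, d[1] * d[2], model$spec$n_classes)
  ids <- max.col(pm, ties.method = "first") - 1L
  list(mask = base::matrix(as.integer(ids), d[1], d[2]), probs = fw$probs)
}
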