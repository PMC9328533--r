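#' Class colour map for colour-coded masks
#'
#' Vegetation carries the olive RGB code (107, 142, 35) used for
#' colour-coded vegetation masks; sky and "other" use distinct constants
#' chosen by this package. The mapping is invertible by construction.
#'
#' @param other,vegetation,sky length-3 RGB triples (0..255).
#' @return a named list of class `color_map` with integer ids as names.
#' @export
svi_colormap <- function(other = c(0, 0, 0), vegetation = c(107, 142, 35),
                         sky = c(70, 130, 180)) {
  cm <- list(`0` = as.integer(other), `1` = as.integer(vegetation),
             `2` = as.integer(sky))
  key <- vapply(cm, paste, character(1), collapse = ",")
  if (anyDuplicated(key)) stop("colour map triples must be distinct")
  structure(cm, class = "color_map")
}

.cm_matrix <- function(colormap) {
  do.call(rbind, lapply(colormap, as.numeric))  # rows in id order 0,1,2
}

#' Decode a colour-coded mask image to a class-id raster
#'
#' @param rgb H x W x 3 array of a colour-coded mask.
#' @param colormap a [svi_colormap()].
#' @param strict if `TRUE` (default), any pixel whose colour is not an
#'   exact colormap entry raises an error naming the offending RGB; if
#'   `FALSE`, unknown colours are assigned the nearest colormap colour
#'   (Euclidean distance in RGB).
#' @return H x W integer matrix of class ids.
#' @export
decode_color_to_mask <- function(rgb, colormap = svi_colormap(),
                                 strict = TRUE) {
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3)
    stop("`rgb` must be a 3-channel image", call. = FALSE)
  px <- base::matrix(as.numeric(rgb), d[1] * d[2], 3)
  cm <- .cm_matrix(colormap)
  ids <- as.integer(names(colormap))
  # squared distance of every pixel to every colormap colour
  d2 <- outer(rowSums(px^2), rowSums(cm^2), "+") - 2 * px %*% t(cm)
  nearest <- max.col(-d2, ties.method = "first")
  exact <- d2[cbind(seq_len(nrow(px)), nearest)] < 1e-9
  if (strict && !all(exact)) {
    bad <- px[which(!exact)[1], ]
    stop(sprintf("unknown mask colour (%d, %d, %d) in strict decode",
                 bad[1], bad[2], bad[3]), call. = FALSE)
  }
  base::matrix(ids[nearest], d[1], d[2])
}

#' Encode a class-id raster as a colour mask image
#'
#' @param mask H x W integer matrix of class ids.
#' @param colormap a [svi_colormap()].
#' @return H x W x 3 array with the per-class colours.
#' @export
encode_mask_to_color <- function(mask, colormap = svi_colormap()) {
  ids <- as.integer(names(colormap))
  if (!all(unique(as.integer(mask)) %in% ids))
    stop("mask contains ids absent from the colour map", call. = FALSE)
  cm <- .cm_matrix(colormap)
  idx <- match(as.integer(mask), ids)
  array(cm[idx, ], c(nrow(mask), ncol(mask), 3))
}

#' Resize a scene pair
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour so no class ids are invented.
#'
#' @param pair a [scene_pair()].
#' @param side target side in pixels (square output, >= 16), or
#'   `c(height, width)`.
#' @return the resized [scene_pair()].
#' @export
resize_pair <- function(pair, side = 256L) {
  stopifnot(inherits(pair, "scene_pair"))
  if (length(side) == 1) side <- c(side, side)
  if (any(side < 16)) stop("target side must be >= 16", call. = FALSE)
  H <- nrow(pair$mask); W <- ncol(pair$mask)
  if (all(side == c(H, W))) return(pair)
  # centre-aligned scaling: output pixel centre -> input pixel centre
  sy <- H / side[1]; sx <- W / side[2]
  tf <- affine_transform(base::matrix(c(sx, 0, 0, sy,
                                        sx / 2 - 0.5, sy / 2 - 0.5), 2, 3))
  img <- warp_array(pair$image, tf, side[1], side[2], "bilinear")
  msk <- warp_array(pair$mask, tf, side[1], side[2], "nearest")
  scene_pair(round(.clip255(img)), msk, pair$site_id, pair$year, pair$quarter)
}

#' Train/validation/test split specification
#'
#' Defaults reproduce the 80/15/5 split; sizes are `floor(frac * n)` per
#' non-training partition with the remainder assigned to training, so
#' 3500 items yield partitions of 2800/525/175.
#'
#' @param train_frac,val_frac,test_frac fractions summing to 1.
#' @param seed shuffle seed.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.80, val_frac = 0.15, test_frac = 0.05,
                       seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition item indices into train/validation/test sets
#'
#' @param n_items number of items (>= 3).
#' @param spec a [split_spec()].
#' @return `list(train =, val =, test =)` of disjoint 1-based index
#'   vectors whose union is `1:n_items`.
#' @export
split_dataset <- function(n_items, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  if (n_items < 3) stop("need at least 3 items to split", call. = FALSE)
  n_val <- floor(spec$val_frac * n_items)
  n_test <- floor(spec$test_frac * n_items)
  n_train <- n_items - n_val - n_test      # remainder goes to training
  perm <- with_seed(spec$seed, sample.int(n_items))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

.aug_kinds <- c("hflip", "vflip", "rot90", "rot180", "zoom", "translate",
                "gaussian_noise", "blur")

#' A single augmentation operation
#'
#' Geometric kinds (`hflip`, `vflip`, `rot90`, `rot180`, `zoom`,
#' `translate`) transform image and mask identically (mask via
#' nearest-neighbour); photometric kinds (`gaussian_noise`, `blur`)
#' touch the image only.
#'
#' @param kind one of `"hflip"`, `"vflip"`, `"rot90"`, `"rot180"`,
#'   `"zoom"`, `"translate"`, `"gaussian_noise"`, `"blur"`.
#' @param zoom_factor central-crop factor for `zoom` (0.8..1); the crop is
#'   resized back to the original frame.
#' @param shift integer `(dx, dy)` pixel shift for `translate`; exposed
#'   borders are filled with black / class "other".
#' @param noise_sd Gaussian noise sd in 8-bit units (`gaussian_noise`).
#' @param sigma Gaussian blur sd in pixels (`blur`).
#' @param seed seed for any sampled magnitude.
#' @return an object of class `augmentation_op`.
#' @export
augmentation_op <- function(kind, zoom_factor = NULL, shift = NULL,
                            noise_sd = 10, sigma = 1.5, seed = 1L) {
  if (!kind %in% .aug_kinds)
    stop("unsupported augmentation kind: ", kind, call. = FALSE)
  structure(list(kind = kind, zoom_factor = zoom_factor, shift = shift,
                 noise_sd = noise_sd, sigma = sigma, seed = as.integer(seed)),
            class = "augmentation_op")
}

# separable Gaussian blur of a matrix, replicate-padded edges
.gauss_blur_mat <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_idx_r <- pmin(pmax(seq(1 - r, nrow(m) + r), 1), nrow(m))
  pad_idx_c <- pmin(pmax(seq(1 - r, ncol(m) + r), 1), ncol(m))
  mp <- m[pad_idx_r, , drop = FALSE]
  acc <- 0
  for (i in seq_along(k)) acc <- acc + k[i] * mp[i:(i + nrow(m) - 1), , drop = FALSE]
  mp <- acc[, pad_idx_c, drop = FALSE]
  acc <- 0
  for (i in seq_along(k)) acc <- acc + k[i] * mp[, i:(i + ncol(m) - 1), drop = FALSE]
  acc
}

#' Apply one augmentation to a scene pair
#'
#' @param pair a [scene_pair()].
#' @param op an [augmentation_op()].
#' @return the augmented [scene_pair()].
#' @export
apply_augmentation <- function(pair, op) {
  stopifnot(inherits(pair, "scene_pair"), inherits(op, "augmentation_op"))
  img <- pair$image; msk <- pair$mask
  H <- nrow(msk); W <- ncol(msk)
  flip_r <- function(a) if (length(dim(a)) == 3) a[H:1, , , drop = FALSE] else a[H:1, , drop = FALSE]
  flip_c <- function(a) if (length(dim(a)) == 3) a[, W:1, , drop = FALSE] else a[, W:1, drop = FALSE]
  rot90cw <- function(a) {
    # transpose then flip columns: (y, x) -> (x, H - y + 1)
    if (length(dim(a)) == 3) {
      aperm(a, c(2, 1, 3))[, H:1, , drop = FALSE]
    } else t(a)[, H:1, drop = FALSE]
  }
  switch(op$kind,
    hflip = { img <- flip_c(img); msk <- flip_c(msk) },
    vflip = { img <- flip_r(img); msk <- flip_r(msk) },
    rot90 = { img <- rot90cw(img); msk <- rot90cw(msk) },
    rot180 = { img <- flip_r(flip_c(img)); msk <- flip_r(flip_c(msk)) },
    zoom = {
      f <- op$zoom_factor
      if (is.null(f)) f <- with_seed(op$seed, runif(1, 0.8, 1))
      ch <- max(16L, round(f * H)); cw <- max(16L, round(f * W))
      y0 <- floor((H - ch) / 2); x0 <- floor((W - cw) / 2)
      crop <- scene_pair(img[y0 + seq_len(ch), x0 + seq_len(cw), , drop = FALSE],
                         msk[y0 + seq_len(ch), x0 + seq_len(cw), drop = FALSE],
                         pair$site_id, pair$year, pair$quarter)
      out <- resize_pair(crop, c(H, W))
      img <- out$image; msk <- out$mask
    },
    translate = {
      sh <- op$shift
      if (is.null(sh)) sh <- with_seed(op$seed,
        round(runif(2, -0.1, 0.1) * c(W, H)))
      tf <- affine_transform(cbind(diag(2), -as.numeric(sh)))  # out -> in
      img <- warp_array(img, tf, method = "nearest")
      msk <- warp_array(msk, tf, method = "nearest")
    },
    gaussian_noise = {
      img <- .clip255(img + with_seed(op$seed,
        array(rnorm(length(img), 0, op$noise_sd), dim(img))))
    },
    blur = {
      for (chn in 1:3) img[, , chn] <- .gauss_blur_mat(img[, , chn], op$sigma)
      img <- .clip255(img)
    }
  )
  scene_pair(round(img), msk, pair$site_id, pair$year, pair$quarter)
}

#' Expand a dataset with sampled augmentations
#'
#' The output keeps every original pair and appends `multiplier - 1`
#' augmented copies of each, with operations drawn from `op_pool`.
#'
#' @param pairs list of [scene_pair()] objects.
#' @param multiplier total copies per input (>= 1).
#' @param op_pool character vector of augmentation kinds to sample from.
#' @param seed sampling seed.
#' @return list of `length(pairs) * multiplier` scene pairs.
#' @export
augment_dataset <- function(pairs, multiplier = 2L,
                            op_pool = c("hflip", "vflip", "rot90", "rot180",
                                        "zoom", "translate",
                                        "gaussian_noise", "blur"),
                            seed = 1L) {
  if (multiplier < 1) stop("`multiplier` must be >= 1", call. = FALSE)
  if (multiplier > 1 && length(op_pool) == 0)
    stop("empty op pool with multiplier > 1", call. = FALSE)
  bad <- setdiff(op_pool, .aug_kinds)
  if (length(bad)) stop("unsupported augmentation kind: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (multiplier == 1) return(pairs)
  n_extra <- length(pairs) * (multiplier - 1)
  kinds <- with_seed(seed, sample(op_pool, n_extra, replace = TRUE))
  out <- pairs
  k <- 0L
  for (i in seq_along(pairs)) {
    for (m in seq_len(multiplier - 1)) {
      k <- k + 1L
      op <- augmentation_op(kinds[k], seed = derive_seed(seed, paste0("aug", k)))
      out[[length(pairs) + k]] <- apply_augmentation(pairs[[i]], op)
    }
  }
  out
}
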