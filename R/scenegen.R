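#' Parameters for a synthetic landscape scene
#'
#' Describes one synthetic repeat-photography frame: a sky band above an
#' irregular horizon, a textured terrain, and elliptical vegetation blobs
#' whose total area is adjusted to hit a requested vegetation fraction
#' exactly (to the pixel).
#'
#' @param height,width frame size in pixels (both >= 16).
#' @param veg_fraction target share of vegetation pixels, in \[0, 1\].
#' @param sky_fraction approximate share of sky pixels, in \[0, 1).
#'   `veg_fraction + sky_fraction` must not exceed 1.
#' @param blob_count number of vegetation blobs to aim for (>= 1).
#' @param texture_noise_sd sd of per-pixel Gaussian photometric noise,
#'   in 8-bit intensity units.
#' @param seed integer RNG seed; identical parameters (including seed)
#'   reproduce the scene bit for bit.
#' @param geom_seed optional separate seed for the scene geometry
#'   (horizon, blob layout, rocks). Site albums keep `geom_seed` fixed
#'   across visits so repeat photographs show one persistent landscape
#'   while vegetation extent and photometry vary; defaults to `seed`.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(height = 128L, width = 128L, veg_fraction = 0.3,
                         sky_fraction = 0.3, blob_count = 6L,
                         texture_noise_sd = 8, seed = 1L,
                         geom_seed = NULL) {
  .assert_scalar_num(height, "height", 16)
  .assert_scalar_num(width, "width", 16)
  .assert_scalar_num(veg_fraction, "veg_fraction", 0, 1)
  .assert_scalar_num(sky_fraction, "sky_fraction", 0, 1 - 1e-12)
  .assert_scalar_num(blob_count, "blob_count", 1)
  .assert_scalar_num(texture_noise_sd, "texture_noise_sd", 0)
  if (veg_fraction + sky_fraction > 1)
    stop("veg_fraction + sky_fraction must be <= 1", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 veg_fraction = veg_fraction, sky_fraction = sky_fraction,
                 blob_count = as.integer(blob_count),
                 texture_noise_sd = texture_noise_sd,
                 seed = as.integer(seed),
                 geom_seed = as.integer(if (is.null(geom_seed)) seed
                                        else geom_seed)),
            class = "scene_params")
}

#' Seasonal vegetation dynamics model
#'
#' True vegetation fraction of quarter `q` in year `t` follows
#' `clip01(base + amplitude * sin(2*pi*(q - phase_quarter)/4)
#'         + annual_trend * (t - t0) + eps)`,
#' with `eps ~ Normal(0, noise_sd)` and `t0` the first year generated.
#'
#' @param base_fraction baseline vegetation fraction in \[0, 1\].
#' @param amplitude seasonal half-range (>= 0).
#' @param phase_quarter quarter (1..4) at which the sinusoid crosses zero
#'   going up.
#' @param annual_trend linear drift in fraction per year.
#' @param noise_sd sd of quarter-to-quarter Gaussian noise on the fraction.
#' @return an object of class `seasonal_model`.
#' @export
seasonal_model <- function(base_fraction = 0.3, amplitude = 0.1,
                           phase_quarter = 1L, annual_trend = 0,
                           noise_sd = 0) {
  .assert_scalar_num(base_fraction, "base_fraction", 0, 1)
  .assert_scalar_num(amplitude, "amplitude", 0)
  if (!phase_quarter %in% 1:4)
    stop("`phase_quarter` must be in 1..4", call. = FALSE)
  .assert_scalar_num(noise_sd, "noise_sd", 0)
  .assert_scalar_num(annual_trend, "annual_trend")
  structure(list(base_fraction = base_fraction, amplitude = amplitude,
                 phase_quarter = as.integer(phase_quarter),
                 annual_trend = annual_trend, noise_sd = noise_sd),
            class = "seasonal_model")
}

#' Evaluate the seasonal model's true vegetation fraction
#'
#' @param seasonal a [seasonal_model()].
#' @param year,quarter timestamp (vectors allowed, recycled).
#' @param t0 reference year for the trend term.
#' @param eps additive noise draw(s); default 0 gives the closed form.
#' @return vegetation fraction(s) clipped to \[0, 1\].
#' @export
seasonal_fraction <- function(seasonal, year, quarter, t0 = min(year),
                              eps = 0) {
  stopifnot(inherits(seasonal, "seasonal_model"))
  .clip01(seasonal$base_fraction +
          seasonal$amplitude * sin(2 * pi * (quarter - seasonal$phase_quarter) / 4) +
          seasonal$annual_trend * (year - t0) + eps)
}

# palette anchors for the three classes (8-bit RGB); vegetation uses the
# olive tone conventionally assigned to vegetation in colour-coded masks
.scene_palette <- list(
  other = c(139, 115, 85),      # bare terrain / soil
  vegetation = c(107, 142, 35),
  sky = c(135, 175, 215)
)

#' Generate one synthetic landscape scene with exact ground truth
#'
#' Renders a sky band over an irregular horizon, a textured terrain with
#' scattered rocks, and elliptical vegetation blobs. Blob area is
#' rejection-adjusted so the returned mask's vegetation share matches
#' `params$veg_fraction` to the pixel. Deterministic in `params$seed`.
#'
#' @param params a [scene_params()].
#' @param site_id,year,quarter metadata stamped onto the returned pair.
#' @return a [scene_pair()]: `image` (H x W x 3, 0..255) and `mask`
#'   (H x W ids: 0 other, 1 vegetation, 2 sky).
#' @export
generate_scene <- function(params, site_id = "site", year = NA_integer_,
                           quarter = NA_integer_) {
  stopifnot(inherits(params, "scene_params"))
  geom <- with_seed(params$geom_seed, .scene_geometry(params))
  with_seed(params$seed, .render_scene(params, geom, site_id, year, quarter))
}

# The persistent landscape: horizon, blob layout and rocks. Drawn from
# the geometry seed only, so every visit to a site shares it.
.scene_geometry <- function(p) {
  H <- p$height; W <- p$width
  base_row <- p$sky_fraction * H
  xs <- seq_len(W)
  wob <- if (base_row >= 1) {
    amp <- min(0.03 * H, base_row / 2)
    amp * sin(2 * pi * (xs / W) * runif(1, 0.5, 2) + runif(1, 0, 2 * pi))
  } else 0
  horizon <- pmax(0, pmin(H, round(base_row + wob)))
  blobs <- data.frame(
    cy = runif(p$blob_count, min(base_row + 1, H - 1), H),
    cx = runif(p$blob_count, 1, W),
    th = runif(p$blob_count, 0, pi),
    aspect = runif(p$blob_count, 0.4, 1),      # ellipse axis ratio
    weight = runif(p$blob_count, 0.6, 1.6))    # relative blob size
  n_rock <- max(8L, round(H * W / 450))
  rocks <- data.frame(
    ry = runif(n_rock, min(base_row + 1, H - 1), H),
    rx = runif(n_rock, 1, W),
    rr = runif(n_rock, 1.2, 0.02 * max(H, W) + 2),
    col = runif(n_rock, 40, 90))
  terr_freq <- runif(2, 3, 9); terr_phase <- runif(2, 0, 6)
  list(horizon = horizon, blobs = blobs, rocks = rocks,
       terr_freq = terr_freq, terr_phase = terr_phase)
}

# Vegetation mask with an exact pixel count: every non-sky pixel gets a
# normalised distance to its nearest blob (unit-ellipse metric); the
# `target` smallest distances are vegetation. Growing/shrinking the
# target grows/shrinks the same blobs, as a season would.
.veg_mask <- function(geom, H, W, sky, target) {
  mask_veg <- base::matrix(FALSE, H, W)
  if (target <= 0) return(mask_veg)
  row_idx <- base::matrix(seq_len(H), H, W)
  col_idx <- base::matrix(seq_len(W), H, W, byrow = TRUE)
  d <- base::matrix(Inf, H, W)
  for (b in seq_len(nrow(geom$blobs))) {
    bb <- geom$blobs[b, ]
    dx <- col_idx - bb$cx; dy <- row_idx - bb$cy
    u <- dx * cos(bb$th) + dy * sin(bb$th)
    v <- -dx * sin(bb$th) + dy * cos(bb$th)
    sa <- sqrt(bb$aspect)
    db <- ((u / (bb$weight * sa))^2 + (v * sa / bb$weight)^2)
    d <- pmin(d, db)
  }
  d[sky] <- Inf
  capacity <- sum(!sky)
  target <- min(target, capacity)
  sel <- order(as.numeric(d))[seq_len(target)]
  mask_veg[sel] <- TRUE
  mask_veg
}

# Per-visit photometry: class colours, per-blob colour jitter, vertical
# sky shading, terrain texture, illumination, rocks, Gaussian noise.
.render_scene <- function(p, geom, site_id, year, quarter) {
  H <- p$height; W <- p$width
  row_idx <- base::matrix(seq_len(H), H, W)
  col_idx <- base::matrix(seq_len(W), H, W, byrow = TRUE)
  sky <- row_idx <= base::matrix(geom$horizon, H, W, byrow = TRUE)
  target <- round(p$veg_fraction * H * W)
  veg <- .veg_mask(geom, H, W, sky, target)
  mask <- base::matrix(0L, H, W)
  mask[sky] <- 2L
  mask[veg] <- 1L

  img <- array(0, c(H, W, 3))
  shade <- 1 - 0.15 * (row_idx - 1) / (H - 1)
  terr_tex <- 1 + 0.08 * sin(row_idx / geom$terr_freq[1] + geom$terr_phase[1]) *
    cos(col_idx / geom$terr_freq[2] + geom$terr_phase[2])
  # nearest blob owns the jitter colour of each vegetation pixel
  blob_jit <- runif(nrow(geom$blobs), -18, 18)
  owner <- base::matrix(1L, H, W)
  if (nrow(geom$blobs) > 1) {
    dmin <- base::matrix(Inf, H, W)
    for (b in seq_len(nrow(geom$blobs))) {
      bb <- geom$blobs[b, ]
      dx <- col_idx - bb$cx; dy <- row_idx - bb$cy
      u <- dx * cos(bb$th) + dy * sin(bb$th)
      v <- -dx * sin(bb$th) + dy * cos(bb$th)
      sa <- sqrt(bb$aspect)
      db <- ((u / (bb$weight * sa))^2 + (v * sa / bb$weight)^2)
      upd <- db < dmin
      owner[upd] <- b
      dmin[upd] <- db[upd]
    }
  }
  jit <- base::matrix(blob_jit[owner], H, W)
  illum <- runif(1, 0.85, 1.15)
  for (ch in 1:3) {
    plane <- base::matrix(.scene_palette$other[ch] * terr_tex, H, W)
    plane[sky] <- (.scene_palette$sky[ch] * (shade + 0.15))[sky]
    plane[veg] <- .scene_palette$vegetation[ch] + jit[veg]
    img[, , ch] <- plane * illum
  }
  for (i in seq_len(nrow(geom$rocks))) {
    rk <- geom$rocks[i, ]
    inside <- (row_idx - rk$ry)^2 + (col_idx - rk$rx)^2 <= rk$rr^2 &
      mask == 0L
    if (!any(inside)) next
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- rk$col * c(1, 0.95, 0.9)[ch]
      img[, , ch] <- plane
    }
  }
  if (p$texture_noise_sd > 0)
    img <- img + array(rnorm(H * W * 3, 0, p$texture_noise_sd), c(H, W, 3))
  img <- round(.clip255(img))
  scene_pair(img, mask, site_id = site_id, year = year, quarter = quarter)
}

#' Generate a multi-year quarterly album for one site
#'
#' One scene per (year, quarter, replicate); the true vegetation fraction
#' follows [seasonal_fraction()] with noise drawn per (year, quarter)
#' under the album seed. Viewpoint differences between visits are added
#' separately with [perturb_viewpoint()].
#'
#' @param site_id character site identifier.
#' @param seasonal a [seasonal_model()].
#' @param years integer vector of years (non-empty).
#' @param per_quarter replicates per quarter (>= 1).
#' @param scene a [scene_params()] template (its `veg_fraction` is
#'   overridden per quarter; its seed seeds the album stream).
#' @return list of [scene_pair()] objects, chronological order, with an
#'   attribute `true_fractions` (data.frame year, quarter, fraction).
#' @export
generate_site_album <- function(site_id, seasonal, years, per_quarter = 1L,
                                scene = scene_params()) {
  stopifnot(inherits(seasonal, "seasonal_model"),
            inherits(scene, "scene_params"))
  if (length(years) == 0) stop("`years` must be non-empty", call. = FALSE)
  if (per_quarter < 1) stop("`per_quarter` must be >= 1", call. = FALSE)
  years <- sort(unique(as.integer(years)))
  grid <- expand.grid(quarter = 1:4, year = years)[, c("year", "quarter")]
  eps <- if (seasonal$noise_sd > 0)
    with_seed(derive_seed(scene$seed, paste0("season-", site_id)),
              rnorm(nrow(grid), 0, seasonal$noise_sd)) else rep(0, nrow(grid))
  frac <- seasonal_fraction(seasonal, grid$year, grid$quarter,
                            t0 = years[1], eps = eps)
  pairs <- vector("list", nrow(grid) * per_quarter)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(per_quarter)) {
      k <- k + 1L
      sp <- scene
      sp$veg_fraction <- min(frac[i], 1 - sp$sky_fraction)
      # one persistent landscape per site; fresh photometry per visit
      sp$geom_seed <- derive_seed(scene$seed, paste0("geom-", site_id))
      sp$seed <- derive_seed(scene$seed,
                             sprintf("%s-%d-%d-%d", site_id, grid$year[i],
                                     grid$quarter[i], r))
      pairs[[k]] <- generate_scene(sp, site_id = site_id,
                                   year = grid$year[i],
                                   quarter = grid$quarter[i])
    }
  }
  attr(pairs, "true_fractions") <- data.frame(grid, fraction = frac)
  pairs
}

#' Jitter the viewpoint of a scene pair
#'
#' Applies a random (or explicitly requested) similarity jitter --
#' rotation, translation and isotropic scale about the image centre -- to
#' image (bilinear) and mask (nearest) identically, emulating a repeat
#' photograph taken from a slightly different vantage point.
#'
#' @param pair a [scene_pair()].
#' @param max_rotation_deg,max_translation_frac,max_scale_delta
#'   non-negative sampling bounds: rotation ~ U(-r, r) degrees,
#'   per-axis translation ~ U(-f, f) x dimension pixels,
#'   scale ~ 1 + U(-d, d).
#' @param seed RNG seed for the draw.
#' @param rotation_deg,translation_px,scale optional exact values that
#'   bypass sampling (translation as `(tx, ty)` pixels).
#' @return `list(pair = jittered scene_pair, transform = affine_transform)`
#'   where `transform` maps sensed (jittered) pixel coordinates back to
#'   the reference frame -- i.e. the transform registration must recover.
#' @export
perturb_viewpoint <- function(pair, max_rotation_deg = 5,
                              max_translation_frac = 0.05,
                              max_scale_delta = 0.05, seed = 1L,
                              rotation_deg = NULL, translation_px = NULL,
                              scale = NULL) {
  stopifnot(inherits(pair, "scene_pair"))
  .assert_scalar_num(max_rotation_deg, "max_rotation_deg", 0)
  .assert_scalar_num(max_translation_frac, "max_translation_frac", 0)
  .assert_scalar_num(max_scale_delta, "max_scale_delta", 0)
  H <- nrow(pair$mask); W <- ncol(pair$mask)
  draw <- with_seed(seed, list(
    rot = runif(1, -max_rotation_deg, max_rotation_deg),
    tr = c(runif(1, -max_translation_frac, max_translation_frac) * W,
           runif(1, -max_translation_frac, max_translation_frac) * H),
    sc = 1 + runif(1, -max_scale_delta, max_scale_delta)))
  if (!is.null(rotation_deg)) draw$rot <- rotation_deg
  if (!is.null(translation_px)) draw$tr <- translation_px
  if (!is.null(scale)) draw$sc <- scale
  center <- c((W - 1) / 2, (H - 1) / 2)
  forward <- affine_from_params(draw$rot, draw$tr, draw$sc, center)
  truth <- affine_invert(forward)       # sensed -> reference
  img <- warp_array(pair$image, truth, method = "bilinear")
  msk <- warp_array(pair$mask, truth, method = "nearest")
  out <- scene_pair(round(.clip255(img)), msk, site_id = pair$site_id,
                    year = pair$year, quarter = pair$quarter)
  list(pair = out, transform = truth)
}
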