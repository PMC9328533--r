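test_that("generated masks hit the requested vegetation fraction", {
  p <- scene_params(64, 64, veg_fraction = 0.25, seed = 7)
  s <- generate_scene(p)
  expect_lte(abs(mean(s$mask == 1L) - 0.25), 0.02)
  # property over a spread of fractions and seeds
  for (i in 1:8) {
    f <- frac_spread(i, 0, 0.65)
    sc <- generate_scene(scene_params(48, 48, veg_fraction = f, seed = i))
    expect_lte(abs(mean(sc$mask == 1L) - f), 0.02)
  }
})

test_that("zero vegetation fraction gives a vegetation-free mask", {
  s <- generate_scene(scene_params(32, 32, veg_fraction = 0, seed = 3))
  expect_identical(sum(s$mask == 1L), 0L)
})

test_that("identical parameters reproduce the scene bit for bit", {
  p <- scene_params(48, 48, veg_fraction = 0.3, seed = 11)
  expect_identical(generate_scene(p), generate_scene(p))
})

test_that("scene parameter invariants are enforced", {
  expect_error(scene_params(8, 64), "height")
  expect_error(scene_params(veg_fraction = 1.2), "veg_fraction")
  expect_error(scene_params(veg_fraction = 0.6, sky_fraction = 0.5),
               "must be <= 1")
})

test_that("masks only contain defined class ids and match image shape", {
  for (i in 1:5) {
    s <- tiny_scene(seed = i, h = 32, w = 40, veg = frac_spread(i, 0, 0.5))
    expect_true(all(unique(as.integer(s$mask)) %in% 0:2))
    expect_identical(dim(s$image)[1:2], dim(s$mask))
  }
})

test_that("site albums have one entry per year/quarter/replicate", {
  alb <- generate_site_album("s1", seasonal_model(noise_sd = 0), 2015:2020,
                             per_quarter = 1,
                             scene = scene_params(32, 32, seed = 1))
  expect_length(alb, 24)
  expect_identical(vapply(alb, `[[`, integer(1), "year"),
                   rep(2015:2020, each = 4))
  expect_identical(vapply(alb, `[[`, integer(1), "quarter"),
                   rep(1:4, times = 6))
  alb2 <- generate_site_album("s1", seasonal_model(noise_sd = 0), 2015,
                              per_quarter = 3,
                              scene = scene_params(32, 32, seed = 1))
  expect_length(alb2, 12)
  expect_error(generate_site_album("s1", seasonal_model(), integer(0)),
               "non-empty")
})

test_that("constant seasonal model gives one shared true fraction", {
  se <- seasonal_model(base_fraction = 0.3, amplitude = 0, annual_trend = 0,
                       noise_sd = 0)
  alb <- generate_site_album("s1", se, 2015:2016,
                             scene = scene_params(32, 32, seed = 2))
  tf <- attr(alb, "true_fractions")
  expect_true(all(tf$fraction == 0.3))
})

test_that("noise-free seasonal fractions follow the closed-form sinusoid", {
  se <- seasonal_model(base_fraction = 0.3, amplitude = 0.1,
                       phase_quarter = 1, annual_trend = 0.02, noise_sd = 0)
  alb <- generate_site_album("s1", se, 2015:2017,
                             scene = scene_params(32, 32, seed = 4))
  tf <- attr(alb, "true_fractions")
  expected <- pmin(1, pmax(0,
    0.3 + 0.1 * sin(2 * pi * (tf$quarter - 1) / 4) +
      0.02 * (tf$year - 2015)))
  expect_equal(tf$fraction, expected, tolerance = 1e-12)
  # and the generated masks track those fractions
  err <- abs(vapply(alb, function(p) mean(p$mask == 1L), numeric(1)) -
               tf$fraction)
  expect_lte(max(err), 0.02)
})

test_that("album regeneration with the same seeds is bit-identical", {
  se <- seasonal_model(noise_sd = 0.05)
  a1 <- generate_site_album("s1", se, 2015:2016,
                            scene = scene_params(32, 32, seed = 9))
  a2 <- generate_site_album("s1", se, 2015:2016,
                            scene = scene_params(32, 32, seed = 9))
  expect_identical(a1, a2)
})

test_that("zero-bound viewpoint jitter is the identity", {
  s <- tiny_scene(seed = 5)
  j <- perturb_viewpoint(s, 0, 0, 0, seed = 1)
  expect_equal(j$transform$matrix, affine_identity()$matrix,
               tolerance = 1e-12)
  expect_equal(j$pair$image, s$image)
  expect_identical(j$pair$mask, s$mask)
})

test_that("explicitly requested jitter returns exactly that transform", {
  s <- tiny_scene(seed = 6, h = 64, w = 64)
  j <- perturb_viewpoint(s, seed = 1, rotation_deg = 5,
                         translation_px = c(3, -2), scale = 1)
  expected <- affine_invert(affine_from_params(5, c(3, -2), 1,
                                               center = c(31.5, 31.5)))
  expect_equal(j$transform$matrix, expected$matrix, tolerance = 1e-10)
})

test_that("inverse-warping a jittered mask recovers the original interior", {
  s <- tiny_scene(seed = 8, h = 64, w = 64)
  j <- perturb_viewpoint(s, max_rotation_deg = 5,
                         max_translation_frac = 0.05,
                         max_scale_delta = 0.03, seed = 21)
  # warp the jittered mask back with the inverse of the true transform
  back <- svimon:::warp_array(j$pair$mask, affine_invert(j$transform),
                              method = "nearest")
  m <- 8  # border margin
  inner <- function(x) x[(m + 1):(64 - m), (m + 1):(64 - m)]
  agree <- mean(inner(back) == inner(s$mask))
  expect_gte(agree, 0.95)
})
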