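test_that("the vegetation colour decodes to class 1", {
  cm <- svi_colormap()
  px <- array(rep(c(107, 142, 35), each = 4), c(2, 2, 3))
  expect_identical(decode_color_to_mask(px, cm),
                   matrix(1L, 2, 2))
})

test_that("strict decode rejects unknown colours, lenient snaps to nearest", {
  cm <- svi_colormap()
  px <- array(rep(c(255, 0, 0), each = 1), c(1, 1, 3))
  expect_error(decode_color_to_mask(px, cm, strict = TRUE),
               "\\(255, 0, 0\\)")
  # (100,140,40) is closest to vegetation
  near <- array(c(100, 140, 40), c(1, 1, 3))
  expect_identical(decode_color_to_mask(near, cm, strict = FALSE),
                   matrix(1L, 1, 1))
})

test_that("colour encode/decode round-trips exactly for random masks", {
  cm <- svi_colormap()
  for (i in 1:10) {
    m <- rand_mask(9, 7, seed = i)
    expect_identical(decode_color_to_mask(encode_mask_to_color(m, cm), cm), m)
  }
  expect_equal(encode_mask_to_color(matrix(1L, 2, 2), cm),
               array(rep(c(107, 142, 35), each = 4), c(2, 2, 3)))
  expect_equal(encode_mask_to_color(matrix(0L, 2, 2), cm),
               array(0, c(2, 2, 3)))
  expect_error(encode_mask_to_color(matrix(7L, 2, 2), cm), "absent")
})

test_that("netpbm raster round trips are exact", {
  s <- tiny_scene(seed = 1, h = 20, w = 24)
  ip <- tempfile(fileext = ".ppm")
  mp <- tempfile(fileext = ".pgm")
  on.exit(unlink(c(ip, mp)))
  write_ppm(s$image, ip)
  write_pgm(s$mask, mp)
  expect_equal(read_ppm(ip), s$image + 0)
  expect_identical(read_pgm(mp), s$mask + 0L)
})

test_that("resize uses bilinear for images and nearest for masks", {
  s <- tiny_scene(seed = 2, h = 96, w = 72)
  r <- resize_pair(s, 32)
  expect_identical(dim(r$mask), c(32L, 32L))
  expect_identical(dim(r$image), c(32L, 32L, 3L))
  expect_true(all(unique(as.integer(r$mask)) %in%
                    unique(as.integer(s$mask))))
  expect_identical(resize_pair(s, c(96, 72)), s)   # identity
  expect_error(resize_pair(s, 8), ">= 16")
})

test_that("split sizes follow the floor/remainder-to-train rule", {
  sp <- split_dataset(3500, split_spec(seed = 1))
  expect_identical(lengths(sp), c(train = 2800L, val = 525L, test = 175L))
  sp20 <- split_dataset(20, split_spec(seed = 2))
  expect_identical(lengths(sp20), c(train = 16L, val = 3L, test = 1L))
  expect_error(split_dataset(2), "at least 3")
  expect_error(split_spec(0.8, 0.15, 0.1), "sum to 1")
})

test_that("splits are deterministic, disjoint and exhaustive", {
  for (n in c(10L, 97L, 350L)) {
    s1 <- split_dataset(n, split_spec(seed = 42))
    s2 <- split_dataset(n, split_spec(seed = 42))
    expect_identical(s1, s2)
    all_idx <- sort(unname(unlist(s1)))
    expect_identical(all_idx, seq_len(n))
    expect_identical(sum(lengths(s1)), as.integer(n))
  }
  expect_false(identical(split_dataset(100, split_spec(seed = 1)),
                         split_dataset(100, split_spec(seed = 2))))
})

test_that("flip and rotation augmentations are involutions/identities", {
  s <- tiny_scene(seed = 3, h = 32, w = 32)
  h2 <- apply_augmentation(apply_augmentation(s, augmentation_op("hflip")),
                           augmentation_op("hflip"))
  expect_identical(h2, s)
  r <- s
  for (k in 1:4) r <- apply_augmentation(r, augmentation_op("rot90"))
  expect_identical(r, s)
  v2 <- apply_augmentation(apply_augmentation(s, augmentation_op("vflip")),
                           augmentation_op("vflip"))
  expect_identical(v2, s)
})

test_that("geometric flips conserve per-class pixel counts", {
  s <- tiny_scene(seed = 4, h = 40, w = 40)
  before <- table(factor(s$mask, levels = 0:2))
  for (kind in c("hflip", "vflip", "rot90", "rot180")) {
    a <- apply_augmentation(s, augmentation_op(kind))
    expect_identical(table(factor(a$mask, levels = 0:2)), before,
                     info = kind)
  }
})

test_that("photometric augmentations leave the mask untouched", {
  s <- tiny_scene(seed = 5, h = 32, w = 32)
  for (kind in c("gaussian_noise", "blur")) {
    a <- apply_augmentation(s, augmentation_op(kind, seed = 3))
    expect_identical(a$mask, s$mask, info = kind)
    expect_false(identical(a$image, s$image))
  }
  # and are deterministic in the op seed
  a1 <- apply_augmentation(s, augmentation_op("gaussian_noise", seed = 9))
  a2 <- apply_augmentation(s, augmentation_op("gaussian_noise", seed = 9))
  expect_identical(a1, a2)
})

test_that("zoom and translate keep shapes and valid ids", {
  s <- tiny_scene(seed = 6, h = 48, w = 48)
  z <- apply_augmentation(s, augmentation_op("zoom", zoom_factor = 0.85))
  tr <- apply_augmentation(s, augmentation_op("translate", shift = c(5, -3)))
  for (a in list(z, tr)) {
    expect_identical(dim(a$mask), dim(s$mask))
    expect_true(all(unique(as.integer(a$mask)) %in% 0:2))
  }
  # translated content actually moved: out(y, x) = in(y + 3, x - 5)
  expect_identical(tr$mask[1:45, 6], s$mask[4:48, 1])
})

test_that("augment_dataset multiplies, preserves originals, reproduces", {
  pairs <- lapply(1:5, tiny_scene, h = 32, w = 32)
  out <- augment_dataset(pairs, multiplier = 3, seed = 11)
  expect_length(out, 15)
  expect_identical(out[1:5], pairs)
  expect_identical(augment_dataset(pairs, multiplier = 3, seed = 11), out)
  expect_identical(augment_dataset(pairs, multiplier = 1), pairs)
  expect_error(augment_dataset(pairs, 2, op_pool = character(0)),
               "empty op pool")
  expect_error(augmentation_op("sharpen"), "unsupported")
})
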