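# Shared fixtures and independent brute-force oracles. Everything is
# generated in code; no binary fixtures.

tiny_scene <- function(seed = 1, h = 48, w = 48, veg = 0.3, sky = 0.3,
                       noise = 8) {
  generate_scene(scene_params(h, w, veg_fraction = veg, sky_fraction = sky,
                              texture_noise_sd = noise, seed = seed))
}

rand_mask <- function(h, w, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:(k - 1), h * w, replace = TRUE), h, w)
}

# exhaustive per-pixel double loop; deliberately naive and independent
# of the package's vectorised implementations
oracle_confusion <- function(pred, true, pos) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == pos
      t <- true[i, j] == pos
      if (p && t) tp <- tp + 1L
      else if (!p && !t) tn <- tn + 1L
      else if (p && !t) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_iou <- function(pred, true, classes) {
  sapply(classes, function(k) {
    inter <- 0L; uni <- 0L
    for (i in seq_len(nrow(pred))) {
      for (j in seq_len(ncol(pred))) {
        p <- pred[i, j] == k
        t <- true[i, j] == k
        if (p && t) inter <- inter + 1L
        if (p || t) uni <- uni + 1L
      }
    }
    if (uni == 0) NA_real_ else inter / uni
  })
}

oracle_veg_count <- function(mask, veg = 1L) {
  n <- 0L
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask)))
      if (mask[i, j] == veg) n <- n + 1L
  n
}

# a deterministic spread of vegetation fractions for training corpora
frac_spread <- function(i, lo = 0.05, hi = 0.55) {
  lo + (hi - lo) * ((i * 37) %% 97) / 97
}

make_pairs <- function(n, h = 64, w = 64, seed0 = 0) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_params(h, w, veg_fraction = frac_spread(i),
                                seed = seed0 + i)))
}
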