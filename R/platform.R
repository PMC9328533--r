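# End-to-end orchestration: one config tree, one global seed, staged
# pipeline generate -> register -> prepare -> train -> evaluate -> series,
# with a run manifest (paths + checksums) and a stage-level log.

#' Save / load a model checkpoint
#'
#' Single-file native checkpoints via R serialization.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "unet_model")) stop("not a unet_model checkpoint: ", path)
  m
}

# ---- minimal structured-config reader -------------------------------------
# Accepts JSON (via jsonlite) or a small YAML subset: nested maps by
# 2-space indentation, "key: value" scalars, '#' comments, numbers,
# true/false, bare or quoted strings.

.parse_scalar <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "TRUE", "yes")) return(TRUE)
  if (s %in% c("false", "FALSE", "no")) return(FALSE)
  if (grepl('^".*"$', s) || grepl("^'.*'$", s))
    return(substr(s, 2, nchar(s) - 1))
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  s
}

#' Read a structured text configuration file
#'
#' `.json` files are parsed with jsonlite; anything else is read as a
#' YAML-style key/value tree (2-space indentation, scalar leaves).
#'
#' @param path config file path.
#' @return a nested named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path))
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  parse_block <- function(idx, indent) {
    out <- list()
    i <- 1
    while (i <= length(idx)) {
      ln <- lines[idx[i]]
      this_ind <- nchar(ln) - nchar(sub("^ *", "", ln))
      if (this_ind != indent)
        stop("config parse error at line: ", trimws(ln), call. = FALSE)
      kv <- sub("^ *", "", ln)
      m <- regmatches(kv, regexec("^([^:]+):(.*)$", kv))[[1]]
      if (length(m) != 3)
        stop("config parse error (expected 'key: value'): ", kv,
             call. = FALSE)
      key <- trimws(m[2]); val <- m[3]
      if (nzchar(trimws(val))) {
        out[[key]] <- .parse_scalar(val)
        i <- i + 1
      } else {
        j <- i + 1
        child <- integer(0)
        while (j <= length(idx)) {
          ind_j <- nchar(lines[idx[j]]) - nchar(sub("^ *", "", lines[idx[j]]))
          if (ind_j <= indent) break
          child <- c(child, idx[j]); j <- j + 1
        }
        out[[key]] <- parse_block(child, indent + 2)
        i <- j
      }
    }
    out
  }
  parse_block(seq_along(lines), 0)
}

.merge_config <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- .merge_config(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Build a full run configuration
#'
#' Desk-scale defaults: 2 synthetic sites, 2015-2020 quarterly, 64 px
#' frames, a depth-3/base-16 U-Net trained briefly with Adam. Every
#' nested seed is derived from the single global `seed`.
#'
#' @param overrides named list (e.g. from [read_config()]) merged over
#'   the defaults.
#' @return nested list of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    out_dir = file.path(tempdir(), "svimon-run"),
    seed = 1,
    sites = 2,
    years = "2015:2020",
    per_quarter = 1,
    scene = list(height = 64, width = 64, sky_fraction = 0.3,
                 blob_count = 5, texture_noise_sd = 8),
    seasonal = list(base_fraction = 0.3, amplitude = 0.1, phase_quarter = 1,
                    annual_trend = 0, noise_sd = 0.02),
    jitter = list(max_rotation_deg = 4, max_translation_frac = 0.04,
                  max_scale_delta = 0.04),
    registration = list(enabled = TRUE, ransac_threshold_px = 2),
    resize_side = 64,
    split = list(train_frac = 0.80, val_frac = 0.15, test_frac = 0.05),
    augment_multiplier = 1,
    unet = list(depth = 3, base_filters = 16, dropout_rate = 0.25),
    train = list(batch_size = 16, learning_rate = 1e-3, optimizer = "adam",
                 max_epochs = 4, early_stop_patience = 3)
  )
  cfg <- .merge_config(cfg, overrides)
  if (is.character(cfg$years)) {
    rng <- as.integer(strsplit(cfg$years, ":")[[1]])
    cfg$years <- rng[1]:rng[length(rng)]
  }
  structure(cfg, class = "run_config")
}

.stage <- function(log, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  msg <- sprintf("[%s] stage %-10s done in %.1fs", format(Sys.time()),
                 name, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(msg)
  cat(msg, "\n", file = log, append = TRUE)
  res
}

#' Run the full monitoring pipeline end to end
#'
#' Generates (or loads) a dataset, registers each album to its
#' chronologically first frame, resizes, splits 80/15/5, augments the
#' training partition, trains the U-Net, evaluates on the test
#' partition, and writes per-site quarterly SVI series -- each stage in
#' the order registration -> resize -> training. All artifacts land
#' under `config$out_dir` and are listed, with MD5 checksums, in the
#' returned run manifest (also written as `manifest.csv`).
#'
#' @param config a [run_config()].
#' @return invisible list: `manifest` (data.frame file/md5), `metrics`
#'   (metric_report), `series` (list of site_series), `model`,
#'   `history`, `paths`.
#' @export
run_end_to_end <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("data", "registered", "metrics", "series"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  log <- file.path(out, "run.log")
  cat(sprintf("[%s] run start, global seed %d\n", format(Sys.time()),
              as.integer(config$seed)), file = log)
  seed_of <- function(stream) derive_seed(config$seed, stream)
  cat(sprintf("module seeds: %s\n",
              paste(sprintf("%s=%d", c("scene", "jitter", "split", "train"),
                            vapply(c("scene", "jitter", "split", "train"),
                                   seed_of, integer(1))), collapse = " ")),
      file = log, append = TRUE)

  # -- generate ------------------------------------------------------------
  gen <- .stage(log, "generate", {
    sites <- sprintf("site%02d", seq_len(config$sites))
    albums <- list(); truth <- list()
    for (s in sites) {
      sc <- do.call(scene_params,
                    c(config$scene, list(seed = seed_of(paste0("scene-", s)))))
      se <- do.call(seasonal_model, config$seasonal)
      alb <- generate_site_album(s, se, config$years, config$per_quarter, sc)
      truth[[s]] <- attr(alb, "true_fractions")
      albums[[s]] <- alb
    }
    list(albums = albums, truth = truth, sites = sites)
  })

  # -- viewpoint jitter + registration (before any resizing) ---------------
  reg <- .stage(log, "register", {
    n_fail <- 0L
    albums <- gen$albums
    for (s in gen$sites) {
      alb <- albums[[s]]
      ref_img <- alb[[1]]$image
      for (i in seq_along(alb)[-1]) {
        jit <- perturb_viewpoint(
          alb[[i]],
          config$jitter$max_rotation_deg,
          config$jitter$max_translation_frac,
          config$jitter$max_scale_delta,
          seed = seed_of(sprintf("jitter-%s-%d", s, i)))
        pair <- jit$pair
        if (isTRUE(config$registration$enabled)) {
          rr <- tryCatch(
            register_pair(ref_img, pair$image,
                          config$registration$ransac_threshold_px,
                          seed = seed_of(sprintf("ransac-%s-%d", s, i))),
            error = function(e) NULL)
          if (is.null(rr)) {
            n_fail <- n_fail + 1L
            warning(sprintf("registration failed for %s frame %d; using %s",
                            s, i, "unregistered image"), call. = FALSE)
          } else {
            inv <- affine_invert(rr$transform)
            msk <- warp_array(pair$mask, inv, method = "nearest")
            pair <- scene_pair(round(.clip255(rr$registered)), msk,
                               pair$site_id, pair$year, pair$quarter)
          }
        }
        alb[[i]] <- pair
      }
      albums[[s]] <- alb
    }
    list(albums = albums, n_fail = n_fail)
  })

  # write the registered dataset + album manifest
  manifest_rows <- list()
  for (s in gen$sites) {
    dir.create(file.path(out, "data", s), showWarnings = FALSE)
    alb <- reg$albums[[s]]
    reps <- ave(seq_along(alb), vapply(alb, function(p)
      sprintf("%d-%d", p$year, p$quarter), character(1)), FUN = seq_along)
    for (i in seq_along(alb)) {
      p <- alb[[i]]
      stem <- sprintf("%dQ%d_%d", p$year, p$quarter, reps[i])
      ip <- file.path(out, "data", s, paste0(stem, ".ppm"))
      mp <- file.path(out, "data", s, paste0(stem, "_mask.pgm"))
      write_ppm(p$image, ip)
      write_pgm(p$mask, mp)
      manifest_rows[[length(manifest_rows) + 1]] <-
        data.frame(site_id = s, path = ip, mask_path = mp,
                   year = p$year, quarter = p$quarter)
    }
  }
  album_manifest <- do.call(rbind, manifest_rows)

  # -- prepare: resize, split, augment training only -----------------------
  prep <- .stage(log, "prepare", {
    pairs <- unlist(reg$albums, recursive = FALSE, use.names = FALSE)
    pairs <- lapply(pairs, resize_pair, side = config$resize_side)
    sp <- split_dataset(length(pairs),
                        do.call(split_spec,
                                c(config$split, list(seed = seed_of("split")))))
    album_manifest$split <- ""
    for (nm in names(sp)) album_manifest$split[sp[[nm]]] <- nm
    train <- augment_dataset(pairs[sp$train],
                             multiplier = config$augment_multiplier,
                             seed = seed_of("augment"))
    list(train = train, val = pairs[sp$val], test = pairs[sp$test],
         all = pairs, split = sp, manifest = album_manifest)
  })
  album_manifest <- prep$manifest
  write.csv(album_manifest, file.path(out, "manifest_album.csv"),
            row.names = FALSE)

  # -- train ---------------------------------------------------------------
  trn <- .stage(log, "train", {
    spec <- do.call(unet_spec, config$unet)
    model <- build_unet(spec, seed = seed_of("init"))
    cfg <- do.call(train_config,
                   c(config$train, list(seed = seed_of("train"))))
    train_model(model, prep$train, prep$val, cfg)
  })
  model_path <- file.path(out, "model.rds")
  save_model(trn$model, model_path)
  export_history(trn$history, file.path(out, "history.csv"),
                 file.path(out, "history.png"))

  # -- evaluate ------------------------------------------------------------
  metrics <- .stage(log, "evaluate",
                    evaluate_testset(trn$model, prep$test))
  jsonlite::write_json(
    c(metrics[c("precision", "recall", "f1", "overall_accuracy")],
      list(iou = as.list(metrics$iou), miou = metrics$miou,
           oa_min = metrics$oa_min, oa_max = metrics$oa_max,
           n_images = metrics$n_images)),
    file.path(out, "metrics", "metrics.json"), auto_unbox = TRUE,
    digits = NA)
  utils::write.csv(data.frame(image = seq_along(metrics$per_image_oa),
                              overall_accuracy = metrics$per_image_oa),
                   file.path(out, "metrics", "per_image.csv"),
                   row.names = FALSE)

  # -- quarterly SVI series ------------------------------------------------
  series <- .stage(log, "series", {
    idx <- split(seq_len(nrow(album_manifest)), album_manifest$site_id)
    lapply(idx, function(ii) {
      recs <- lapply(ii, function(i)
        svi_from_image(trn$model, prep$all[[i]]$image,
                       site_id = album_manifest$site_id[i],
                       year = album_manifest$year[i],
                       quarter = album_manifest$quarter[i]))
      quarterly_series(recs)
    })
  })
  series_paths <- character(0)
  for (s in names(series)) {
    sp_path <- file.path(out, "series", paste0(s, ".csv"))
    export_series(series[[s]], sp_path)
    series_paths <- c(series_paths, sp_path)
    if (isTRUE(capabilities("png")[[1]])) {
      grDevices::png(file.path(out, "series", paste0(s, ".png")),
                     width = 700, height = 350)
      plot(series[[s]])
      grDevices::dev.off()
    }
  }

  # -- run manifest with checksums ----------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.csv"))
  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)
  cat(sprintf("[%s] run complete: %d artifacts\n", format(Sys.time()),
              nrow(manifest)), file = log, append = TRUE)

  invisible(list(manifest = manifest, metrics = metrics, series = series,
                 model = trn$model, history = trn$history,
                 registration_failures = reg$n_fail,
                 paths = list(out = out, model = model_path,
                              album_manifest = file.path(out, "manifest_album.csv"),
                              series = series_paths)))
}
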