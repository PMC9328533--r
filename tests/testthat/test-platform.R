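test_that("the YAML-subset config parser reads nested trees", {
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  writeLines(c("seed: 7",
               "sites: 3            # inline comment",
               "years: \"2016:2018\"",
               "scene:",
               "  height: 32",
               "  width: 32",
               "  texture_noise_sd: 4.5",
               "train:",
               "  optimizer: adam",
               "  max_epochs: 2"), path)
  cfg <- read_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$sites, 3)
  expect_equal(cfg$years, "2016:2018")
  expect_equal(cfg$scene$height, 32)
  expect_equal(cfg$scene$texture_noise_sd, 4.5)
  expect_equal(cfg$train$optimizer, "adam")
  rc <- run_config(cfg)
  expect_identical(rc$years, 2016:2018)
  expect_equal(rc$scene$height, 32)
  # untouched defaults survive the merge
  expect_equal(rc$split$train_frac, 0.80)
  jp <- tempfile(fileext = ".json")
  on.exit(unlink(jp), add = TRUE)
  jsonlite::write_json(list(seed = 9, unet = list(depth = 2)), jp,
                       auto_unbox = TRUE)
  expect_equal(read_config(jp)$unet$depth, 2)
})

test_that("derived module seeds are deterministic and within range", {
  s1 <- svimon:::derive_seed(1, "train")
  expect_identical(s1, svimon:::derive_seed(1, "train"))
  expect_false(s1 == svimon:::derive_seed(1, "split"))
  expect_lt(svimon:::derive_seed(2^20, "x"), 2^31)
  expect_gte(svimon:::derive_seed(123456, "scene"), 0)
})

test_that("the end-to-end run produces the full artifact set in order", {
  out <- file.path(tempdir(), "svimon-e2e")
  unlink(out, recursive = TRUE)
  cfg <- run_config(list(
    out_dir = out, seed = 5, sites = 2, years = "2015:2020",
    per_quarter = 1,
    scene = list(height = 48, width = 48),
    resize_side = 48,
    unet = list(depth = 2, base_filters = 8, dropout_rate = 0),
    train = list(batch_size = 8, learning_rate = 1e-3, optimizer = "adam",
                 max_epochs = 2, early_stop_patience = 1)))
  res <- suppressWarnings(run_end_to_end(cfg))

  # counting contract: 2 sites x 6 years x 4 quarters = 48 input pairs
  mf <- read.csv(file.path(out, "manifest_album.csv"))
  expect_identical(nrow(mf), 48L)
  expect_identical(sort(unique(mf$site_id)), c("site01", "site02"))
  expect_true(file.exists(file.path(out, "model.rds")))
  expect_length(res$paths$series, 2)
  expect_true(all(file.exists(res$paths$series)))

  # split respects the 80/15/5 floor rule at n = 48
  expect_identical(as.integer(table(mf$split)[c("train", "val", "test")]),
                   c(39L, 7L, 2L))

  # stages were executed in the pipeline order
  log <- readLines(file.path(out, "run.log"))
  stage_lines <- grep("stage", log, value = TRUE)
  ord <- vapply(c("generate", "register", "prepare", "train", "evaluate",
                  "series"),
                function(s) grep(s, stage_lines)[1], numeric(1))
  expect_true(all(diff(ord) > 0))

  # the run manifest is complete: every artifact on disk is listed
  files <- list.files(out, recursive = TRUE)
  listed <- read.csv(file.path(out, "manifest.csv"))$file
  expect_setequal(setdiff(files, "manifest.csv"), listed)

  # metrics JSON exists and parses
  met <- jsonlite::fromJSON(file.path(out, "metrics", "metrics.json"))
  expect_true(all(c("precision", "recall", "f1", "overall_accuracy",
                    "miou") %in% names(met)))
  unlink(out, recursive = TRUE)
})

test_that("reruns with one seed give identical split and series artifacts", {
  run_once <- function(dir) {
    cfg <- run_config(list(
      out_dir = dir, seed = 11, sites = 1, years = "2015:2019",
      scene = list(height = 48, width = 48), resize_side = 48,
      jitter = list(max_rotation_deg = 2, max_translation_frac = 0.02,
                    max_scale_delta = 0.02),
      unet = list(depth = 2, base_filters = 4, dropout_rate = 0),
      train = list(batch_size = 4, learning_rate = 1e-3, optimizer = "adam",
                   max_epochs = 2, early_stop_patience = 1)))
    suppressWarnings(run_end_to_end(cfg))
  }
  d1 <- file.path(tempdir(), "svimon-rep1")
  d2 <- file.path(tempdir(), "svimon-rep2")
  unlink(c(d1, d2), recursive = TRUE)
  run_once(d1); run_once(d2)
  for (f in c("series/site01.csv", "history.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # album manifests match apart from the run-directory prefix in paths
  m1 <- read.csv(file.path(d1, "manifest_album.csv"))
  m2 <- read.csv(file.path(d2, "manifest_album.csv"))
  drop_paths <- function(m) m[setdiff(names(m), c("path", "mask_path"))]
  expect_identical(drop_paths(m1), drop_paths(m2))
  expect_identical(basename(m1$path), basename(m2$path))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the CLI generates albums and registers pairs", {
  out <- file.path(tempdir(), "svimon-cli")
  unlink(out, recursive = TRUE)
  status <- svi_cli(c("generate", "--sites", "1", "--years", "2015:2015",
                      "--per-quarter", "1", "--out", out, "--seed", "3",
                      "--size", "96"))
  expect_identical(status, 0L)
  mf <- read.csv(file.path(out, "manifest.csv"))
  expect_identical(nrow(mf), 4L)
  expect_true(all(file.exists(mf$path)), all(file.exists(mf$mask_path)))

  regdir <- file.path(out, "reg")
  status <- svi_cli(c("register", "--reference", mf$path[1],
                      "--sensed", mf$path[2], "--out", regdir,
                      "--checkerboard"))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(regdir, "registered.ppm")))
  expect_true(file.exists(file.path(regdir, "transform.json")))
  expect_true(file.exists(file.path(regdir, "checkerboard.ppm")))
  tf <- jsonlite::fromJSON(file.path(regdir, "transform.json"))
  expect_length(tf$matrix, 6)

  expect_identical(svi_cli(character(0)), 2L)
  expect_identical(svi_cli("frobnicate"), 2L)
  expect_identical(svi_cli(c("register", "--reference", "nope.ppm")), 2L)
  unlink(out, recursive = TRUE)
})
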