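#' Semantic Vegetation Index of a mask
#'
#' The SVI of an image is the percentage of its pixels classified as
#' vegetation: `SVI = 100 * sum(SP_a) / sum(Area_t)` where `SP_a` is the
#' vegetation (semantic) pixel count and `Area_t` the total pixel count
#' of each image entering the index. With a single image this is the
#' per-image vegetation fraction times 100.
#'
#' @param mask non-empty H x W class-id matrix.
#' @param vegetation_class id counted as vegetation (default 1).
#' @param site_id,year,quarter optional metadata carried into the record.
#' @return an `svi_record` list: `site_id`, `year`, `quarter`,
#'   `svi_percent`, `sp_a`, `area_t`, `n_images = 1`.
#' @export
compute_svi <- function(mask, vegetation_class = 1L, site_id = NA_character_,
                        year = NA_integer_, quarter = NA_integer_) {
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  sp_a <- sum(mask == vegetation_class)
  area_t <- length(mask)
  structure(list(site_id = site_id, year = as.integer(year),
                 quarter = as.integer(quarter),
                 svi_percent = 100 * sp_a / area_t,
                 sp_a = sp_a, area_t = area_t, n_images = 1L),
            class = "svi_record")
}

#' SVI of an image via a trained segmentation model
#'
#' Predicts the mask with [predict_mask()] and applies [compute_svi()].
#'
#' @param model trained segmentation model.
#' @param image H x W x 3 array (0..255).
#' @param vegetation_class id counted as vegetation.
#' @param site_id,year,quarter metadata for the record.
#' @return an `svi_record`.
#' @export
svi_from_image <- function(model, image, vegetation_class = 1L,
                           site_id = NA_character_, year = NA_integer_,
                           quarter = NA_integer_) {
  pred <- predict_mask(model, image)
  compute_svi(pred$mask, vegetation_class, site_id, year, quarter)
}

#' Aggregate per-image SVI records into a quarterly site series
#'
#' Per (year, quarter) the arithmetic mean of the member `svi_percent`
#' values is reported with the contributing image count. Quarters between
#' the first and last populated quarter with no record are emitted as
#' explicit gaps (`svi_percent = NA`, `n_images = 0`), never interpolated.
#'
#' @param records list of `svi_record` objects sharing one `site_id`.
#' @return a `site_series`: data.frame (site_id, year, quarter,
#'   svi_percent, n_images) in strictly increasing (year, quarter) order.
#' @export
quarterly_series <- function(records) {
  if (length(records) == 0) stop("no records", call. = FALSE)
  sid <- unique(vapply(records, `[[`, character(1), "site_id"))
  if (length(sid) != 1)
    stop("records mix site ids: ", paste(sid, collapse = ", "), call. = FALSE)
  df <- data.frame(
    year = vapply(records, function(r) as.integer(r[["year"]]), integer(1)),
    quarter = vapply(records, function(r) as.integer(r[["quarter"]]),
                     integer(1)),
    svi = vapply(records, function(r) as.numeric(r[["svi_percent"]]),
                 numeric(1)))
  if (anyNA(df$year) || anyNA(df$quarter))
    stop("records must carry year and quarter", call. = FALSE)
  agg <- aggregate(svi ~ year + quarter, df, mean)
  cnt <- aggregate(svi ~ year + quarter, df, length)
  key <- function(y, q) 4 * y + (q - 1)
  k0 <- min(key(df$year, df$quarter)); k1 <- max(key(df$year, df$quarter))
  ks <- k0:k1
  out <- data.frame(site_id = sid, year = ks %/% 4, quarter = ks %% 4 + 1,
                    svi_percent = NA_real_, n_images = 0L)
  m <- match(key(agg$year, agg$quarter), ks)
  out$svi_percent[m] <- agg$svi
  out$n_images[m] <- cnt$svi
  structure(out, class = c("site_series", "data.frame"))
}

#' Write / read a quarterly site series as CSV
#'
#' The file carries exactly the header
#' `site_id,year,quarter,svi_percent,n_images`; gaps are stored with an
#' empty `svi_percent`. `read_series(write (x)) == x`.
#'
#' @param series a `site_series` (see [quarterly_series()]).
#' @param path file path.
#' @return `export_series` returns `path` invisibly; `read_series`
#'   returns the `site_series`.
#' @export
export_series <- function(series, path) {
  stopifnot(inherits(series, "site_series"))
  df <- as.data.frame(series)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("site_id,year,quarter,svi_percent,n_images", con)
  writeLines(sprintf("%s,%d,%d,%s,%d", df$site_id, df$year, df$quarter,
                     ifelse(is.na(df$svi_percent), "",
                            format(df$svi_percent, digits = 15,
                                   scientific = FALSE, trim = TRUE)),
                     df$n_images), con)
  invisible(path)
}

#' @rdname export_series
#' @export
read_series <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 ||
      lines[1] != "site_id,year,quarter,svi_percent,n_images")
    stop("line 1: expected header 'site_id,year,quarter,svi_percent,n_images'",
         call. = FALSE)
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(f) < 4 || length(f) > 5)
      stop(sprintf("line %d: expected 5 comma-separated fields", i),
           call. = FALSE)
    if (length(f) == 4) f <- c(f[1:3], "", f[4])  # empty svi before last comma
    y <- suppressWarnings(as.integer(f[2]))
    q <- suppressWarnings(as.integer(f[3]))
    s <- if (nzchar(f[4])) suppressWarnings(as.numeric(f[4])) else NA_real_
    n <- suppressWarnings(as.integer(f[5]))
    if (is.na(y) || is.na(q) || is.na(n) || (nzchar(f[4]) && is.na(s)))
      stop(sprintf("line %d: malformed numeric field", i), call. = FALSE)
    if (!q %in% 1:4)
      stop(sprintf("line %d: quarter must be in 1..4 (got %s)", i, f[3]),
           call. = FALSE)
    data.frame(site_id = f[1], year = y, quarter = q, svi_percent = s,
               n_images = n)
  })
  out <- do.call(rbind, rows)
  k <- 4 * out$year + out$quarter
  if (any(diff(k) <= 0))
    stop("series rows must be strictly increasing in (year, quarter)",
         call. = FALSE)
  structure(out, class = c("site_series", "data.frame"))
}

#' Plot a quarterly site series
#'
#' Draws the mean SVI per quarter against time (quarter boundaries on the
#' x axis), leaving gaps where no record exists.
#'
#' @param x a `site_series`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.site_series <- function(x, ...) {
  tt <- x$year + (x$quarter - 1) / 4
  graphics::plot(tt, x$svi_percent, type = "b", pch = 16,
                 xlab = "year (quarterly)", ylab = "mean SVI [%]",
                 main = paste("Site", x$site_id[1]), ylim = c(0, 100), ...)
  invisible(x)
}
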