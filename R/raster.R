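#' Scene pair: an RGB raster plus its aligned class-id mask
#'
#' The unit flowing through the whole pipeline. `image` is an H x W x 3
#' numeric array with 8-bit channel values (0..255); `mask` is an H x W
#' integer matrix of class ids (0 = other, 1 = vegetation, 2 = sky).
#'
#' @param image H x W x 3 numeric array, values in 0..255.
#' @param mask H x W integer matrix with ids in `0:2`.
#' @param site_id character site identifier.
#' @param year,quarter capture timestamp; `quarter` in 1..4.
#' @return an object of class `scene_pair`.
#' @export
scene_pair <- function(image, mask, site_id = "site", year = NA_integer_,
                       quarter = NA_integer_) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3)
    stop("`image` must be an H x W x 3 array", call. = FALSE)
  if (!is.matrix(mask) || !all(dim(mask) == d[1:2]))
    stop("`mask` must be a matrix with the image's H x W", call. = FALSE)
  ids <- unique(as.integer(mask))
  if (!all(ids %in% 0:2))
    stop("mask contains undefined class ids: ",
         paste(setdiff(ids, 0:2), collapse = ", "), call. = FALSE)
  if (!is.na(quarter) && !(quarter %in% 1:4))
    stop("`quarter` must be in 1..4", call. = FALSE)
  structure(list(image = image, mask = base::matrix(as.integer(mask), d[1], d[2]),
                 site_id = as.character(site_id),
                 year = as.integer(year), quarter = as.integer(quarter)),
            class = "scene_pair")
}

#' @export
print.scene_pair <- function(x, ...) {
  cat(sprintf("<scene_pair> %dx%d site=%s %s Q%s veg=%.1f%%\n",
              nrow(x$mask), ncol(x$mask), x$site_id,
              ifelse(is.na(x$year), "?", x$year),
              ifelse(is.na(x$quarter), "?", x$quarter),
              100 * mean(x$mask == 1L)))
  invisible(x)
}

# ---- portable netpbm raster I/O (plain-text P2/P3) -------------------------
# The toolchain stores rasters as ASCII netpbm: PPM (P3) for RGB images and
# PGM (P2) for class-id masks. Lossless, greppable, and readable with base R.

#' Read and write rasters as plain-text netpbm (PPM/PGM)
#'
#' `write_ppm()` stores an H x W x 3 array as ASCII PPM (magic `P3`);
#' `write_pgm()` stores a matrix as ASCII PGM (`P2`). The readers invert
#' them exactly. Values are clamped to 0..maxval and rounded.
#'
#' @param x raster to write (array for PPM, matrix for PGM).
#' @param path file path.
#' @param maxval maximum sample value written to the header.
#' @return the reader functions return the raster; writers return `path`
#'   invisibly.
#' @export
write_ppm <- function(x, path, maxval = 255L) {
  d <- dim(x)
  if (length(d) != 3 || d[3] != 3) stop("PPM needs an H x W x 3 array")
  v <- as.integer(round(.clip255(as.numeric(x))))
  # interleave channels pixel by pixel, row-major as the format requires
  arr <- aperm(array(v, d), c(3, 2, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), as.character(maxval)), con)
  apply_rows <- vapply(seq_len(d[1]), function(r)
    paste(arr[, , r], collapse = " "), character(1))
  writeLines(apply_rows, con)
  invisible(path)
}

#' @rdname write_ppm
#' @export
write_pgm <- function(x, path, maxval = 255L) {
  if (!is.matrix(x)) stop("PGM needs a matrix")
  v <- base::matrix(as.integer(round(as.numeric(x))), nrow(x), ncol(x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(x), nrow(x)), as.character(maxval)), con)
  writeLines(vapply(seq_len(nrow(x)), function(r)
    paste(v[r, ], collapse = " "), character(1)), con)
  invisible(path)
}

.read_pnm_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- scan(text = paste(lines, collapse = "\n"), what = character(),
               quiet = TRUE)
  toks
}

#' @rdname write_ppm
#' @export
read_ppm <- function(path) {
  toks <- .read_pnm_tokens(path)
  if (toks[1] != "P3") stop("not an ASCII PPM (P3) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  v <- as.numeric(toks[-(1:4)])
  if (length(v) != w * h * 3) stop("corrupt PPM payload: ", path)
  aperm(array(v, c(3, w, h)), c(3, 2, 1))
}

#' @rdname write_ppm
#' @export
read_pgm <- function(path) {
  toks <- .read_pnm_tokens(path)
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  v <- as.integer(toks[-(1:4)])
  if (length(v) != w * h) stop("corrupt PGM payload: ", path)
  base::matrix(v, h, w, byrow = TRUE)
}

# grayscale luma in 0..255 from an RGB array
to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
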