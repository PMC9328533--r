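#' Affine transform in pixel coordinates
#'
#' A 2x3 coefficient matrix mapping 0-based pixel coordinates
#' `(x, y, 1)` (x = column, y = row) of a sensed image into a reference
#' frame. The linear 2x2 part must be non-singular.
#'
#' @param matrix numeric 2x3 matrix of coefficients.
#' @return an object of class `affine_transform`.
#' @examples
#' affine_identity()
#' affine_from_params(rotation_deg = 5, translation = c(3, -2))
#' @export
affine_transform <- function(matrix) {
  m <- base::matrix(as.numeric(matrix), 2, 3)
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det) <= 1e-6)
    stop("affine transform is singular (|det| <= 1e-6)", call. = FALSE)
  structure(list(matrix = m), class = "affine_transform")
}

#' @rdname affine_transform
#' @export
affine_identity <- function() {
  affine_transform(cbind(diag(2), c(0, 0)))
}

#' Build an affine transform from rotation/translation/scale about a centre
#'
#' @param rotation_deg rotation angle in degrees (counter-clockwise in
#'   image axes).
#' @param translation length-2 numeric `(tx, ty)` in pixels.
#' @param scale isotropic scale factor.
#' @param center length-2 numeric `(cx, cy)` fixed point of rotation and
#'   scaling, in 0-based pixel coordinates.
#' @rdname affine_transform
#' @export
affine_from_params <- function(rotation_deg = 0, translation = c(0, 0),
                               scale = 1, center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  R <- scale * base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t <- center - R %*% center + translation
  affine_transform(cbind(R, t))
}

#' Apply an affine transform to points
#'
#' @param tf an `affine_transform`.
#' @param pts n x 2 matrix of `(x, y)` coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
affine_apply <- function(tf, pts) {
  stopifnot(inherits(tf, "affine_transform"))
  pts <- base::matrix(as.numeric(pts), ncol = 2)
  out <- cbind(pts, 1) %*% t(tf$matrix)
  colnames(out) <- c("x", "y")
  out
}

#' Invert / compose affine transforms
#'
#' `affine_invert(tf)` returns the inverse map; `affine_compose(a, b)`
#' returns the transform applying `b` first, then `a`.
#'
#' @param tf,a,b `affine_transform` objects.
#' @export
affine_invert <- function(tf) {
  stopifnot(inherits(tf, "affine_transform"))
  A <- tf$matrix[, 1:2]
  t <- tf$matrix[, 3]
  Ai <- solve(A)
  affine_transform(cbind(Ai, -Ai %*% t))
}

#' @rdname affine_invert
#' @export
affine_compose <- function(a, b) {
  stopifnot(inherits(a, "affine_transform"), inherits(b, "affine_transform"))
  A <- a$matrix[, 1:2]
  affine_transform(cbind(A %*% b$matrix[, 1:2],
                         A %*% b$matrix[, 3] + a$matrix[, 3]))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Mean displacement of image corners under a transform pair
#'
#' Measures how far `est` deviates from `truth` by mapping the four
#' 0-based corner pixels of an `h` x `w` frame through
#' `est o truth^-1` and averaging their displacement. The standard
#' registration accuracy summary used by the test-suite.
#'
#' @param est,truth `affine_transform` objects.
#' @param h,w frame dimensions in pixels.
#' @return mean corner displacement in pixels.
#' @export
corner_error <- function(est, truth, h, w) {
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  d <- affine_apply(affine_compose(est, affine_invert(truth)), corners) - corners
  mean(sqrt(rowSums(d^2)))
}

# Warp an H x W (x C) numeric array. `tf` maps OUTPUT pixel coordinates to
# INPUT pixel coordinates (inverse mapping). method "bilinear" or "nearest".
warp_array <- function(x, tf, out_h = NULL, out_w = NULL,
                       method = c("bilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  d <- dim(x)
  if (is.null(d)) stop("`x` must be a matrix or array", call. = FALSE)
  H <- d[1]; W <- d[2]; C <- if (length(d) >= 3) d[3] else 1L
  if (is.null(out_h)) out_h <- H
  if (is.null(out_w)) out_w <- W
  v <- cpp_warp_affine(as.numeric(x), H, W, C, out_h, out_w, tf$matrix,
                       method == "bilinear", fill)
  if (length(d) >= 3) array(v, c(out_h, out_w, C)) else
    base::matrix(v, out_h, out_w)
}
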