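# Classical keypoint registration: Harris corners with sub-pixel
# refinement, normalized patch descriptors, mutual ratio-test matching,
# and RANSAC affine estimation with a least-squares consensus refit.

.harris_corners <- function(gray, n_max = 250L, k = 0.04, min_dist = 4L) {
  g <- .gauss_blur_mat(gray, 1)
  H <- nrow(g); W <- ncol(g)
  gx <- g; gy <- g
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gx[, c(1, W)] <- 0
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  gy[c(1, H), ] <- 0
  Sxx <- .gauss_blur_mat(gx * gx, 1.5)
  Syy <- .gauss_blur_mat(gy * gy, 1.5)
  Sxy <- .gauss_blur_mat(gx * gy, 1.5)
  R <- (Sxx * Syy - Sxy^2) - k * (Sxx + Syy)^2
  b <- 8L  # keep clear of the frame so descriptors fit
  Rin <- R[(b + 1):(H - b), (b + 1):(W - b)]
  thr <- max(Rin) * 1e-4
  # 3x3 non-maximum suppression via shifted comparisons
  is_max <- Rin >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- Rin
    ry <- seq_len(nrow(Rin)) + dy; rx <- seq_len(ncol(Rin)) + dx
    ok_y <- ry >= 1 & ry <= nrow(Rin); ok_x <- rx >= 1 & rx <= ncol(Rin)
    cmp <- base::matrix(-Inf, nrow(Rin), ncol(Rin))
    cmp[ok_y, ok_x] <- Rin[ry[ok_y], rx[ok_x]]
    is_max <- is_max & (Rin >= cmp)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(base::matrix(numeric(0), 0, 2))
  score <- Rin[idx]
  ord <- order(-score)
  idx <- idx[ord, , drop = FALSE]
  # greedy spatial thinning, strongest first
  keep <- logical(nrow(idx))
  taken <- base::matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    if (nrow(taken) == 0 ||
        min((taken[, 1] - p[1])^2 + (taken[, 2] - p[2])^2) >= min_dist^2) {
      keep[i] <- TRUE
      taken <- rbind(taken, p)
      if (nrow(taken) >= n_max) break
    }
  }
  idx <- idx[keep, , drop = FALSE]
  # sub-pixel quadratic refinement on the response surface
  pts <- base::matrix(0, nrow(idx), 2)
  for (i in seq_len(nrow(idx))) {
    y <- idx[i, 1] + b; x <- idx[i, 2] + b
    dxo <- dyo <- 0
    if (y > 1 && y < H && x > 1 && x < W) {
      dR_dx <- (R[y, x + 1] - R[y, x - 1]) / 2
      dR_dy <- (R[y + 1, x] - R[y - 1, x]) / 2
      d2x <- R[y, x + 1] - 2 * R[y, x] + R[y, x - 1]
      d2y <- R[y + 1, x] - 2 * R[y, x] + R[y - 1, x]
      if (d2x < 0) dxo <- max(-0.5, min(0.5, -dR_dx / d2x))
      if (d2y < 0) dyo <- max(-0.5, min(0.5, -dR_dy / d2y))
    }
    pts[i, ] <- c(x - 1 + dxo, y - 1 + dyo)   # 0-based (x, y)
  }
  pts
}

# normalized intensity patch sampled bilinearly on a (2*half+1)^2 grid
# with spacing `scale` around each keypoint; scale > 1 samples a larger
# neighbourhood, making matching tolerant to moderate zoom
.patch_descriptors <- function(gray, pts, half = 5L, scale = 1) {
  n <- nrow(pts)
  side <- 2L * half + 1L
  D <- base::matrix(0, n, side^2)
  if (n == 0) return(D)
  offs <- as.matrix(expand.grid(dy = (-half:half) * scale,
                                dx = (-half:half) * scale))
  H <- nrow(gray); W <- ncol(gray)
  for (i in seq_len(n)) {
    xx <- pts[i, 1] + offs[, "dx"]   # 0-based coords
    yy <- pts[i, 2] + offs[, "dy"]
    x0 <- floor(xx); y0 <- floor(yy)
    fx <- xx - x0; fy <- yy - y0
    x0 <- pmin(pmax(x0, 0), W - 2); y0 <- pmin(pmax(y0, 0), H - 2)
    v <- (1 - fx) * (1 - fy) * gray[cbind(y0 + 1, x0 + 1)] +
         fx * (1 - fy) * gray[cbind(y0 + 1, x0 + 2)] +
         (1 - fx) * fy * gray[cbind(y0 + 2, x0 + 1)] +
         fx * fy * gray[cbind(y0 + 2, x0 + 2)]
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    D[i, ] <- if (nv > 1e-9) v / nv else 0
  }
  D
}

#' Match keypoints between two images
#'
#' Detects Harris corners in both grayscale images, describes them with
#' normalized intensity patches, and returns mutual nearest-neighbour
#' matches passing Lowe's ratio test.
#'
#' @param reference,sensed H x W x 3 arrays or grayscale matrices.
#' @param n_keypoints corners to keep per image.
#' @param ratio Lowe ratio-test threshold on descriptor distances.
#' @return a `match_set`: `list(ref = n x 2, sensed = n x 2, score = n)`
#'   of 0-based (x, y) coordinates.
#' @export
match_keypoints <- function(reference, sensed, n_keypoints = 250L,
                            ratio = 0.92) {
  g1 <- if (length(dim(reference)) == 3) to_gray(reference) else reference
  g2 <- if (length(dim(sensed)) == 3) to_gray(sensed) else sensed
  p1 <- .harris_corners(g1, n_keypoints)
  p2 <- .harris_corners(g2, n_keypoints)
  if (nrow(p1) < 3 || nrow(p2) < 3)
    return(structure(list(ref = p1[0, , drop = FALSE],
                          sensed = p2[0, , drop = FALSE],
                          score = numeric(0)), class = "match_set"))
  # describe on the smoothed images for photometric-noise robustness;
  # the sensed side is described over a small scale search so moderate
  # zoom between visits still matches
  b1 <- .gauss_blur_mat(g1, 1); b2 <- .gauss_blur_mat(g2, 1)
  d1 <- .patch_descriptors(b1, p1)
  sim <- base::matrix(-Inf, nrow(p1), nrow(p2))
  for (sc in c(0.9, 1, 1.1))
    sim <- pmax(sim, d1 %*% t(.patch_descriptors(b2, p2, scale = sc)))
  best21 <- max.col(t(sim), ties.method = "first")   # for each sensed kp
  pick <- integer(0); qual <- numeric(0); sens <- integer(0)
  for (i in seq_len(nrow(p1))) {
    s <- sim[i, ]
    j <- which.max(s)
    if (best21[j] != i) next                          # mutual check
    s2 <- if (length(s) > 1) max(s[-j]) else -1
    dist1 <- sqrt(max(0, 2 - 2 * s[j]))
    dist2 <- sqrt(max(0, 2 - 2 * s2))
    if (dist2 > 1e-9 && dist1 / dist2 > ratio) next   # ratio test
    pick <- c(pick, i); sens <- c(sens, j); qual <- c(qual, s[j])
  }
  structure(list(ref = p1[pick, , drop = FALSE],
                 sensed = p2[sens, , drop = FALSE], score = qual),
            class = "match_set")
}

.fit_affine_ls <- function(ref, sensed) {
  # least squares for r = A s + t over matched points
  n <- nrow(ref)
  X <- cbind(sensed, 1)
  cf <- tryCatch(qr.solve(X, ref), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  m <- rbind(c(cf[1, 1], cf[2, 1], cf[3, 1]),
             c(cf[1, 2], cf[2, 2], cf[3, 2]))
  det <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(det) || abs(det) <= 1e-6) return(NULL)
  affine_transform(m)
}

.collinear <- function(pts, tol = 1e-6) {
  if (nrow(pts) < 3) return(TRUE)
  p <- sweep(pts, 2, colMeans(pts))
  sv <- svd(p)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Estimate an affine transform from point matches with RANSAC
#'
#' Samples minimal 3-point subsets, scores consensus by reprojection
#' error, and refits by least squares on the final inlier set.
#' Matches are canonically sorted internally, so the estimate is
#' invariant to match ordering.
#'
#' @param matches a `match_set` (see [match_keypoints()]) or a list with
#'   `ref` and `sensed` n x 2 coordinate matrices (n >= 3).
#' @param ransac_threshold_px inlier reprojection threshold in pixels.
#' @param max_iters RANSAC iterations.
#' @param seed RNG seed (deterministic result for a given seed).
#' @return `list(transform = affine_transform mapping sensed -> reference,
#'   inliers = logical vector over matches)`.
#' @export
estimate_affine <- function(matches, ransac_threshold_px = 2, max_iters = 500L,
                            seed = 1L) {
  ref <- base::matrix(as.numeric(matches$ref), ncol = 2)
  sen <- base::matrix(as.numeric(matches$sensed), ncol = 2)
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 matches to estimate an affine",
                  call. = FALSE)
  ord <- order(ref[, 1], ref[, 2], sen[, 1], sen[, 2])
  ref <- ref[ord, , drop = FALSE]; sen <- sen[ord, , drop = FALSE]
  if (.collinear(sen) || .collinear(ref))
    stop("matches are collinear; affine is underdetermined", call. = FALSE)
  thr2 <- ransac_threshold_px^2
  best <- NULL; best_in <- rep(FALSE, n)
  with_seed(seed, {
    for (it in seq_len(max_iters)) {
      s <- sample.int(n, 3)
      if (.collinear(sen[s, , drop = FALSE], 1e-3)) next
      tf <- .fit_affine_ls(ref[s, , drop = FALSE], sen[s, , drop = FALSE])
      if (is.null(tf)) next
      e <- affine_apply(tf, sen) - ref
      inl <- (e[, 1]^2 + e[, 2]^2) <= thr2
      if (sum(inl) > sum(best_in)) { best_in <- inl; best <- tf }
      if (sum(best_in) > 0.8 * n && it >= 50) break
    }
  })
  if (is.null(best) || sum(best_in) < 3)
    stop("RANSAC found no 3-point consensus", call. = FALSE)
  if (.collinear(sen[best_in, , drop = FALSE]))
    stop("RANSAC consensus is collinear", call. = FALSE)
  # refit on inliers with re-selection, then tighten the threshold once
  # if enough support remains (suppresses borderline pseudo-matches)
  for (t2 in c(thr2, thr2, thr2 / 4)) {
    cand_in <- if (t2 == thr2) best_in else {
      e <- affine_apply(best, sen) - ref
      (e[, 1]^2 + e[, 2]^2) <= t2
    }
    if (sum(cand_in) < max(6, 3) && t2 < thr2) break
    tf <- .fit_affine_ls(ref[cand_in, , drop = FALSE],
                         sen[cand_in, , drop = FALSE])
    if (is.null(tf)) break
    best <- tf
    e <- affine_apply(best, sen) - ref
    best_in <- (e[, 1]^2 + e[, 2]^2) <= thr2
  }
  inl_orig <- logical(n)
  inl_orig[ord] <- best_in
  list(transform = best, inliers = inl_orig)
}

#' Register a sensed repeat photograph to a reference image
#'
#' Keypoint matching plus RANSAC affine estimation (with a least-squares
#' refit over the consensus set) yields the transform mapping sensed
#' pixel coordinates into the reference frame. The sensed image is
#' warped onto the reference grid (out-of-frame pixels zero-filled).
#'
#' @param reference,sensed H x W x 3 arrays (or grayscale matrices);
#'   converted to grayscale internally for matching.
#' @param ransac_threshold_px RANSAC inlier threshold in pixels.
#' @param seed RNG seed for RANSAC.
#' @return `list(registered = warped sensed image with the reference's
#'   dimensions, transform = affine_transform (sensed -> reference),
#'   matches = inlier match_set)`.
#' @seealso [estimate_affine()], [checkerboard_mosaic()]
#' @export
register_pair <- function(reference, sensed, ransac_threshold_px = 2,
                          seed = 1L) {
  if (length(reference) == 0 || length(sensed) == 0)
    stop("empty image", call. = FALSE)
  ms <- match_keypoints(reference, sensed)
  if (nrow(ms$ref) < 3)
    stop("registration failure: fewer than 3 keypoint matches",
         call. = FALSE)
  est <- tryCatch(
    estimate_affine(ms, ransac_threshold_px, seed = seed),
    error = function(e)
      stop("registration failure: ", conditionMessage(e), call. = FALSE))
  if (sum(est$inliers) < max(6, 0.15 * nrow(ms$ref)))
    stop("registration failure: consensus too small (",
         sum(est$inliers), " inliers)", call. = FALSE)
  tf <- est$transform
  g1 <- if (length(dim(reference)) == 3) to_gray(reference) else reference
  outH <- nrow(g1); outW <- ncol(g1)
  inv <- affine_invert(tf)       # reference grid -> sensed coords
  registered <- warp_array(sensed, inv, outH, outW, "bilinear", fill = 0)
  inl <- structure(list(ref = ms$ref[est$inliers, , drop = FALSE],
                        sensed = ms$sensed[est$inliers, , drop = FALSE],
                        score = ms$score[est$inliers]),
                   class = "match_set")
  list(registered = registered, transform = tf, matches = inl)
}

#' Checkerboard mosaic of a reference and a registered image
#'
#' Alternates square tiles from the two inputs for visual inspection of
#' alignment; tiles of even parity (top-left first) come from the
#' reference.
#'
#' @param reference,registered equal-dimension images.
#' @param tiles number of tiles along each axis (>= 2).
#' @return mosaic image with the reference's dimensions.
#' @export
checkerboard_mosaic <- function(reference, registered, tiles = 8L) {
  if (!all(dim(reference) == dim(registered)))
    stop("images must share dimensions", call. = FALSE)
  if (tiles < 2) stop("`tiles` must be >= 2", call. = FALSE)
  d <- dim(reference)
  H <- d[1]; W <- d[2]
  th <- ceiling(H / tiles); tw <- ceiling(W / tiles)
  ty <- (matrix(seq_len(H), H, W) - 1) %/% th
  tx <- (matrix(seq_len(W), H, W, byrow = TRUE) - 1) %/% tw
  use_ref <- (ty + tx) %% 2 == 0
  out <- reference
  if (length(d) == 3) {
    for (ch in seq_len(d[3])) {
      plane <- out[, , ch]; reg <- registered[, , ch]
      plane[!use_ref] <- reg[!use_ref]
      out[, , ch] <- plane
    }
  } else out[!use_ref] <- registered[!use_ref]
  out
}
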