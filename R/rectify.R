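#' Epipolar rectification of an image pair
#'
#' Resamples two views so that corresponding points share a row
#' coordinate, reducing stereo matching to a 1-D scan-line search. With
#' full calibration (`method = "calibrated"`) both cameras are rotated
#' onto a common plane whose x-axis is the baseline; with only point
#' correspondences (`method = "uncalibrated"`) the Hartley method maps the
#' second epipole to infinity and aligns the first view by a matching
#' projective transform estimated from the correspondences.
#'
#' Both homographies receive a common vertical offset so rectified rows
#' remain aligned; per-image horizontal offsets keep the content in frame.
#' An already row-aligned pair (pure x-translation, identical intrinsics)
#' yields identity homographies.
#'
#' @param image_i,image_j Grayscale image matrices.
#' @param cameras List of the two [camera_model()]s (calibrated method).
#' @param F Fundamental matrix (uncalibrated method).
#' @param points_i,points_j Correspondences for the uncalibrated method.
#' @param method `"calibrated"` (default when cameras are given) or
#'   `"uncalibrated"`.
#' @param pair Optional integer pair `(ci, cj)` recorded in the result.
#' @return An object of class `rectified_pair`: list with `images`
#'   (two resampled images), `H` (two 3x3 pixel-to-rectified-pixel
#'   homographies), `size` (common output height, per-image widths) and
#'   `pair`.
#' @export
rectify_pair <- function(image_i, image_j, cameras = NULL, F = NULL,
                         points_i = NULL, points_j = NULL,
                         method = if (!is.null(cameras)) "calibrated" else "uncalibrated",
                         pair = NULL) {
  stopifnot_image(image_i); stopifnot_image(image_j)
  size_i <- c(ncol(image_i), nrow(image_i))
  size_j <- c(ncol(image_j), nrow(image_j))
  method <- match.arg(method, c("calibrated", "uncalibrated"))
  if (method == "calibrated") {
    if (is.null(cameras) || length(cameras) != 2)
      stop("calibrated rectification needs a list of two cameras", call. = FALSE)
    check_epipoles_outside(cameras[[1]], cameras[[2]], size_i, size_j)
    Hs <- rectify_homographies_calibrated(cameras[[1]], cameras[[2]])
    if (is.null(pair)) pair <- c(cameras[[1]]$camera_id, cameras[[2]]$camera_id)
  } else {
    if (is.null(F)) {
      if (is.null(points_i) || is.null(points_j))
        stop("uncalibrated rectification needs F or correspondences", call. = FALSE)
      F <- estimate_fundamental(points_i, points_j)
    }
    if (is.null(points_i)) stop("uncalibrated rectification needs correspondences", call. = FALSE)
    Hs <- rectify_homographies_uncalibrated(F, points_i, points_j, size_j)
  }

  off <- rectification_offsets(Hs, size_i, size_j)
  out <- list(
    images = list(warp_image(image_i, off$H[[1]], off$out_size[[1]]),
                  warp_image(image_j, off$H[[2]], off$out_size[[2]])),
    H = off$H,
    size = off$out_size,
    pair = pair,
    method = method
  )
  class(out) <- "rectified_pair"
  out
}

#' @export
print.rectified_pair <- function(x, ...) {
  cat(sprintf("<rectified_pair> method = %s, pair = %s\n", x$method,
              if (is.null(x$pair)) "?" else paste(x$pair, collapse = "|")))
  cat(sprintf("  sizes: %dx%d and %dx%d (w x h)\n",
              x$size[[1]][1], x$size[[1]][2], x$size[[2]][1], x$size[[2]][2]))
  invisible(x)
}

# Fusiello-style calibrated rectification: common rotation whose x-axis is
# the baseline, shared averaged intrinsics.
rectify_homographies_calibrated <- function(cam_i, cam_j) {
  Ci <- camera_center(cam_i); Cj <- camera_center(cam_j)
  base <- Cj - Ci
  if (sqrt(sum(base^2)) < 1e-9) stop("coincident camera centers", call. = FALSE)
  r1 <- unit(base)
  z_old <- cam_i$R[3, ]  # optical axis of first camera, world frame
  r2 <- unit(cross3(z_old, r1))
  r3 <- cross3(r1, r2)
  R_new <- rbind(r1, r2, r3)
  K_new <- (intrinsic_matrix(cam_i) + intrinsic_matrix(cam_j)) / 2
  Hi <- K_new %*% R_new %*% t(cam_i$R) %*% solve(intrinsic_matrix(cam_i))
  Hj <- K_new %*% R_new %*% t(cam_j$R) %*% solve(intrinsic_matrix(cam_j))
  list(Hi / Hi[3, 3], Hj / Hj[3, 3])
}

# Hartley uncalibrated rectification: send the second epipole to infinity,
# then find the matching affine transform for the first view minimizing
# the horizontal disparity over the given correspondences.
rectify_homographies_uncalibrated <- function(F, points_i, points_j, size_j) {
  pi <- as_points(points_i); pj <- as_points(points_j)
  # epipole in view j: F^T e' = 0
  ep <- svd(t(unclass(F)))$v[, 3]
  if (abs(ep[3]) > 1e-12) ep <- ep / ep[3]
  cx <- (size_j[1] - 1) / 2; cy <- (size_j[2] - 1) / 2
  T1 <- matrix(c(1, 0, 0, 0, 1, 0, -cx, -cy, 1), 3, 3)
  e_t <- as.numeric(T1 %*% ep)
  phi <- atan2(e_t[2], e_t[1])
  Rr <- matrix(c(cos(phi), sin(phi), 0,
                 -sin(phi), cos(phi), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)  # rotate e onto the +x axis
  e_r <- as.numeric(Rr %*% e_t)
  G <- diag(3)
  if (is.finite(e_r[1]) && abs(e_r[3]) > 0) G[3, 1] <- -e_r[3] / e_r[1]
  Hj <- solve(T1) %*% G %*% Rr %*% T1

  # matching homography for view i: H0 = Hj M with F = [e']x M
  M <- skew3(ep) %*% unclass(F) + ep %*% t(c(1, 1, 1))
  H0 <- Hj %*% M
  a_i <- apply_homography(H0, pi)
  b_j <- apply_homography(Hj, pj)
  A <- cbind(a_i[, 1], a_i[, 2], 1)
  abc <- qr.solve(A, b_j[, 1])
  HA <- matrix(c(abc[1], 0, 0, abc[2], 1, 0, abc[3], 0, 1), 3, 3)
  Hi <- HA %*% H0
  list(Hi / Hi[3, 3], Hj / Hj[3, 3])
}

# Translate both homographies so warped content starts at pixel 0;
# the vertical offset is shared to preserve row alignment.
rectification_offsets <- function(Hs, size_i, size_j) {
  corners <- function(size) cbind(c(0, size[1] - 1, 0, size[1] - 1),
                                  c(0, 0, size[2] - 1, size[2] - 1))
  wi <- apply_homography(Hs[[1]], corners(size_i))
  wj <- apply_homography(Hs[[2]], corners(size_j))
  ty <- -min(wi[, 2], wj[, 2])
  tx_i <- -min(wi[, 1]); tx_j <- -min(wj[, 1])
  Ti <- matrix(c(1, 0, 0, 0, 1, 0, tx_i, ty, 1), 3, 3)
  Tj <- matrix(c(1, 0, 0, 0, 1, 0, tx_j, ty, 1), 3, 3)
  h_out <- ceiling(max(wi[, 2], wj[, 2]) + ty) + 1
  w_i <- ceiling(max(wi[, 1]) + tx_i) + 1
  w_j <- ceiling(max(wj[, 1]) + tx_j) + 1
  list(H = list(Ti %*% Hs[[1]], Tj %*% Hs[[2]]),
       out_size = list(c(w_i, h_out), c(w_j, h_out)))
}

check_epipoles_outside <- function(cam_i, cam_j, size_i, size_j) {
  inside <- function(px, size) {
    is.finite(px[1]) && is.finite(px[2]) &&
      px[1] >= 0 && px[1] <= size[1] - 1 && px[2] >= 0 && px[2] <= size[2] - 1
  }
  Ci <- camera_center(cam_i); Cj <- camera_center(cam_j)
  # epipole = image of the other camera's center; ignore if behind camera
  ep_i <- tryCatch(suppressWarnings(project_points(cam_i, Cj, distort = FALSE))[1, ],
                   error = function(e) c(NA, NA))
  ep_j <- tryCatch(suppressWarnings(project_points(cam_j, Ci, distort = FALSE))[1, ],
                   error = function(e) c(NA, NA))
  zi <- sum(cam_i$R[3, ] * (Cj - Ci)); zj <- sum(cam_j$R[3, ] * (Ci - Cj))
  if ((zi > 0 && inside(ep_i, size_i)) || (zj > 0 && inside(ep_j, size_j)))
    stop("rectification degeneracy: epipole lies inside an image", call. = FALSE)
  invisible(TRUE)
}

#' Warp an image by a homography
#'
#' Inverse-maps every output pixel through `solve(H)` and samples the
#' input bilinearly; out-of-frame samples are filled with `fill`.
#'
#' @param image Grayscale image matrix.
#' @param H 3x3 homography mapping input pixels to output pixels.
#' @param out_size `c(width, height)` of the output.
#' @param fill Fill value for samples outside the source image.
#' @return The warped image.
#' @export
warp_image <- function(image, H, out_size, fill = 0) {
  stopifnot_image(image)
  w <- out_size[1]; h <- out_size[2]
  Hinv <- solve(H)
  g <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  src <- apply_homography(Hinv, cbind(g$x, g$y))
  v <- bilinear_sample(image, src[, 1], src[, 2], fill = fill)
  matrix(v, nrow = h, byrow = TRUE)
}

#' Map rectified pixel coordinates back to original image coordinates
#'
#' @param rect A `rectified_pair` from [rectify_pair()].
#' @param pts Nx2 rectified pixel points.
#' @param which Side of the pair (1 or 2).
#' @return Nx2 matrix of original (unrectified) pixel coordinates.
#' @export
derectify_points <- function(rect, pts, which = 1) {
  apply_homography(solve(rect$H[[which]]), pts)
}
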