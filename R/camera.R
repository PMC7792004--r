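#' Pinhole camera model for a multi-camera rig
#'
#' Constructs a pinhole camera with radial/tangential lens distortion in a
#' metric rig frame. The rotation maps world (rig) coordinates into the
#' camera frame, `X_cam = R X + t`; all translations and 3D coordinates are
#' in millimetres. Pixel coordinates are 0-based with x = column and
#' y = row (downward), origin at the center of the top-left pixel.
#'
#' @param camera_id Integer camera identifier (1..4 on the standard rig).
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param cx,cy Principal point in pixels.
#' @param dist Distortion coefficients `c(k1, k2, p1, p2, k3)`
#'   (radial k1,k2,k3; tangential p1,p2). Defaults to no distortion.
#' @param R 3x3 world-to-camera rotation (orthonormal, det +1).
#' @param t Length-3 translation, millimetres.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(1, fx = 1800, fy = 1800, cx = 255.5, cy = 191.5)
#' camera_center(cam)
#' @export
camera_model <- function(camera_id, fx, fy, cx, cy,
                         dist = c(0, 0, 0, 0, 0),
                         R = diag(3), t = c(0, 0, 0)) {
  stopifnot(length(fx) == 1, length(fy) == 1, is.finite(fx), is.finite(fy))
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive", call. = FALSE)
  dist <- as.numeric(dist)
  if (length(dist) < 5) dist <- c(dist, rep(0, 5 - length(dist)))
  if (!all(is.finite(dist))) stop("distortion coefficients must be finite", call. = FALSE)
  R <- matrix(as.numeric(R), 3, 3)
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R must be orthonormal with determinant +1", call. = FALSE)
  t <- as.numeric(t)
  stopifnot(length(t) == 3, all(is.finite(t)))
  structure(list(camera_id = as.integer(camera_id),
                 fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy),
                 dist = dist, R = R, t = t),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model #%d>  f = (%.1f, %.1f) px, pp = (%.2f, %.2f)\n",
              x$camera_id, x$fx, x$fy, x$cx, x$cy))
  cat(sprintf("  center (mm): %s   distortion: %s\n",
              paste(sprintf("%.2f", camera_center(x)), collapse = ", "),
              if (all(x$dist == 0)) "none" else paste(signif(x$dist, 3), collapse = ", ")))
  invisible(x)
}

#' Camera center in the rig frame (millimetres)
#' @param camera A [camera_model()].
#' @return Length-3 numeric vector, `-R^T t`.
#' @export
camera_center <- function(camera) {
  as.numeric(-t(camera$R) %*% camera$t)
}

#' Intrinsic matrix K of a camera
#' @param camera A [camera_model()].
#' @return 3x3 upper-triangular intrinsic matrix.
#' @export
intrinsic_matrix <- function(camera) {
  matrix(c(camera$fx, 0, 0,
           0, camera$fy, 0,
           camera$cx, camera$cy, 1), 3, 3)
}

# Forward distortion in normalized image coordinates.
distort_normalized <- function(xn, yn, dist) {
  k1 <- dist[1]; k2 <- dist[2]; p1 <- dist[3]; p2 <- dist[4]; k3 <- dist[5]
  r2 <- xn^2 + yn^2
  radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- xn * radial + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
  cbind(xd, yd)
}

#' Project 3D rig-frame points into a camera
#'
#' Applies the full pinhole model with lens distortion.
#'
#' @param camera A [camera_model()].
#' @param X Nx3 matrix of 3D points (mm), or a length-3 vector.
#' @param distort Apply the lens distortion (default TRUE). With
#'   `distort = FALSE` the ideal (undistorted) pixel is returned.
#' @return Nx2 matrix of 0-based pixel coordinates (x, y).
#' @export
project_points <- function(camera, X, distort = TRUE) {
  X <- as_points(X)
  stopifnot(ncol(X) == 3)
  Xc <- X %*% t(camera$R) + matrix(camera$t, nrow(X), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0))
    warning("point(s) at or behind the camera plane")
  xn <- Xc[, 1] / Xc[, 3]
  yn <- Xc[, 2] / Xc[, 3]
  if (distort && any(camera$dist != 0)) {
    d <- distort_normalized(xn, yn, camera$dist)
    xn <- d[, 1]; yn <- d[, 2]
  }
  cbind(camera$fx * xn + camera$cx, camera$fy * yn + camera$cy)
}

#' Undistort observed pixel coordinates
#'
#' Inverts the polynomial distortion model by fixed-point iteration
#' (10 iterations, tolerance 1e-8 px), returning ideal pinhole pixels.
#'
#' @param camera A [camera_model()].
#' @param px Nx2 matrix of observed (distorted) 0-based pixels.
#' @param iterations,tol Iteration controls for the fixed-point inversion.
#' @return Nx2 matrix of undistorted pixel coordinates.
#' @export
undistort_points <- function(camera, px, iterations = 10, tol = 1e-8) {
  px <- as_points(px)
  if (all(camera$dist == 0)) return(px)
  xd <- (px[, 1] - camera$cx) / camera$fx
  yd <- (px[, 2] - camera$cy) / camera$fy
  xn <- xd; yn <- yd
  for (i in seq_len(iterations)) {
    d <- distort_normalized(xn, yn, camera$dist)
    # residual correction: d(xn) should reproduce the observed (xd, yd)
    xn2 <- xn + (xd - d[, 1])
    yn2 <- yn + (yd - d[, 2])
    step <- max(abs(xn2 - xn), abs(yn2 - yn)) * max(camera$fx, camera$fy)
    xn <- xn2; yn <- yn2
    if (step < tol) break
  }
  cbind(camera$fx * xn + camera$cx, camera$fy * yn + camera$cy)
}

#' Undistort a camera image
#'
#' Resamples the image so that straight world lines become straight: each
#' output pixel, interpreted as an ideal pinhole pixel, is filled by
#' bilinear sampling of the input at its forward-distorted location.
#' With all distortion coefficients zero the input is returned unchanged
#' (bit-exact).
#'
#' @param image Grayscale image matrix (see package conventions).
#' @param camera A [camera_model()] supplying intrinsics and distortion.
#' @return The undistorted image on the same pixel grid.
#' @export
correct_intrinsics <- function(image, camera) {
  stopifnot_image(image)
  if (all(camera$dist == 0)) return(image)
  h <- nrow(image); w <- ncol(image)
  g <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  xn <- (g$x - camera$cx) / camera$fx
  yn <- (g$y - camera$cy) / camera$fy
  d <- distort_normalized(xn, yn, camera$dist)
  xs <- camera$fx * d[, 1] + camera$cx
  ys <- camera$fy * d[, 2] + camera$cy
  v <- bilinear_sample(image, xs, ys, fill = 0)
  matrix(v, nrow = h, byrow = TRUE)
}

#' Cast the 3D viewing ray through a pixel
#'
#' Returns the ray from the camera center through the given (undistorted)
#' sub-pixel location. Projecting any point on the ray reproduces the
#' input pixel (for an undistorted, noiseless model).
#'
#' @param camera A [camera_model()].
#' @param pixel Nx2 matrix (or length-2 vector) of 0-based pixel points.
#' @return A list with `origin` (length-3, the camera center, mm) and
#'   `direction` (Nx3 matrix of unit vectors in the rig frame).
#' @export
pixel_ray <- function(camera, pixel) {
  px <- as_points(pixel)
  if (!all(is.finite(px))) stop("pixel coordinates must be finite", call. = FALSE)
  xn <- (px[, 1] - camera$cx) / camera$fx
  yn <- (px[, 2] - camera$cy) / camera$fy
  d_cam <- cbind(xn, yn, 1)
  d_world <- d_cam %*% camera$R  # = t(R) %*% d per row
  d_world <- d_world / sqrt(rowSums(d_world^2))
  list(origin = camera_center(camera), direction = d_world)
}

#' The six ordered camera pairs of a rig
#'
#' @param n_cameras Number of cameras (default 4, giving six pairs).
#' @return Two-column integer matrix of ordered pairs (ci < cj).
#' @export
camera_pairs <- function(n_cameras = 4) {
  stopifnot(n_cameras >= 2)
  t(utils::combn(seq_len(n_cameras), 2))
}

#' Read and write rig calibration files
#'
#' The calibration file is JSON: a list of records
#' `{camera_id, fx, fy, cx, cy, dist:[k1,k2,p1,p2,k3], R (row-major 9),
#' t (3), units:"mm"}`.
#'
#' @param path File path.
#' @return `read_calibration()` returns a list of [camera_model()] objects.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    camera_model(r$camera_id, r$fx, r$fy, r$cx, r$cy,
                 dist = unlist(r$dist),
                 R = matrix(unlist(r$R), 3, 3, byrow = TRUE),
                 t = unlist(r$t))
  })
}

#' @param cameras List of [camera_model()] objects.
#' @rdname read_calibration
#' @export
write_calibration <- function(cameras, path) {
  recs <- lapply(cameras, function(cm) {
    list(camera_id = cm$camera_id, fx = cm$fx, fy = cm$fy,
         cx = cm$cx, cy = cm$cy, dist = cm$dist,
         R = as.numeric(t(cm$R)), t = cm$t, units = "mm")
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
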