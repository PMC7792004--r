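#' Estimate the fundamental matrix with the normalized eight-point algorithm
#'
#' For matching pixel points `x` (first view) and `x'` (second view) the
#' fundamental matrix satisfies `x'^T F x = 0`. Points are Hartley
#' normalized (centroid at the origin, mean distance sqrt(2)), the
#' least-squares solution is taken from the SVD of the design matrix, the
#' rank-2 constraint is enforced by zeroing the smallest singular value,
#' and the result is denormalized. F is scaled to unit Frobenius norm with
#' its largest-magnitude entry positive (first in column-major order on
#' ties) so the output is deterministic.
#'
#' @param points_i Nx2 pixel points in the first view (`x`).
#' @param points_j Nx2 pixel points in the second view (`x'`).
#' @param normalize Use Hartley normalization (default TRUE). The
#'   unnormalized variant exists for comparison experiments only.
#' @return A 3x3 matrix of class `fundamental_matrix`, rank 2, unit norm.
#' @examples
#' # two cameras displaced along x view a random cloud
#' cams <- make_rig(n_cameras = 2)
#' X <- cbind(runif(20, -20, 20), runif(20, -15, 15), runif(20, -2, 2))
#' F <- estimate_fundamental(project_points(cams[[1]], X),
#'                           project_points(cams[[2]], X))
#' @export
estimate_fundamental <- function(points_i, points_j, normalize = TRUE) {
  pi <- as_points(points_i); pj <- as_points(points_j)
  if (nrow(pi) != nrow(pj)) stop("point lists must have equal length", call. = FALSE)
  if (nrow(pi) < 8) stop("at least 8 correspondences are required", call. = FALSE)
  if (is_collinear(pi) || is_collinear(pj))
    stop("degenerate configuration: points are collinear", call. = FALSE)

  if (normalize) {
    Ti <- normalizing_transform(pi)
    Tj <- normalizing_transform(pj)
    pi_n <- apply_homography(Ti, pi)
    pj_n <- apply_homography(Tj, pj)
  } else {
    Ti <- Tj <- diag(3)
    pi_n <- pi; pj_n <- pj
  }

  x <- pi_n[, 1]; y <- pi_n[, 2]
  xp <- pj_n[, 1]; yp <- pj_n[, 2]
  A <- cbind(xp * x, xp * y, xp, yp * x, yp * y, yp, x, y, 1)
  sv <- svd(A, nu = 0, nv = 9)
  f <- sv$v[, 9]
  Fn <- matrix(f, 3, 3, byrow = TRUE)

  # rank-2 enforcement
  s <- svd(Fn)
  Fn <- s$u %*% diag(c(s$d[1], s$d[2], 0)) %*% t(s$v)

  Fm <- t(Tj) %*% Fn %*% Ti
  Fm <- normalize_fmatrix(Fm)
  class(Fm) <- c("fundamental_matrix", class(Fm))
  Fm
}

normalizing_transform <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums((p - matrix(ctr, nrow(p), 2, byrow = TRUE))^2))
  md <- mean(d)
  s <- if (md > 0) sqrt(2) / md else 1
  matrix(c(s, 0, 0,
           0, s, 0,
           -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

is_collinear <- function(p, tol = 1e-9) {
  if (nrow(p) < 3) return(TRUE)
  q <- scale(p, scale = FALSE)
  d <- svd(q, nu = 0, nv = 0)$d
  d[2] <= tol * max(d[1], 1)
}

normalize_fmatrix <- function(Fm) {
  Fm <- Fm / sqrt(sum(Fm^2))
  k <- which.max(abs(Fm))  # column-major position; first wins on ties
  if (Fm[k] < 0) Fm <- -Fm
  Fm
}

#' Fundamental matrix from two calibrated cameras
#'
#' Computes `F = K_j^{-T} [t]_x R K_i^{-1}` for the relative pose of the
#' ordered pair, useful as a calibrated reference and for epipole checks.
#'
#' @param cam_i,cam_j [camera_model()] objects.
#' @return 3x3 `fundamental_matrix` (unit norm, deterministic sign).
#' @export
fundamental_from_cameras <- function(cam_i, cam_j) {
  R_rel <- cam_j$R %*% t(cam_i$R)
  t_rel <- cam_j$t - as.numeric(R_rel %*% cam_i$t)
  E <- skew3(t_rel) %*% R_rel
  Ki <- intrinsic_matrix(cam_i); Kj <- intrinsic_matrix(cam_j)
  Fm <- t(solve(Kj)) %*% E %*% solve(Ki)
  Fm <- normalize_fmatrix(Fm)
  class(Fm) <- c("fundamental_matrix", class(Fm))
  Fm
}

#' Algebraic epipolar residuals |x'^T F x|
#'
#' @param F A 3x3 fundamental matrix.
#' @param points_i,points_j Matched Nx2 pixel points (`x`, `x'`).
#' @return Numeric vector of absolute residuals.
#' @export
epipolar_residuals <- function(F, points_i, points_j) {
  pi <- as_points(points_i); pj <- as_points(points_j)
  xi <- cbind(pi, 1); xj <- cbind(pj, 1)
  abs(rowSums((xj %*% F) * xi))
}

#' @export
print.fundamental_matrix <- function(x, ...) {
  cat("<fundamental_matrix> (unit Frobenius norm, rank 2)\n")
  print(unclass(x))
  invisible(x)
}
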