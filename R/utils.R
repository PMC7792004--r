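# Internal helpers shared across the pipeline.
#
# Image convention: a grayscale image is a numeric matrix `img[row, col]`
# with intensities in 0..255. Pixel coordinates are 0-based, x = column
# increasing rightward, y = row increasing downward, origin at the center
# of the top-left pixel, so pixel (x, y) lives at img[y + 1, x + 1].

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop("expected a nonempty numeric matrix image", call. = FALSE)
  invisible(img)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = length(p))
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  p
}

#' Bilinear sampling of an image at sub-pixel locations
#'
#' Coordinates are 0-based pixel-center coordinates. Samples outside the
#' image are given `fill`.
#' @noRd
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp corner indices; validity decided on the un-clamped coordinates
  valid <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  x0c <- clamp(x0, 0, w - 1); x1c <- clamp(x0 + 1, 0, w - 1)
  y0c <- clamp(y0, 0, h - 1); y1c <- clamp(y0 + 1, 0, h - 1)
  i00 <- img[cbind(y0c + 1, x0c + 1)]
  i01 <- img[cbind(y0c + 1, x1c + 1)]
  i10 <- img[cbind(y1c + 1, x0c + 1)]
  i11 <- img[cbind(y1c + 1, x1c + 1)]
  v <- (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
  v[!valid] <- fill
  v
}

#' Summed-area table with a zero top/left border.
#'
#' `ii[i + 1, j + 1]` is the sum of `img[1:i, 1:j]`; dimensions (h+1, w+1).
#' @noRd
integral_image <- function(img) {
  cs <- apply(img, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(img))
  cs2 <- t(apply(cs, 1, cumsum))
  if (is.null(dim(cs2))) cs2 <- matrix(cs2, ncol = ncol(img))
  rbind(0, cbind(0, cs2))
}

#' Exact integral of the piecewise-constant image over a real-valued box.
#'
#' Box edges are given in "corner" coordinates u in 0..w, v in 0..h
#' where pixel (x, y) covers u in (x, x+1), v in (y, y+1); i.e. u = x + 0.5
#' at a pixel center. The summed-area table is piecewise bilinear, so
#' bilinear interpolation at the four corners is exact. Boxes are clipped
#' to the image.
#' @noRd
box_integral <- function(ii, u1, v1, u2, v2) {
  h <- nrow(ii) - 1L; w <- ncol(ii) - 1L
  u1 <- clamp(u1, 0, w); u2 <- clamp(u2, 0, w)
  v1 <- clamp(v1, 0, h); v2 <- clamp(v2, 0, h)
  ii_at <- function(u, v) {
    u0 <- clamp(floor(u), 0, w - 1); v0 <- clamp(floor(v), 0, h - 1)
    fu <- u - u0; fv <- v - v0
    a <- ii[cbind(v0 + 1, u0 + 1)]; b <- ii[cbind(v0 + 1, u0 + 2)]
    cc <- ii[cbind(v0 + 2, u0 + 1)]; d <- ii[cbind(v0 + 2, u0 + 2)]
    (1 - fv) * ((1 - fu) * a + fu * b) + fv * ((1 - fu) * cc + fu * d)
  }
  ii_at(u2, v2) - ii_at(u1, v2) - ii_at(u2, v1) + ii_at(u1, v1)
}

#' Apply a 3x3 homography to 0-based pixel points (Nx2), returning Nx2.
#' @noRd
apply_homography <- function(H, pts) {
  pts <- as_points(pts)
  ph <- cbind(pts[, 1], pts[, 2], 1) %*% t(H)
  cbind(ph[, 1] / ph[, 3], ph[, 2] / ph[, 3])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Quantize a numeric image to 8-bit levels (stays a double matrix).
#' @noRd
quantize8 <- function(img) {
  m <- round(clamp(img, 0, 255))
  storage.mode(m) <- "double"
  m
}
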