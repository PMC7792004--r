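#' Contrast-Limited Adaptive Histogram Equalization (CLAHE)
#'
#' Local contrast enhancement applied to skin images before feature
#' detection: low-contrast pigment spots become separable from the
#' surrounding skin without amplifying noise the way plain histogram
#' equalization would.
#'
#' The image is divided into a `tiles[1] x tiles[2]` grid of near-equal
#' tiles. Per tile, an `n_bins` histogram is clipped at
#' `clip_limit * tile_pixel_count` and the clipped excess is redistributed
#' uniformly over all bins in a single pass; the clipped cumulative
#' distribution, scaled to the 0..255 range and rounded, is the tile's transfer
#' function. Each output pixel bilinearly blends the transfer functions of
#' the (up to) four surrounding tile centers, and the blend is rounded
#' back to an 8-bit level.
#'
#' @param image Grayscale image matrix with values in 0..255.
#' @param tiles `c(rows, cols)` tile grid; both must not exceed the image
#'   dimensions. Default `c(8, 8)`.
#' @param clip_limit Clip limit as a fraction of the per-tile histogram
#'   mass (> 0). Default 0.01.
#' @param n_bins Number of histogram bins (>= 2). Default 256.
#' @return The equalized image, same dimensions, values in 0..255.
#' @examples
#' img <- matrix(rep(seq(90, 110, length.out = 64), each = 64), 64, 64)
#' out <- clahe(img, tiles = c(2, 2))
#' range(out)
#' @export
clahe <- function(image, tiles = c(8, 8), clip_limit = 0.01, n_bins = 256) {
  stopifnot_image(image)
  tr <- as.integer(tiles[1]); tc <- as.integer(tiles[2])
  if (tr < 1 || tc < 1) stop("tiles must be >= (1,1)", call. = FALSE)
  if (clip_limit <= 0) stop("clip_limit must be positive", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  if (tr > h || tc > w) stop("tile grid larger than the image", call. = FALSE)

  v <- clamp(round(image), 0, 255)
  bin <- floor(v * n_bins / 256) + 1  # matrix of bin indices in 1..n_bins

  # balanced tile partition: 0-based row r belongs to tile floor(r*tr/h)+1
  row_tile <- floor((0:(h - 1)) * tr / h) + 1
  col_tile <- floor((0:(w - 1)) * tc / w) + 1

  # per-tile transfer functions, m[ti, tj, bin] in 0..255
  m <- array(0, dim = c(tr, tc, n_bins))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (ti in seq_len(tr)) {
    rows <- which(row_tile == ti)
    centers_r[ti] <- (min(rows) - 1 + max(rows) - 1) / 2
    for (tj in seq_len(tc)) {
      cols <- which(col_tile == tj)
      if (ti == 1) centers_c[tj] <- (min(cols) - 1 + max(cols) - 1) / 2
      hs <- tabulate(bin[rows, cols], nbins = n_bins)
      n_px <- length(rows) * length(cols)
      cl <- clip_limit * n_px
      excess <- sum(pmax(hs - cl, 0))
      hs <- pmin(hs, cl) + excess / n_bins
      cdf <- cumsum(hs) / sum(hs)
      m[ti, tj, ] <- round(cdf * 255)
    }
  }

  # bilinear blend between tile mappings, clamped at the border tiles
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  iy <- tile_interp(yy, centers_r)
  ix <- tile_interp(xx, centers_c)
  b <- as.vector(bin)
  val <-
    (1 - iy$f) * (1 - ix$f) * m[cbind(as.vector(iy$i0), as.vector(ix$i0), b)] +
    (1 - iy$f) * ix$f       * m[cbind(as.vector(iy$i0), as.vector(ix$i1), b)] +
    iy$f       * (1 - ix$f) * m[cbind(as.vector(iy$i1), as.vector(ix$i0), b)] +
    iy$f       * ix$f       * m[cbind(as.vector(iy$i1), as.vector(ix$i1), b)]
  matrix(round(val), h, w)
}

# For coordinates `pos` (matrix) and sorted tile centers, return the
# bracketing tile indices and the interpolation fraction (clamped).
tile_interp <- function(pos, centers) {
  n <- length(centers)
  p <- as.vector(pos)
  i0 <- findInterval(p, centers)
  i0 <- clamp(i0, 1, max(n - 1, 1))
  i1 <- pmin(i0 + 1, n)
  if (n == 1) {
    f <- rep(0, length(p))
  } else {
    f <- (p - centers[i0]) / (centers[i1] - centers[i0])
    f <- clamp(f, 0, 1)
    f[i1 == i0] <- 0
  }
  list(i0 = i0, i1 = i1, f = f)
}
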