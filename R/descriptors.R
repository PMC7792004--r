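#' Extract upright SURF-style 64-d descriptors
#'
#' For each feature a 20s x 20s window (s = feature scale) is sampled on a
#' 20 x 20 grid with spacing s. At every sample point Haar-wavelet
#' responses dx, dy of size 2s are computed exactly from the summed-area
#' table (the table is piecewise bilinear, so real-valued box sums are
#' exact) and weighted by a Gaussian (sigma = 3.3 s) centred on the
#' feature. The grid is grouped into 4 x 4 subregions of 5 x 5 samples;
#' each subregion contributes (sum dx, sum |dx|, sum dy, sum |dy|),
#' giving 64 values normalized to unit length.
#'
#' Descriptors are computed upright (no orientation assignment): the
#' matching stage operates on rectified image pairs whose rows are
#' epipolar scan lines, so in-plane rotation between views is already
#' removed and rotation invariance would only discard information.
#'
#' Features whose window exceeds the image border are dropped from both
#' the ensemble and the descriptor set, which stay aligned
#' index-for-index. A feature on a constant patch yields a zero raw
#' vector; it is kept as the zero vector and flagged unmatchable.
#'
#' @param image Grayscale image (the same image the features were
#'   detected on, normally a rectified view).
#' @param ensemble A `feature_ensemble` from [detect_mser()] or
#'   [detect_fast_hessian()].
#' @return An object of class `descriptor_set`: list with `vectors`
#'   (n x 64 matrix, unit rows or zero), `y_row` (the features' row
#'   coordinates), `x`, `unmatchable` (logical), `ensemble` (the filtered,
#'   aligned ensemble) and `camera_id`.
#' @export
extract_descriptors <- function(image, ensemble) {
  stopifnot_image(image)
  h <- nrow(image); w <- ncol(image)
  n <- nrow(ensemble)
  if (n == 0) {
    return(new_descriptor_set(matrix(0, 0, 64), numeric(0), numeric(0),
                              logical(0), ensemble))
  }
  margin <- 10.5 * ensemble$scale + 1
  keep <- ensemble$x - margin >= 0 & ensemble$x + margin <= w - 1 &
          ensemble$y - margin >= 0 & ensemble$y + margin <= h - 1
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("extract_descriptors: dropped %d border feature(s)", dropped))
  ens <- ensemble[keep, , drop = FALSE]
  regions <- attr(ensemble, "regions")
  if (!is.null(regions)) attr(ens, "regions") <- regions[keep]
  ens$index <- seq_len(nrow(ens))
  rownames(ens) <- NULL
  class(ens) <- c("feature_ensemble", "data.frame")
  m <- nrow(ens)
  if (m == 0) {
    return(new_descriptor_set(matrix(0, 0, 64), numeric(0), numeric(0),
                              logical(0), ens))
  }

  ii <- integral_image(image)
  ks <- (-10):9
  offs <- ks + 0.5                       # sample offsets in units of s
  grid <- expand.grid(ju = offs, jv = offs)  # ju = x offset, jv = y offset
  wgt <- exp(-(grid$ju^2 + grid$jv^2) / (2 * 3.3^2))
  sub_u <- floor((grid$ju + 10) / 5)     # subregion column 0..3
  sub_v <- floor((grid$jv + 10) / 5)
  sub_id <- sub_v * 4 + sub_u + 1        # 1..16, row-major over (v, u)

  vectors <- matrix(0, m, 64)
  for (i in seq_len(m)) {
    s <- ens$scale[i]
    # corner coordinates (pixel + 0.5) of sample centers
    u <- ens$x[i] + 0.5 + grid$ju * s
    v <- ens$y[i] + 0.5 + grid$jv * s
    dx <- box_integral(ii, u, v - s, u + s, v + s) -
          box_integral(ii, u - s, v - s, u, v + s)
    dy <- box_integral(ii, u - s, v, u + s, v + s) -
          box_integral(ii, u - s, v - s, u + s, v)
    dx <- dx * wgt; dy <- dy * wgt
    acc <- cbind(rowsum(dx, sub_id), rowsum(abs(dx), sub_id),
                 rowsum(dy, sub_id), rowsum(abs(dy), sub_id))
    vec <- as.numeric(t(acc))            # per subregion: dx,|dx|,dy,|dy|
    nv <- sqrt(sum(vec^2))
    if (nv > 0) vec <- vec / nv
    vectors[i, ] <- vec
  }
  unmatchable <- rowSums(vectors^2) < 0.5
  new_descriptor_set(vectors, ens$y, ens$x, unmatchable, ens)
}

new_descriptor_set <- function(vectors, y_row, x, unmatchable, ensemble) {
  structure(list(vectors = vectors, y_row = y_row, x = x,
                 unmatchable = unmatchable, ensemble = ensemble,
                 camera_id = if (nrow(ensemble)) ensemble$camera_id[1] else NA_integer_),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set> %d descriptor(s), %d unmatchable\n",
              nrow(x$vectors), sum(x$unmatchable)))
  invisible(x)
}

#' @export
length.descriptor_set <- function(x) nrow(x$vectors)
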