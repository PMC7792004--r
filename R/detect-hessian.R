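#' Detect blob features with the fast-Hessian (SURF-style) detector
#'
#' Builds a summed-area table and evaluates box-filter approximations of
#' the scale-normalized Hessian determinant over an octave/scale pyramid
#' (filter side lengths 9, 15, 21, 27 in the first octave, doubling lobe
#' steps per octave; all responses are computed at full pixel resolution).
#' Local maxima over 3x3x3 scale-space neighbourhoods above
#' `hessian_threshold` are kept and refined to sub-pixel/sub-scale
#' precision by a quadratic fit. Dark and bright blobs both produce
#' positive determinant responses and are both reported.
#'
#' The characteristic scale is `1.2 * L / 9` for interpolated filter side
#' L, i.e. the Gaussian sigma the filter approximates.
#'
#' @param image Grayscale image matrix, values in 0..255.
#' @param roi Optional `c(x, y, width, height)` region of interest.
#' @param hessian_threshold Minimum determinant response. The default
#'   (15) was tuned once on the bundled synthetic-scene fixture.
#' @param n_octaves,n_scales Pyramid extent. Defaults 2 octaves of 4
#'   filter sizes; only interior sizes can host a maximum.
#' @param camera_id Optional camera id stored with the features.
#' @return A `feature_ensemble` data frame (see [detect_mser()]) with
#'   `detector = "SURF"`; `response` is the interpolated determinant.
#' @export
detect_fast_hessian <- function(image, roi = NULL, hessian_threshold = 15,
                                n_octaves = 2, n_scales = 4,
                                camera_id = NA_integer_) {
  stopifnot_image(image)
  stopifnot(n_octaves >= 1, n_scales >= 3)
  cr <- crop_roi(image, roi)
  if (is.null(cr)) return(empty_ensemble(camera_id, "SURF"))
  sub <- cr$img
  h <- nrow(sub); w <- ncol(sub)
  ii <- integral_image(sub)

  out <- list()
  for (o in seq_len(n_octaves)) {
    lobes <- 2^o * seq_len(n_scales) + 1
    sizes <- 3 * lobes
    bmax <- (3 * max(lobes) - 1) / 2
    if (h < 2 * bmax + 3 || w < 2 * bmax + 3) next
    resp <- lapply(lobes, function(l) hessian_det_map(ii, l, h, w))
    for (s in 2:(n_scales - 1)) {
      cand <- which(!is.na(resp[[s]]) & resp[[s]] > hessian_threshold, arr.ind = TRUE)
      if (nrow(cand) == 0) next
      for (k in seq_len(nrow(cand))) {
        r <- as.integer(cand[k, 1]); cc <- as.integer(cand[k, 2])
        if (r < 2 || r > h - 1 || cc < 2 || cc > w - 1) next
        v <- resp[[s]][r, cc]
        nb <- c(resp[[s - 1]][(r - 1):(r + 1), (cc - 1):(cc + 1)],
                resp[[s]][(r - 1):(r + 1), (cc - 1):(cc + 1)],
                resp[[s + 1]][(r - 1):(r + 1), (cc - 1):(cc + 1)])
        if (any(is.na(nb))) next
        if (v < max(nb) || sum(nb == v) > 1) next
        ref <- refine_maximum(resp, s, r, cc)
        if (is.null(ref)) next
        L <- sizes[s] + ref$ds * 3 * 2^o
        out[[length(out) + 1]] <- c(x = cc - 1 + ref$dx + cr$off[1],
                                    y = r - 1 + ref$dy + cr$off[2],
                                    scale = 1.2 * L / 9,
                                    response = ref$value)
      }
    }
  }
  if (length(out) == 0) return(empty_ensemble(camera_id, "SURF"))
  m <- do.call(rbind, out)
  ens <- data.frame(camera_id = camera_id, index = 0L,
                    x = m[, "x"], y = m[, "y"], scale = m[, "scale"],
                    detector = "SURF", response = m[, "response"],
                    polarity = NA_character_, level = NA_integer_,
                    area = pi * m[, "scale"]^2, stringsAsFactors = FALSE)
  ens <- ens[order(ens$y, ens$x, ens$scale), , drop = FALSE]
  ens$index <- seq_len(nrow(ens))
  rownames(ens) <- NULL
  class(ens) <- c("feature_ensemble", "data.frame")
  ens
}

# Scale-normalized Hessian determinant response map for lobe size l
# (filter side L = 3l), NA within the invalid border.
hessian_det_map <- function(ii, l, h, w) {
  L <- 3 * l
  b <- (L - 1) / 2
  if (h <= 2 * b || w <= 2 * b) return(matrix(NA_real_, h, w))
  hw <- (l - 1) / 2  # half middle-box height

  # sum over rows (y+dr1)..(y+dr2), cols (x+dc1)..(x+dc2) for all centers
  boxm <- function(dr1, dc1, dr2, dc2) {
    rows <- (b + 1):(h - b)   # 1-based center rows
    cols <- (b + 1):(w - b)
    ii[rows + dr2 + 1, cols + dc2 + 1, drop = FALSE] -
      ii[rows + dr1, cols + dc2 + 1, drop = FALSE] -
      ii[rows + dr2 + 1, cols + dc1, drop = FALSE] +
      ii[rows + dr1, cols + dc1, drop = FALSE]
  }
  # Dyy: three stacked boxes (height l, width 2l-1), weights 1,-2,1
  dyy <- boxm(-hw - l, -(l - 1), -hw - 1, l - 1) +
         boxm(hw + 1, -(l - 1), hw + l, l - 1) -
         2 * boxm(-hw, -(l - 1), hw, l - 1)
  dxx <- boxm(-(l - 1), -hw - l, l - 1, -hw - 1) +
         boxm(-(l - 1), hw + 1, l - 1, hw + l) -
         2 * boxm(-hw, -hw, hw, hw)
  dxy <- boxm(-l, -l, -1, -1) + boxm(1, 1, l, l) -
         boxm(-l, 1, -1, l) - boxm(1, -l, l, -1)
  dyy <- dyy / L^2; dxx <- dxx / L^2; dxy <- dxy / L^2
  det <- dxx * dyy - (0.9 * dxy)^2
  full <- matrix(NA_real_, h, w)
  full[(b + 1):(h - b), (b + 1):(w - b)] <- det
  full
}

# Quadratic refinement of a 3x3x3 scale-space maximum; falls back to the
# unrefined grid point when the fit is degenerate or diverges by more
# than one sample step.
refine_maximum <- function(resp, s, r, cc) {
  f <- function(ds, dr, dc) resp[[s + ds]][r + dr, cc + dc]
  g <- c((f(0, 0, 1) - f(0, 0, -1)) / 2,
         (f(0, 1, 0) - f(0, -1, 0)) / 2,
         (f(1, 0, 0) - f(-1, 0, 0)) / 2)
  H <- matrix(0, 3, 3)
  v0 <- f(0, 0, 0)
  H[1, 1] <- f(0, 0, 1) - 2 * v0 + f(0, 0, -1)
  H[2, 2] <- f(0, 1, 0) - 2 * v0 + f(0, -1, 0)
  H[3, 3] <- f(1, 0, 0) - 2 * v0 + f(-1, 0, 0)
  H[1, 2] <- H[2, 1] <- (f(0, 1, 1) - f(0, 1, -1) - f(0, -1, 1) + f(0, -1, -1)) / 4
  H[1, 3] <- H[3, 1] <- (f(1, 0, 1) - f(1, 0, -1) - f(-1, 0, 1) + f(-1, 0, -1)) / 4
  H[2, 3] <- H[3, 2] <- (f(1, 1, 0) - f(1, -1, 0) - f(-1, 1, 0) + f(-1, -1, 0)) / 4
  off <- tryCatch(-solve(H, g), error = function(e) NULL)
  if (is.null(off) || any(!is.finite(off)) || max(abs(off)) > 1)
    return(list(dx = 0, dy = 0, ds = 0, value = v0))
  list(dx = off[1], dy = off[2], ds = off[3],
       value = v0 + 0.5 * sum(g * off))
}
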