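#' Segment bright optical markers by intensity thresholding
#'
#' Markers are bright circular adhesive patches, far brighter than skin;
#' simple binarization separates them. Components smaller than `min_area`
#' pixels (salt noise, specular glints) are removed.
#'
#' @param image Grayscale image matrix.
#' @param intensity_threshold Threshold level; pixels `>=` it enter the
#'   mask. `NULL` (default) selects the threshold by Otsu's method on the
#'   image histogram.
#' @param min_area Minimum component area in pixels. Default 5.
#' @return Logical mask matrix with attribute `"labels"` (integer
#'   component labels) and `"threshold"` (the level used).
#' @export
segment_markers <- function(image, intensity_threshold = NULL, min_area = 5) {
  stopifnot_image(image)
  v <- clamp(round(image), 0, 255)
  if (is.null(intensity_threshold)) intensity_threshold <- otsu_threshold(v)
  mask <- v >= intensity_threshold
  lab <- matrix(label_components_cpp(as.vector(mask), nrow(mask), ncol(mask)),
                nrow(mask), ncol(mask))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_area)
    if (length(small)) {
      mask[lab %in% small] <- FALSE
      lab[lab %in% small] <- 0L
      # relabel compactly, preserving scan order
      keep <- sort(unique(lab[lab > 0]))
      lab[lab > 0] <- match(lab[lab > 0], keep)
    }
  }
  attr(mask, "labels") <- lab
  attr(mask, "threshold") <- intensity_threshold
  mask
}

# Otsu's between-class-variance maximizing threshold on an 8-bit image.
# The histogram is restricted to intensities at or above the median:
# markers are by construction brighter than skin, and the dark-blob tail
# would otherwise dominate the between-class variance and split skin
# from moles instead of markers from skin.
otsu_threshold <- function(v) {
  v <- as.vector(v)
  v <- v[v >= stats::median(v)]
  if (length(unique(v)) < 2) return(256)  # nothing brighter than skin
  hs <- tabulate(v + 1, nbins = 256)
  p <- hs / sum(hs)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- -Inf
  which.max(sigma2)  # threshold level: mask is v >= this
}

#' Detect marker centers inside a segmentation mask
#'
#' Runs the chosen blob detector on the masked image and keeps, per
#' connected mask component, the highest-response feature whose center
#' falls inside it; components where the detector fires nothing fall back
#' to their intensity-weighted centroid, so every marker yields exactly
#' one detection.
#'
#' @param image Grayscale image matrix.
#' @param mask Mask from [segment_markers()].
#' @param method `"MSER"` (default) or `"SURF"`.
#' @return Data frame of marker detections: `marker_component`, `x`, `y`
#'   (the winning feature's sub-pixel center), `radius` (px), `cx`, `cy`
#'   (the component's intensity-weighted centroid, used for sub-pixel
#'   correspondence and triangulation), `method`.
#' @export
detect_markers <- function(image, mask, method = c("MSER", "SURF")) {
  method <- match.arg(method)
  lab <- attr(mask, "labels")
  if (is.null(lab))
    lab <- matrix(label_components_cpp(as.vector(mask), nrow(mask), ncol(mask)),
                  nrow(mask), ncol(mask))
  ncomp <- max(lab)
  if (ncomp == 0) {
    return(data.frame(marker_component = integer(0), x = numeric(0),
                      y = numeric(0), radius = numeric(0),
                      method = character(0), stringsAsFactors = FALSE))
  }
  masked <- matrix(0, nrow(image), ncol(image))
  masked[mask] <- image[mask]
  feats <- if (method == "MSER") {
    detect_mser(masked, polarity = "bright", min_area = 5, max_area = length(masked))
  } else {
    detect_fast_hessian(masked)
  }
  out <- lapply(seq_len(ncomp), function(k) {
    px <- which(lab == k, arr.ind = TRUE)  # rows: (row, col) 1-based
    r_eq <- sqrt(nrow(px) / pi)
    inside <- rep(FALSE, nrow(feats))
    if (nrow(feats)) {
      fx <- round(feats$x) + 1; fy <- round(feats$y) + 1
      okidx <- fx >= 1 & fx <= ncol(lab) & fy >= 1 & fy <= nrow(lab)
      inside[okidx] <- lab[cbind(fy[okidx], fx[okidx])] == k
    }
    ctr <- weighted_centroid(image, px)
    if (any(inside)) {
      f <- feats[inside, , drop = FALSE]
      f <- f[which.max(f$response), , drop = FALSE]
      data.frame(marker_component = k, x = f$x, y = f$y,
                 radius = f$scale, cx = ctr[1], cy = ctr[2],
                 method = method, stringsAsFactors = FALSE)
    } else {
      data.frame(marker_component = k, x = ctr[1], y = ctr[2],
                 radius = r_eq, cx = ctr[1], cy = ctr[2],
                 method = paste0(method, "/centroid"),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

weighted_centroid <- function(image, px) {
  wgt <- image[px]
  if (sum(wgt) <= 0) wgt <- rep(1, nrow(px))
  c(sum((px[, 2] - 1) * wgt) / sum(wgt),
    sum((px[, 1] - 1) * wgt) / sum(wgt))
}

#' Benchmark detected 3D markers against ground truth
#'
#' Assigns detections to ground-truth markers one-to-one by greedy
#' nearest-neighbour (ascending distance, capped at `max_assign_dist`)
#' and reports per-pair 3D Euclidean distances.
#'
#' @param detected_3d Nx3 matrix (mm) of triangulated marker positions.
#' @param gt_3d Mx3 matrix (mm) of ground-truth marker coordinates.
#' @param max_assign_dist Assignment cap in mm. Default 2.
#' @param triangulation_error Optional per-detection triangulation error
#'   carried into the report.
#' @return An object of class `marker_comparison`: data frame with
#'   `marker_id` (row in `gt_3d`), `det_id`, detected and ground-truth
#'   coordinates, `euclidean_distance` (mm) and `triangulation_error`;
#'   attributes `unassigned_detected` and `unassigned_gt`.
#' @export
compare_to_ground_truth <- function(detected_3d, gt_3d, max_assign_dist = 2,
                                    triangulation_error = NULL) {
  D <- as_points(detected_3d); G <- as_points(gt_3d)
  if (nrow(D) == 0 || nrow(G) == 0)
    stop("both marker lists must be nonempty", call. = FALSE)
  dist2 <- outer(rowSums(D^2), rowSums(G^2), "+") - 2 * D %*% t(G)
  dist <- sqrt(pmax(dist2, 0))
  pairs <- data.frame(det = rep(seq_len(nrow(D)), nrow(G)),
                      gt = rep(seq_len(nrow(G)), each = nrow(D)),
                      d = as.vector(dist))
  pairs <- pairs[pairs$d <= max_assign_dist, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pairs$det, pairs$gt), , drop = FALSE]
  used_d <- logical(nrow(D)); used_g <- logical(nrow(G))
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$det[k]; j <- pairs$gt[k]
    if (used_d[i] || used_g[j]) next
    used_d[i] <- TRUE; used_g[j] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      marker_id = j, det_id = i,
      x = D[i, 1], y = D[i, 2], z = D[i, 3],
      gt_x = G[j, 1], gt_y = G[j, 2], gt_z = G[j, 3],
      euclidean_distance = dist[i, j],
      triangulation_error = if (is.null(triangulation_error)) NA_real_
                            else triangulation_error[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker_id = integer(0), det_id = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               gt_x = numeric(0), gt_y = numeric(0), gt_z = numeric(0),
               euclidean_distance = numeric(0),
               triangulation_error = numeric(0))
  rownames(out) <- NULL
  attr(out, "unassigned_detected") <- which(!used_d)
  attr(out, "unassigned_gt") <- which(!used_g)
  class(out) <- c("marker_comparison", "data.frame")
  out
}

#' @export
print.marker_comparison <- function(x, ...) {
  cat(sprintf("<marker_comparison> %d assigned marker(s)\n", nrow(x)))
  if (nrow(x))
    cat(sprintf("  mean Euclidean distance: %.4f mm\n",
                mean(x$euclidean_distance)))
  un <- attr(x, "unassigned_gt")
  if (length(un)) cat("  unassigned ground-truth markers:",
                      paste(un, collapse = ", "), "\n")
  invisible(x)
}
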