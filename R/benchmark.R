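#' Localize bright optical markers and benchmark against ground truth
#'
#' The marker pipeline mirrors the skin-feature pipeline on the bright
#' circular markers: binarization-based segmentation, blob detection
#' restricted to the marker components, scan-line correspondence across
#' the selected camera pair (marker centers are mapped through the
#' rectification homographies; only point coordinates are warped, never
#' the images), midpoint triangulation, and one-to-one comparison with
#' the known 3D marker coordinates by Euclidean distance. Marker
#' triangulation errors are produced by the same [triangulate()] code
#' path as skin features, so the two statistics are directly comparable.
#'
#' @param images List of grayscale images indexed by camera id.
#' @param cameras List of [camera_model()]s.
#' @param gt_markers Ground truth: Nx3 matrix or data frame with columns
#'   `x`, `y`, `z` (mm), optionally `marker_id`.
#' @param method Detector for the marker blobs: `"MSER"` or `"SURF"`.
#' @param pair Camera pair to use; default selects the widest-vergence
#'   pair seeing the marker cloud center.
#' @param intensity_threshold Binarization level; NULL (default) uses
#'   Otsu's method (see [segment_markers()]).
#' @param min_area Minimum marker component area, px.
#' @param band Scan-line tolerance for marker correspondence, rows.
#' @param max_assign_dist Ground-truth assignment cap, mm.
#' @return An object of class `marker_benchmark`: list with `comparison`
#'   (a `marker_comparison`), `stats` (Table-style rows for the
#'   triangulation error and the Euclidean distance), `detections`,
#'   `pair` and `method`.
#' @export
benchmark_markers <- function(images, cameras, gt_markers, method = "MSER",
                              pair = NULL, intensity_threshold = NULL,
                              min_area = 5, band = 2, max_assign_dist = 2) {
  gt <- if (is.data.frame(gt_markers)) as.matrix(gt_markers[, c("x", "y", "z")])
        else as_points(gt_markers)
  if (nrow(gt) == 0) stop("gt_markers must be nonempty", call. = FALSE)
  img_size <- c(ncol(images[[1]]), nrow(images[[1]]))
  if (is.null(pair))
    pair <- select_pair(cameras, colMeans(gt), image_size = img_size)
  cams2 <- cameras[pair]

  det <- lapply(1:2, function(k) {
    und <- correct_intrinsics(images[[pair[k]]], cams2[[k]])
    mask <- segment_markers(und, intensity_threshold = intensity_threshold,
                            min_area = min_area)
    detect_markers(und, mask, method = method)
  })
  if (nrow(det[[1]]) == 0 || nrow(det[[2]]) == 0)
    stop("no markers detected in one of the views", call. = FALSE)

  # correspond by rectified scan-line rows (refined component centroids)
  Hs <- rectify_homographies_calibrated(cams2[[1]], cams2[[2]])
  rows_k <- lapply(1:2, function(k)
    apply_homography(Hs[[k]], cbind(det[[k]]$cx, det[[k]]$cy))[, 2])
  cand <- expand.grid(i = seq_len(nrow(det[[1]])), j = seq_len(nrow(det[[2]])))
  cand$drow <- abs(rows_k[[1]][cand$i] - rows_k[[2]][cand$j])
  cand <- cand[cand$drow <= band, , drop = FALSE]
  cand <- cand[order(cand$drow, cand$i, cand$j), , drop = FALSE]
  used_i <- logical(nrow(det[[1]])); used_j <- logical(nrow(det[[2]]))
  mi <- mj <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    mi <- c(mi, i); mj <- c(mj, j)
  }
  if (length(mi) == 0) stop("no marker correspondences within the scan-line band",
                            call. = FALSE)

  rays_i <- pixel_ray(cams2[[1]], cbind(det[[1]]$cx[mi], det[[1]]$cy[mi]))
  rays_j <- pixel_ray(cams2[[2]], cbind(det[[2]]$cx[mj], det[[2]]$cy[mj]))
  tri <- lapply(seq_along(mi), function(k)
    triangulate(list(origin = rays_i$origin, direction = rays_i$direction[k, ]),
                list(origin = rays_j$origin, direction = rays_j$direction[k, ])))
  det3 <- do.call(rbind, lapply(tri, function(t) t$point))
  errs <- vapply(tri, function(t) t$e, numeric(1))

  cmp <- compare_to_ground_truth(det3, gt, max_assign_dist = max_assign_dist,
                                 triangulation_error = errs)
  stats <- rbind(
    triangulation_error = marker_summary_stats(cmp$triangulation_error),
    euclidean_distance = marker_summary_stats(cmp$euclidean_distance))
  structure(list(comparison = cmp, stats = stats, detections = det,
                 pair = pair, method = method,
                 n_markers = nrow(cmp)),
            class = "marker_benchmark")
}

marker_summary_stats <- function(v) {
  v <- v[is.finite(v)]
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(v), mean = mean(v),
             sd = if (length(v) > 1) stats::sd(v) else 0,
             rms = sqrt(mean(v^2)), min = min(v),
             q1 = qs[1], median = qs[2], q3 = qs[3], max = max(v))
}

#' @export
print.marker_benchmark <- function(x, ...) {
  cat(sprintf("<marker_benchmark> %s, pair %d|%d, %d marker(s) assigned\n",
              x$method, x$pair[1], x$pair[2], x$n_markers))
  print(round(x$stats, 4))
  invisible(x)
}
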