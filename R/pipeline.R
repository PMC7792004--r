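#' Default pipeline configuration
#'
#' Collects every tunable of the localization pipeline with its default.
#' Values can be overridden by the matching arguments, or loaded from a
#' YAML file with [read_pipeline_config()].
#'
#' @param ... Named overrides of the top-level groups (`clahe`, `mser`,
#'   `surf`, `match`, `plane`, `refine`), each a named list merged over
#'   the defaults, plus scalars `seed` and `roi_center`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    clahe = list(enabled = TRUE, tiles = c(8, 8), clip_limit = 0.01, n_bins = 256),
    mser = list(delta = 2, min_area = 10, max_area = NULL, max_variation = 0.25),
    surf = list(hessian_threshold = 15, n_octaves = 2, n_scales = 4),
    match = list(band = 2, disparity_range = c(-Inf, Inf), ssd_max = 1,
                 ratio = 0.8, mutual = TRUE),
    plane = list(threshold = 1, iterations = 1000, use_axis_prior = TRUE,
                 axis_max_angle = 60),
    refine = list(enabled = TRUE, radius_factor = 2.5, iterations = 3),
    roi_center = c(0, 0, 0),
    seed = 1L
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(cfg[[nm]]) && is.list(ov[[nm]])) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else {
      cfg[[nm]] <- ov[[nm]]
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full multi-view skin-feature localization pipeline
#'
#' Orchestrates the stages end-to-end for each analyzed region:
#' undistort, CLAHE contrast enhancement, calibrated epipolar
#' rectification of the selected camera pair, blob detection (MSER and/or
#' fast-Hessian) inside the region, descriptor extraction, scan-line SSD
#' matching, optional sub-pixel recentring of matched blobs on the
#' original undistorted images, midpoint triangulation, MSAC plane-based
#' outlier removal, Delaunay area estimation and descriptive statistics.
#'
#' @param images List of grayscale images, indexed by camera id.
#' @param cameras List of [camera_model()]s (same indexing).
#' @param regions List of regions; each region is a list with optional
#'   `region_id`, `rois` (data frame `camera_id, x, y, w, h`, 0-based)
#'   and `center` (3D world point for pair selection). NULL (default)
#'   analyzes one region covering the full frames.
#' @param detector `"MSER"`, `"SURF"` or `"both"`.
#' @param config A [pipeline_config()].
#' @return An object of class `localization_report`; see
#'   [compute_region_stats()] for the per-region statistics schema.
#' @export
run_localization <- function(images, cameras, regions = NULL,
                             detector = c("MSER", "SURF", "both"),
                             config = pipeline_config()) {
  detector <- match.arg(detector)
  detectors <- if (detector == "both") c("MSER", "SURF") else detector
  ncam <- length(cameras)
  stopifnot(length(images) == ncam)
  img_size <- c(ncol(images[[1]]), nrow(images[[1]]))
  if (is.null(regions)) {
    regions <- list(list(region_id = 1,
                         rois = data.frame(camera_id = seq_len(ncam), x = 0, y = 0,
                                           w = img_size[1], h = img_size[2]),
                         center = config$roi_center))
  }

  und <- lapply(seq_len(ncam), function(i) correct_intrinsics(images[[i]], cameras[[i]]))
  enh <- if (isTRUE(config$clahe$enabled)) {
    lapply(und, clahe, tiles = config$clahe$tiles,
           clip_limit = config$clahe$clip_limit, n_bins = config$clahe$n_bins)
  } else und

  region_results <- list()
  for (ri in seq_along(regions)) {
    reg <- regions[[ri]]
    reg_id <- reg$region_id %||% ri
    center <- reg$center %||% config$roi_center
    rois <- reg$rois
    vis_cams <- if (is.null(rois)) seq_len(ncam) else unique(rois$camera_id)
    visible <- seq_len(ncam) %in% vis_cams
    pair <- select_pair(cameras, center, visible = visible & frustum_visible(
      cameras, center, img_size), image_size = img_size)
    cams2 <- cameras[pair]
    rect <- rectify_pair(enh[[pair[1]]], enh[[pair[2]]], cameras = cams2)

    for (det in detectors) {
      res <- localize_region(rect, und, cams2, pair, rois, det, config)
      res$region_id <- reg_id
      res$detector <- det
      region_results[[length(region_results) + 1]] <- res
    }
  }

  report <- list(regions = region_results,
                 totals = aggregate_totals(region_results),
                 detectors = detectors,
                 config = config,
                 n_cameras = ncam,
                 version = as.character(utils::packageVersion("dermatrack")))
  class(report) <- "localization_report"
  report
}

frustum_visible <- function(cameras, center, img_size) {
  vapply(cameras, function(cm) {
    Xc <- cm$R %*% as.numeric(center) + cm$t
    if (Xc[3] <= 0) return(FALSE)
    px <- project_points(cm, center)
    px[1] >= 0 & px[1] <= img_size[1] - 1 & px[2] >= 0 & px[2] <= img_size[2] - 1
  }, logical(1))
}

# One region x detector pass over an already-rectified pair.
localize_region <- function(rect, und, cams2, pair, rois, det, config) {
  roi_rect <- lapply(1:2, function(k) {
    if (is.null(rois)) return(NULL)
    rr <- rois[rois$camera_id == pair[k], , drop = FALSE]
    if (nrow(rr) == 0) return(NULL)
    map_roi(rect$H[[k]], rr[1, ], rect$size[[k]])
  })
  ens <- lapply(1:2, function(k) {
    img <- rect$images[[k]]
    e <- if (det == "MSER") {
      detect_mser(img, roi = roi_rect[[k]], delta = config$mser$delta,
                  min_area = config$mser$min_area, max_area = config$mser$max_area,
                  max_variation = config$mser$max_variation, camera_id = pair[k])
    } else {
      detect_fast_hessian(img, roi = roi_rect[[k]],
                          hessian_threshold = config$surf$hessian_threshold,
                          n_octaves = config$surf$n_octaves,
                          n_scales = config$surf$n_scales, camera_id = pair[k])
    }
    # the rectified ROI is only a bounding box of the warped region;
    # enforce exact membership on the de-rectified feature centers
    if (!is.null(rois) && nrow(e) > 0) {
      rr <- rois[rois$camera_id == pair[k], , drop = FALSE]
      if (nrow(rr) > 0) {
        orig <- apply_homography(solve(rect$H[[k]]), cbind(e$x, e$y))
        keep <- orig[, 1] >= rr$x[1] - 0.5 &
                orig[, 1] <= rr$x[1] + rr$w[1] - 0.5 &
                orig[, 2] >= rr$y[1] - 0.5 &
                orig[, 2] <= rr$y[1] + rr$h[1] - 0.5
        e <- e[keep, , drop = FALSE]
        e$index <- seq_len(nrow(e))
        rownames(e) <- NULL
        class(e) <- c("feature_ensemble", "data.frame")
      }
    }
    e
  })
  des <- lapply(1:2, function(k)
    suppressMessages(extract_descriptors(rect$images[[k]], ens[[k]])))
  ms <- match_scanline_ssd(des[[1]], des[[2]], band = config$match$band,
                           disparity_range = config$match$disparity_range,
                           ssd_max = config$match$ssd_max,
                           ratio = config$match$ratio,
                           mutual = config$match$mutual)
  empty <- list(n_detected = c(nrow(ens[[1]]), nrow(ens[[2]])),
                n_matched = nrow(ms), pair = pair,
                tri = empty_triangulation_set(pair), inliers = NULL,
                plane = NULL, area = NULL, stats = NULL)
  if (nrow(ms) == 0) return(empty)

  pts <- lapply(1:2, function(k) {
    idx <- if (k == 1) ms$index_i else ms$index_j
    d <- des[[k]]
    p_rect <- cbind(d$x[idx], d$y_row[idx])
    p_orig <- derectify_points(rect, p_rect, k)
    if (isTRUE(config$refine$enabled)) {
      refine_centers(und[[pair[k]]], p_orig, d$ensemble$scale[idx],
                     polarity = d$ensemble$polarity[idx],
                     radius_factor = config$refine$radius_factor,
                     iterations = config$refine$iterations)
    } else p_orig
  })

  tri <- triangulate_matches(ms, cams2, rect = NULL,
                             points_i = pts[[1]], points_j = pts[[2]])
  ok3 <- nrow(tri) >= 3 && !is_collinear3d(as.matrix(tri[, c("x", "y", "z")]))
  if (!ok3) {
    empty$tri <- tri
    return(empty)
  }
  axis <- if (isTRUE(config$plane$use_axis_prior))
    unit(cams2[[1]]$R[3, ] + cams2[[2]]$R[3, ]) else NULL
  plane <- msac_plane_fit(as.matrix(tri[, c("x", "y", "z")]),
                          threshold = config$plane$threshold,
                          iterations = config$plane$iterations,
                          seed = config$seed, axis = axis,
                          axis_max_angle = config$plane$axis_max_angle)
  filt <- filter_outliers(tri, plane)
  area <- if (nrow(filt$inliers) >= 3 &&
              !is_collinear3d(as.matrix(filt$inliers[, c("x", "y", "z")])))
    estimate_area(filt$inliers, plane) else NULL
  stats <- compute_region_stats(filt$inliers$e,
                                area_cm2 = if (is.null(area)) NA_real_ else area$area_cm2,
                                matched_count = nrow(tri))
  list(n_detected = c(nrow(ens[[1]]), nrow(ens[[2]])), n_matched = nrow(ms),
       pair = pair, tri = tri, inliers = filt$inliers,
       outliers = filt$outliers, plane = plane, area = area, stats = stats)
}

# Transform an ROI box into the rectified frame (bounding box of the
# warped corners, clipped to the rectified image).
map_roi <- function(H, roi, size) {
  corners <- cbind(c(roi$x, roi$x + roi$w - 1, roi$x, roi$x + roi$w - 1),
                   c(roi$y, roi$y, roi$y + roi$h - 1, roi$y + roi$h - 1))
  wc <- apply_homography(H, corners)
  x0 <- max(0, floor(min(wc[, 1]))); y0 <- max(0, floor(min(wc[, 2])))
  x1 <- min(size[1] - 1, ceiling(max(wc[, 1])))
  y1 <- min(size[2] - 1, ceiling(max(wc[, 2])))
  c(x = x0, y = y0, w = x1 - x0 + 1, h = y1 - y0 + 1)
}

#' Sub-pixel refinement of blob centers by intensity-weighted centroid
#'
#' Detected blob centers inherit pixel-grid quantization and resampling
#' bias from the rectified detection images. This recentring step
#' computes, on the original (undistorted, non-equalized) image, the
#' centroid of the background-subtracted intensity inside a window of
#' `radius_factor * scale` pixels, iterating a few times so the window
#' tracks the center. Dark blobs weight `max(0, bg - I)`, bright ones
#' `max(0, I - bg)`, with `bg` the median of the window border ring.
#'
#' @param image Grayscale image (original resolution).
#' @param pts Nx2 initial centers, 0-based pixels.
#' @param scale Per-feature characteristic radius, pixels.
#' @param polarity Per-feature `"dark"`/`"bright"` (NA treated as dark).
#' @param radius_factor Window radius in units of scale. Default 2.5.
#' @param iterations Recentring iterations. Default 3.
#' @return Nx2 matrix of refined centers.
#' @export
refine_centers <- function(image, pts, scale, polarity = NULL,
                           radius_factor = 2.5, iterations = 3) {
  pts <- as_points(pts)
  n <- nrow(pts)
  if (length(scale) == 1) scale <- rep(scale, n)
  if (is.null(polarity)) polarity <- rep("dark", n)
  polarity[is.na(polarity)] <- "dark"
  h <- nrow(image); w <- ncol(image)
  out <- pts
  for (i in seq_len(n)) {
    rad <- max(3, radius_factor * scale[i])
    ctr <- pts[i, ]
    for (it in seq_len(iterations)) {
      x0 <- max(0, floor(ctr[1] - rad)); x1 <- min(w - 1, ceiling(ctr[1] + rad))
      y0 <- max(0, floor(ctr[2] - rad)); y1 <- min(h - 1, ceiling(ctr[2] + rad))
      if (x1 - x0 < 2 || y1 - y0 < 2) break
      win <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
      yy <- matrix(y0:y1, nrow(win), ncol(win))
      xx <- matrix(x0:x1, nrow(win), ncol(win), byrow = TRUE)
      # local background as an affine plane fitted to the window border:
      # robust to lateral illumination gradients, which would otherwise
      # bias the centroid toward the brighter side
      ring <- cbind(1, c(xx[1, ], xx[nrow(win), ], xx[, 1], xx[, ncol(win)]),
                    c(yy[1, ], yy[nrow(win), ], yy[, 1], yy[, ncol(win)]))
      ringv <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
      cf <- tryCatch({
        c0 <- qr.solve(ring, ringv)
        res <- ringv - ring %*% c0
        keep <- abs(res) <= 3 * stats::mad(res) + 1e-9  # drop ring pixels
        if (sum(keep) >= 6) qr.solve(ring[keep, , drop = FALSE], ringv[keep]) else c0
      }, error = function(e) c(stats::median(ringv), 0, 0))
      bg <- cf[1] + cf[2] * xx + cf[3] * yy
      wgt <- if (polarity[i] == "bright") pmax(0, win - bg) else pmax(0, bg - win)
      # restrict to the circular window
      wgt[(xx - ctr[1])^2 + (yy - ctr[2])^2 > rad^2] <- 0
      sw <- sum(wgt)
      if (sw <= 0) break
      ctr <- c(sum(xx * wgt) / sw, sum(yy * wgt) / sw)
    }
    out[i, ] <- ctr
  }
  out
}

#' Descriptive statistics for one analyzed region
#'
#' The per-region summary schema used in the run report: feature count,
#' analyzed area, feature density, the distribution of the triangulation
#' error (mean, sample standard deviation, RMS, min, quartiles by linear
#' interpolation of order statistics, max) and the discard ratio
#' (matched features per surviving inlier).
#'
#' @param errors Numeric vector of triangulation errors, mm (nonempty).
#' @param area_cm2 Analyzed area in cm^2.
#' @param matched_count Number of matched features before outlier
#'   removal.
#' @return A one-row data frame with columns `n_features`, `area_cm2`,
#'   `features_per_cm2`, `mean`, `sd`, `rms`, `min`, `q1`, `median`,
#'   `q3`, `max`, `discard_ratio`.
#' @examples
#' compute_region_stats(c(0.1, 0.1, 0.1), area_cm2 = 2, matched_count = 6)
#' @export
compute_region_stats <- function(errors, area_cm2, matched_count) {
  e <- as.numeric(errors)
  if (length(e) == 0) stop("errors must be nonempty", call. = FALSE)
  qs <- stats::quantile(e, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    n_features = length(e),
    area_cm2 = area_cm2,
    features_per_cm2 = length(e) / area_cm2,
    mean = mean(e),
    sd = if (length(e) > 1) stats::sd(e) else 0,
    rms = sqrt(mean(e^2)),
    min = min(e), q1 = qs[1], median = qs[2], q3 = qs[3], max = max(e),
    discard_ratio = matched_count / length(e))
}

aggregate_totals <- function(region_results) {
  dets <- unique(vapply(region_results, function(r) r$detector, character(1)))
  out <- list()
  for (det in dets) {
    rs <- Filter(function(r) identical(r$detector, det) && !is.null(r$stats),
                 region_results)
    if (length(rs) == 0) next
    pooled <- unlist(lapply(rs, function(r) r$inliers$e))
    area <- sum(vapply(rs, function(r) r$stats$area_cm2, numeric(1)))
    matched <- sum(vapply(rs, function(r) r$n_matched, numeric(1)))
    out[[det]] <- compute_region_stats(pooled, area_cm2 = area,
                                       matched_count = matched)
  }
  out
}

#' @export
print.localization_report <- function(x, ...) {
  cat("<localization_report>\n")
  for (r in x$regions) {
    cat(sprintf("  region %s / %s: pair %d|%d, detected %d+%d, matched %d",
                as.character(r$region_id), r$detector, r$pair[1], r$pair[2],
                r$n_detected[1], r$n_detected[2], r$n_matched))
    if (!is.null(r$stats)) {
      cat(sprintf(", inliers %d, mean e %.4f mm, area %.2f cm^2",
                  r$stats$n_features, r$stats$mean, r$stats$area_cm2))
    }
    cat("\n")
  }
  for (det in names(x$totals)) {
    s <- x$totals[[det]]
    cat(sprintf("  TOT %s: n %d, mean %.4f, sd %.4f, rms %.4f mm, %.1f features/cm^2, discard %.2f\n",
                det, s$n_features, s$mean, s$sd, s$rms, s$features_per_cm2,
                s$discard_ratio))
  }
  invisible(x)
}

#' @export
summary.localization_report <- function(object, ...) {
  rows <- lapply(object$regions, function(r) {
    if (is.null(r$stats)) return(NULL)
    cbind(data.frame(region_id = r$region_id, detector = r$detector,
                     pair = paste(r$pair, collapse = "|"),
                     matched = r$n_matched), r$stats)
  })
  do.call(rbind, rows)
}
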