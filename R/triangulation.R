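#' Triangulate two viewing rays by the midpoint of the common perpendicular
#'
#' Back-projected rays of a matched feature rarely intersect exactly. The
#' triangulated point is defined as the midpoint of the shortest segment
#' connecting the two rays, and the segment length is the triangulation
#' error `e` in millimetres — the per-feature localization quality metric
#' used throughout the package.
#'
#' @param ray_i,ray_j Rays as returned by [pixel_ray()]: lists with
#'   `origin` (length 3) and `direction` (1x3 or length 3, unit norm).
#' @return A list with `point` (length-3, mm), `e` (mm, >= 0) and
#'   `cheirality` (TRUE when both closest points lie in front of their
#'   ray origins; a FALSE value flags a behind-camera solution).
#' @examples
#' r1 <- list(origin = c(0, 0, 0), direction = c(1, 0, 0))
#' r2 <- list(origin = c(0, 0, 1), direction = c(0, 1, 0))
#' triangulate(r1, r2)  # point (0, 0, 0.5), e = 1
#' @export
triangulate <- function(ray_i, ray_j) {
  o1 <- as.numeric(ray_i$origin); d1 <- unit(as.numeric(ray_i$direction))
  o2 <- as.numeric(ray_j$origin); d2 <- unit(as.numeric(ray_j$direction))
  cr <- cross3(d1, d2)
  sin2 <- sum(cr^2)
  if (sqrt(sin2) < 1e-8)
    stop("degenerate geometry: rays are parallel", call. = FALSE)
  # closest points o1 + s d1 and o2 + t d2
  w0 <- o1 - o2
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w0); e0 <- sum(d2 * w0)
  den <- a * cc - b * b
  s <- (b * e0 - cc * d) / den
  t <- (a * e0 - b * d) / den
  p1 <- o1 + s * d1
  p2 <- o2 + t * d2
  list(point = (p1 + p2) / 2,
       e = sqrt(sum((p1 - p2)^2)),
       cheirality = (s > 0 && t > 0))
}

#' Triangulate a match set into a 3D feature cloud
#'
#' Maps each match's rectified pixel coordinates back through the inverse
#' rectification homographies, casts metric rays from both cameras and
#' triangulates with [triangulate()]. Ordering follows the match set.
#'
#' @param match_set A `match_set` from [match_scanline_ssd()].
#' @param cameras List of the two [camera_model()]s of the pair.
#' @param rect The `rectified_pair` the matches were found on, or NULL if
#'   the match coordinates are already in (undistorted) camera pixels.
#' @param points_i,points_j Optional Nx2 matched pixel coordinates
#'   overriding those implied by the match set (e.g. after sub-pixel
#'   refinement); rectified coordinates unless `rect` is NULL.
#' @return An object of class `triangulation_set`: data frame with
#'   columns `index`, `x`, `y`, `z`, `e` (mm) and `cheirality`; attribute
#'   `pair`.
#' @export
triangulate_matches <- function(match_set, cameras, rect = NULL,
                                points_i = NULL, points_j = NULL) {
  stopifnot(length(cameras) == 2)
  n <- nrow(match_set)
  pair <- attr(match_set, "pair")
  if (is.null(pair) || any(is.na(pair)))
    pair <- c(cameras[[1]]$camera_id, cameras[[2]]$camera_id)
  if (n == 0) return(empty_triangulation_set(pair))
  if (is.null(points_i)) {
    set_i <- attr(match_set, "set_i"); set_j <- attr(match_set, "set_j")
    if (is.null(set_i))
      stop("supply points_i/points_j or a match_set carrying its descriptor sets",
           call. = FALSE)
    points_i <- cbind(set_i$x[match_set$index_i], set_i$y_row[match_set$index_i])
    points_j <- cbind(set_j$x[match_set$index_j], set_j$y_row[match_set$index_j])
  }
  points_i <- as_points(points_i); points_j <- as_points(points_j)
  if (!is.null(rect)) {
    points_i <- derectify_points(rect, points_i, 1)
    points_j <- derectify_points(rect, points_j, 2)
  }
  rays_i <- pixel_ray(cameras[[1]], points_i)
  rays_j <- pixel_ray(cameras[[2]], points_j)
  out <- data.frame(index = seq_len(n), x = NA_real_, y = NA_real_,
                    z = NA_real_, e = NA_real_, cheirality = NA)
  for (k in seq_len(n)) {
    tri <- tryCatch(
      triangulate(list(origin = rays_i$origin, direction = rays_i$direction[k, ]),
                  list(origin = rays_j$origin, direction = rays_j$direction[k, ])),
      error = function(err) NULL)
    if (is.null(tri)) next  # parallel-ray degeneracy flagged as NA row
    out$x[k] <- tri$point[1]; out$y[k] <- tri$point[2]; out$z[k] <- tri$point[3]
    out$e[k] <- tri$e; out$cheirality[k] <- tri$cheirality
  }
  attr(out, "pair") <- pair
  class(out) <- c("triangulation_set", "data.frame")
  out
}

empty_triangulation_set <- function(pair = c(NA, NA)) {
  out <- data.frame(index = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), e = numeric(0), cheirality = logical(0))
  attr(out, "pair") <- pair
  class(out) <- c("triangulation_set", "data.frame")
  out
}

#' @export
print.triangulation_set <- function(x, ...) {
  pair <- attr(x, "pair")
  cat(sprintf("<triangulation_set> %d feature(s)%s\n", nrow(x),
              if (!is.null(pair) && !any(is.na(pair)))
                sprintf(", pair %d|%d", pair[1], pair[2]) else ""))
  if (nrow(x))
    cat(sprintf("  mean triangulation error: %.4f mm\n", mean(x$e, na.rm = TRUE)))
  invisible(x)
}

#' Mean triangulation error of a feature cloud
#'
#' The overall localization-quality summary: the arithmetic mean of the
#' per-feature triangulation errors, in millimetres.
#'
#' @param set A `triangulation_set`, or a numeric vector of errors.
#' @return Mean error in mm.
#' @export
mean_triangulation_error <- function(set) {
  e <- if (is.data.frame(set)) set$e else as.numeric(set)
  if (length(e) == 0) stop("empty triangulation set", call. = FALSE)
  mean(e)
}

#' Select the most favourable camera pair for a region
#'
#' Among the admissible camera pairs, keeps those that see the region in
#' both views and returns the one with the widest vergence angle at the
#' region center (a wide baseline angle conditions the triangulation
#' best). Deterministic: ties resolve to the first pair in canonical
#' order.
#'
#' @param cameras List of [camera_model()]s.
#' @param roi_center Length-3 world point (mm) the region sits at.
#' @param visible Optional logical vector, per camera, marking cameras
#'   whose view of the region is unoccluded; by default visibility is the
#'   frustum test of `roi_center` (projection inside `image_size`).
#' @param image_size `c(width, height)` in pixels for the frustum test.
#' @param pairs Candidate pairs (two-column matrix); default all pairs.
#' @return Integer vector `c(ci, cj)` of class `camera_pair` with
#'   attribute `angle` (degrees).
#' @export
select_pair <- function(cameras, roi_center, visible = NULL,
                        image_size = NULL, pairs = NULL) {
  ncam <- length(cameras)
  if (is.null(pairs)) pairs <- camera_pairs(ncam)
  if (is.null(visible)) {
    if (is.null(image_size))
      stop("supply image_size for the frustum test or an explicit visibility vector",
           call. = FALSE)
    visible <- vapply(cameras, function(cm) {
      px <- tryCatch(suppressWarnings(project_points(cm, roi_center)),
                     error = function(e) matrix(NA, 1, 2))
      Xc <- cm$R %*% as.numeric(roi_center) + cm$t
      all(is.finite(px)) && Xc[3] > 0 &&
        px[1, 1] >= 0 && px[1, 1] <= image_size[1] - 1 &&
        px[1, 2] >= 0 && px[1, 2] <= image_size[2] - 1
    }, logical(1))
  }
  ok <- visible[pairs[, 1]] & visible[pairs[, 2]]
  if (!any(ok)) stop("no camera pair sees the region", call. = FALSE)
  pairs <- pairs[ok, , drop = FALSE]
  ang <- apply(pairs, 1, function(p) {
    v1 <- unit(camera_center(cameras[[p[1]]]) - as.numeric(roi_center))
    v2 <- unit(camera_center(cameras[[p[2]]]) - as.numeric(roi_center))
    acos(clamp(sum(v1 * v2), -1, 1)) * 180 / pi
  })
  best <- which.max(ang)
  structure(as.integer(pairs[best, ]), angle = ang[best], class = "camera_pair")
}
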