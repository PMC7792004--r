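#' Robust plane fit to a 3D point cloud with MSAC
#'
#' The skin surface under an analyzed region is approximated by a single
#' plane; triangulated features far from it are gross mismatches and are
#' discarded. MSAC scores each 3-point hypothesis by the sum of truncated
#' squared residuals `sum(min(r^2, threshold^2))` — unlike plain RANSAC
#' the score rewards tight inliers, not just their count. When the number
#' of distinct point triples does not exceed `iterations` every triple is
#' evaluated (deterministic, and at least as good as sampling); otherwise
#' `iterations` random triples are drawn from the seeded RNG. The best
#' hypothesis is refit by total least squares on its inliers and the
#' inlier mask is recomputed from the refit plane.
#'
#' An optional orientation prior restricts hypotheses to normals within
#' `axis_max_angle` degrees of a reference viewing axis, mirroring the
#' mechanically known orientation of a camera rig relative to the skin.
#'
#' @param points Nx3 matrix of 3D points (mm).
#' @param threshold Inlier distance threshold in mm. Default 1.
#' @param iterations Hypothesis budget. Default 1000.
#' @param seed Integer seed making the fit reproducible. Default 1.
#' @param axis Optional length-3 reference axis for the orientation
#'   prior (need not be unit length).
#' @param axis_max_angle Cone half-angle in degrees for the prior.
#'   Default 60.
#' @return An object of class `plane_model`: list with `normal` (unit),
#'   `offset` (mm; the plane is `n . p = offset`), `inliers` (logical
#'   mask), `residuals` (signed distances, mm), `threshold` and `cost`.
#' @export
msac_plane_fit <- function(points, threshold = 1, iterations = 1000,
                           seed = 1, axis = NULL, axis_max_angle = 60) {
  P <- as_points(points)
  stopifnot(ncol(P) == 3)
  n <- nrow(P)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (is_collinear3d(P)) stop("degenerate input: points are collinear", call. = FALSE)
  stopifnot(threshold > 0, iterations >= 1)

  cos_min <- if (is.null(axis)) -1 else cos(axis_max_angle * pi / 180)
  axis_u <- if (is.null(axis)) NULL else unit(as.numeric(axis))
  t2 <- threshold^2

  score_triple <- function(idx) {
    pl <- plane_from_points(P[idx[1], ], P[idx[2], ], P[idx[3], ])
    if (is.null(pl)) return(NULL)
    if (!is.null(axis_u) && abs(sum(pl$normal * axis_u)) < cos_min) return(NULL)
    r2 <- (P %*% pl$normal - pl$offset)^2
    list(cost = sum(pmin(r2, t2)), plane = pl)
  }

  best <- NULL
  if (choose(n, 3) <= iterations) {
    triples <- utils::combn(n, 3)
    for (k in seq_len(ncol(triples))) {
      sc <- score_triple(triples[, k])
      if (!is.null(sc) && (is.null(best) || sc$cost < best$cost)) best <- sc
    }
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    for (k in seq_len(iterations)) {
      sc <- score_triple(sample.int(n, 3))
      if (!is.null(sc) && (is.null(best) || sc$cost < best$cost)) best <- sc
    }
  }
  if (is.null(best))
    stop("no admissible plane hypothesis (orientation prior too tight?)", call. = FALSE)

  # least-squares refit on the consensus set, then final mask
  res <- as.numeric(P %*% best$plane$normal - best$plane$offset)
  inl <- abs(res) <= threshold
  if (sum(inl) >= 3 && !is_collinear3d(P[inl, , drop = FALSE])) {
    pl <- fit_plane_lsq(P[inl, , drop = FALSE])
    # orient consistently with the hypothesis (and the prior, if any)
    ref <- if (is.null(axis_u)) best$plane$normal else axis_u
    if (sum(pl$normal * ref) < 0) {
      pl$normal <- -pl$normal; pl$offset <- -pl$offset
    }
  } else {
    pl <- best$plane
  }
  res <- as.numeric(P %*% pl$normal - pl$offset)
  inl <- abs(res) <= threshold
  structure(list(normal = pl$normal, offset = pl$offset,
                 inliers = inl, residuals = res,
                 threshold = threshold,
                 cost = sum(pmin(res^2, t2))),
            class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> n = (%.4f, %.4f, %.4f), offset = %.3f mm\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  cat(sprintf("  %d/%d inliers at threshold %.3g mm\n",
              sum(x$inliers), length(x$inliers), x$threshold))
  invisible(x)
}

plane_from_points <- function(p1, p2, p3) {
  nrm <- cross3(p2 - p1, p3 - p1)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-12) return(NULL)
  nrm <- nrm / nn
  list(normal = nrm, offset = sum(nrm * p1))
}

fit_plane_lsq <- function(P) {
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Q), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  nrm <- nrm / sqrt(sum(nrm^2))
  list(normal = nrm, offset = sum(nrm * ctr))
}

is_collinear3d <- function(P, tol = 1e-9) {
  if (nrow(P) < 3) return(TRUE)
  Q <- sweep(P, 2, colMeans(P))
  d <- svd(Q, nu = 0, nv = 0)$d
  d[2] <= tol * max(d[1], 1)
}

#' Remove 3D outliers with a fitted plane
#'
#' @param tri_set A `triangulation_set`.
#' @param plane A `plane_model` fitted to the same points.
#' @return List with `inliers` (the masked `triangulation_set`),
#'   `outliers`, and `discard_ratio` = matched feature count / inlier
#'   count (>= 1; large values mean heavy pruning).
#' @export
filter_outliers <- function(tri_set, plane) {
  stopifnot(inherits(plane, "plane_model"))
  n <- nrow(tri_set)
  if (n != length(plane$inliers))
    stop("plane model does not match the triangulation set", call. = FALSE)
  mask <- plane$inliers
  if (!any(mask)) stop("plane fit left zero inliers", call. = FALSE)
  inl <- tri_set[mask, , drop = FALSE]
  outl <- tri_set[!mask, , drop = FALSE]
  for (s in list(inl, outl)) class(s) <- class(tri_set)
  attr(inl, "pair") <- attr(tri_set, "pair")
  attr(outl, "pair") <- attr(tri_set, "pair")
  class(inl) <- class(tri_set); class(outl) <- class(tri_set)
  list(inliers = inl, outliers = outl, discard_ratio = n / sum(mask))
}

#' Estimate the analyzed skin area from plane inliers
#'
#' Inlier features are orthogonally projected onto the fitted plane,
#' expressed in 2D plane coordinates, Delaunay triangulated, and the
#' triangle areas are summed; the result is reported in cm^2. For a
#' convex scatter the triangulation tiles the convex hull, so the sum
#' equals the hull area.
#'
#' @param inliers A `triangulation_set` (or Nx3 matrix) of inlier points.
#' @param plane The `plane_model` they belong to.
#' @return An object of class `area_estimate`: list with `area_cm2`,
#'   `triangle_count`, `boundary` (hull vertex indices into the inliers)
#'   and `coords2d`.
#' @export
estimate_area <- function(inliers, plane) {
  P <- if (is.data.frame(inliers)) as.matrix(inliers[, c("x", "y", "z")]) else as_points(inliers)
  if (nrow(P) < 3) stop("need at least 3 inlier points", call. = FALSE)
  nrm <- plane$normal
  proj <- P - (P %*% nrm - plane$offset) %*% t(nrm)
  # orthonormal in-plane basis
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(cross3(nrm, ref))
  e2 <- cross3(nrm, e1)
  uv <- cbind(proj %*% e1, proj %*% e2)
  if (is_collinear(uv)) {
    warning("projected points are collinear; area is zero")
    return(structure(list(area_cm2 = 0, triangle_count = 0L,
                          boundary = integer(0), coords2d = uv),
                     class = "area_estimate"))
  }
  # co-located duplicate detections collapse to one site; duplicates
  # carry no area and degrade the triangulation numerically
  uvu <- unique(round(uv, 6))
  areas <- tryCatch({
    dd <- deldir::deldir(uvu[, 1], uvu[, 2], suppressMsge = TRUE)
    tl <- deldir::triang.list(dd)
    vapply(tl, function(tr) {
      abs((tr$x[2] - tr$x[1]) * (tr$y[3] - tr$y[1]) -
          (tr$x[3] - tr$x[1]) * (tr$y[2] - tr$y[1])) / 2
    }, numeric(1))
  }, error = function(e) {
    # numerically degenerate scatter: fall back to the hull polygon area,
    # which the Delaunay triangle sum tiles exactly
    warning("Delaunay triangulation failed (", conditionMessage(e),
            "); using convex-hull area", call. = FALSE)
    hl <- grDevices::chull(uvu[, 1], uvu[, 2])
    hx <- uvu[hl, 1]; hy <- uvu[hl, 2]
    abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  })
  hull <- grDevices::chull(uv[, 1], uv[, 2])
  structure(list(area_cm2 = sum(areas) / 100,  # mm^2 -> cm^2
                 triangle_count = length(areas),
                 boundary = hull, coords2d = uv),
            class = "area_estimate")
}

#' @export
print.area_estimate <- function(x, ...) {
  cat(sprintf("<area_estimate> %.3f cm^2 from %d Delaunay triangle(s)\n",
              x$area_cm2, x$triangle_count))
  invisible(x)
}
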