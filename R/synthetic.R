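#' Build a convergent synthetic camera rig
#'
#' Places `n_cameras` on a ring at height `distance` above the skin-plane
#' center (for four cameras, the corners of a square, echoing cameras
#' mounted in the flat detector of a surgical C-arm) and points them all
#' at `target`. Pairwise vergence angles on the default rig exceed 5
#' degrees, which conditions triangulation well.
#'
#' @param n_cameras Number of cameras (>= 2). Default 4.
#' @param distance Height of the camera plane above the target, mm.
#' @param offset Half side-length of the mounting square, mm.
#' @param image_size `c(width, height)` in pixels.
#' @param focal Focal length in pixels (fx = fy).
#' @param dist Distortion coefficients shared by all cameras.
#' @param target Length-3 world point all cameras converge on (mm).
#' @return List of [camera_model()] objects.
#' @examples
#' rig <- make_rig()
#' camera_pairs(length(rig))  # the six admissible pairs
#' @export
make_rig <- function(n_cameras = 4, distance = 450, offset = 100,
                     image_size = c(512, 384), focal = 1800,
                     dist = c(0, 0, 0, 0, 0), target = c(0, 0, 0)) {
  stopifnot(n_cameras >= 2)
  r <- offset * sqrt(2)
  theta <- pi / 4 + 2 * pi * (seq_len(n_cameras) - 1) / n_cameras
  lapply(seq_len(n_cameras), function(i) {
    C <- c(r * cos(theta[i]), r * sin(theta[i]), distance) + target
    z <- unit(as.numeric(target) - C)
    x <- unit(cross3(c(0, 1, 0), z))
    y <- cross3(z, x)
    R <- rbind(x, y, z)
    camera_model(i, fx = focal, fy = focal,
                 cx = (image_size[1] - 1) / 2, cy = (image_size[2] - 1) / 2,
                 dist = dist, R = R, t = as.numeric(-R %*% C))
  })
}

#' Configure a synthetic skin scene
#'
#' Describes a near-planar skin patch carrying dark elliptical blobs
#' (moles and pigment spots) and bright circular optical markers, to be
#' rendered through a rig from [make_rig()]. Defaults model a surgical
#' field: a 70 x 50 mm patch at 450 mm working distance, blobs of
#' 0.8-2 mm radius with moderate elongation and 0.2 mm out-of-plane
#' jitter (skin is not perfectly flat, giving the plane-based outlier
#' stage realistic work), markers of 3 mm radius lying exactly on the
#' plane, and a mild lateral illumination gradient.
#'
#' `noise_px` is the standard deviation (pixels) of an independent
#' per-camera jitter applied to each object's rendered image position; it
#' emulates the view-inconsistency that detection and calibration errors
#' produce and drives the triangulation error. `noise_intensity` is
#' additive Gaussian grey-level noise.
#'
#' @param n_blobs,blob_radius,blob_intensity,blob_elongation Blob count,
#'   radius range (mm), intensity range (grey levels) and axis-ratio
#'   range.
#' @param tilt_sd Out-of-plane blob jitter sigma, mm.
#' @param n_markers,marker_radius,marker_intensity Marker spec.
#' @param extent Plane extent `c(x, y)` in mm, centred on the origin.
#' @param background Skin background grey level.
#' @param illumination Peak-to-peak amplitude of the linear illumination
#'   gradient across the image, grey levels.
#' @param noise_px Per-camera projection jitter sigma, pixels.
#' @param noise_intensity Additive pixel noise sigma, grey levels.
#' @param image_size Rendered image size `c(width, height)`; the
#'   clinical-resolution preset is `c(2592, 1920)`.
#' @param supersample Rasterization supersampling factor per axis.
#' @param seed Mandatory integer seed; the scene is fully reproducible.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(n_blobs = 20, blob_radius = c(0.8, 2.0),
                         blob_intensity = c(40, 110),
                         blob_elongation = c(1, 1.5), tilt_sd = 0.2,
                         n_markers = 5, marker_radius = 3,
                         marker_intensity = 250,
                         extent = c(70, 50), background = 170,
                         illumination = 15, noise_px = 0,
                         noise_intensity = 0,
                         image_size = c(512, 384), supersample = 8,
                         seed = 1) {
  stopifnot(n_blobs >= 0, n_markers >= 0, all(blob_radius > 0),
            supersample >= 1, !is.null(seed))
  structure(list(n_blobs = n_blobs, blob_radius = blob_radius,
                 blob_intensity = blob_intensity,
                 blob_elongation = blob_elongation, tilt_sd = tilt_sd,
                 n_markers = n_markers, marker_radius = marker_radius,
                 marker_intensity = marker_intensity,
                 extent = extent, background = background,
                 illumination = illumination, noise_px = noise_px,
                 noise_intensity = noise_intensity,
                 image_size = image_size, supersample = supersample,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Render a synthetic scene through a camera rig
#'
#' Rasterizes every blob and marker analytically: supersampled pixel
#' rays are intersected with the object's plane and tested against the
#' object's ellipse, coverage fractions are box-averaged, composited over
#' the illumination-graded background, optionally degraded with noise,
#' and quantized to 8-bit levels. Rendering is deterministic given the
#' scene seed.
#'
#' @param config A [scene_config()].
#' @param cameras Optional rig; defaults to `make_rig()` at the scene's
#'   image size.
#' @return A list of class `synthetic_scene`: `images` (one 8-bit matrix
#'   per camera), `cameras`, and `ground_truth` with `blobs` and
#'   `markers` data frames (3D centres in mm plus geometry) and
#'   `projections` (per camera, the analytic noiseless projected
#'   centres).
#' @export
render_scene <- function(config, cameras = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(cameras)) cameras <- make_rig(image_size = config$image_size)
  ncam <- length(cameras)
  w <- config$image_size[1]; h <- config$image_size[2]

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  objs <- place_objects(config)
  blobs <- objs$blobs; markers <- objs$markers
  all_obj <- rbind(
    if (nrow(blobs)) cbind(blobs, type = "blob"),
    if (nrow(markers)) cbind(markers, type = "marker"))
  if (is.null(all_obj))
    all_obj <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0), type = character(0))

  # per-camera, per-object projection jitter (view inconsistency)
  jitter <- array(0, dim = c(max(nrow(all_obj), 1), 2, ncam))
  if (config$noise_px > 0 && nrow(all_obj) > 0)
    jitter[] <- stats::rnorm(length(jitter), sd = config$noise_px)

  images <- vector("list", ncam)
  projections <- vector("list", ncam)
  for (ci in seq_len(ncam)) {
    cam <- cameras[[ci]]
    xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
    img <- matrix(config$background, h, w) +
      config$illumination * (xx / max(w - 1, 1) - 0.5)
    if (nrow(all_obj) > 0) {
      for (k in seq_len(nrow(all_obj))) {
        img <- composite_object(img, cam, all_obj[k, ],
                                jitter[k, , ci], config$supersample)
      }
      projections[[ci]] <- data.frame(
        id = all_obj$id, type = all_obj$type,
        project_points(cam, as.matrix(all_obj[, c("x", "y", "z")])))
      names(projections[[ci]])[3:4] <- c("px", "py")
    } else {
      projections[[ci]] <- data.frame(id = integer(0), type = character(0),
                                      px = numeric(0), py = numeric(0))
    }
    if (config$noise_intensity > 0)
      img <- img + stats::rnorm(length(img), sd = config$noise_intensity)
    images[[ci]] <- quantize8(img)
  }

  structure(list(images = images, cameras = cameras,
                 ground_truth = list(blobs = blobs, markers = markers,
                                     projections = projections),
                 config = config),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d camera(s) %dx%d, %d blob(s), %d marker(s), seed %d\n",
              length(x$images), ncol(x$images[[1]]), nrow(x$images[[1]]),
              nrow(x$ground_truth$blobs), nrow(x$ground_truth$markers),
              x$config$seed))
  invisible(x)
}

# Rejection-sample non-overlapping object placements; draws happen in a
# fixed order so scenes are reproducible.
place_objects <- function(config) {
  ex <- config$extent / 2
  placed <- matrix(numeric(0), 0, 2)  # centers
  excl <- numeric(0)                  # exclusion radii (refinement window)
  draw_center <- function(margin, excl_r) {
    for (att in 1:2000) {
      p <- c(stats::runif(1, -ex[1] + margin, ex[1] - margin),
             stats::runif(1, -ex[2] + margin, ex[2] - margin))
      if (nrow(placed) == 0 ||
          all(sqrt(rowSums((placed - matrix(p, nrow(placed), 2, byrow = TRUE))^2)) >
              excl + excl_r))
        return(p)
    }
    stop("could not place scene objects without overlap; reduce counts or radii",
         call. = FALSE)
  }
  blobs <- markers <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                                 z = numeric(0), radius = numeric(0),
                                 intensity = numeric(0), elongation = numeric(0),
                                 angle = numeric(0))
  # markers first: they are few and large, blobs pack around them
  for (i in seq_len(config$n_markers)) {
    r <- config$marker_radius
    excl_r <- r + 2
    p <- draw_center(margin = r + 2, excl_r = excl_r)
    placed <- rbind(placed, p); excl <- c(excl, excl_r)
    markers <- rbind(markers, data.frame(
      id = config$n_blobs + i, x = p[1], y = p[2], z = 0,
      radius = r, intensity = config$marker_intensity,
      elongation = 1, angle = 0))
  }
  for (i in seq_len(config$n_blobs)) {
    r <- stats::runif(1, config$blob_radius[1], config$blob_radius[2])
    el <- stats::runif(1, config$blob_elongation[1], config$blob_elongation[2])
    excl_r <- 1.25 * r * el + 1.25
    p <- draw_center(margin = r * el + 2, excl_r = excl_r)
    placed <- rbind(placed, p); excl <- c(excl, excl_r)
    blobs <- rbind(blobs, data.frame(
      id = i, x = p[1], y = p[2],
      z = stats::rnorm(1, 0, config$tilt_sd),
      radius = r,
      intensity = stats::runif(1, config$blob_intensity[1], config$blob_intensity[2]),
      elongation = el, angle = stats::runif(1, 0, pi)))
  }
  list(blobs = blobs, markers = markers)
}

# Composite one planar elliptical object into a camera image by
# supersampled ray casting against the object's plane z = z_obj.
composite_object <- function(img, cam, obj, jitter, ss) {
  h <- nrow(img); w <- ncol(img)
  a <- obj$radius * obj$elongation; b <- obj$radius
  ca <- cos(obj$angle); sa <- sin(obj$angle)
  ctr <- c(obj$x, obj$y, obj$z)
  # projected bounding box from boundary samples
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  bnd <- cbind(obj$x + a * cos(th) * ca - b * sin(th) * sa,
               obj$y + a * cos(th) * sa + b * sin(th) * ca,
               obj$z)
  pb <- project_points(cam, bnd)
  pb[, 1] <- pb[, 1] + jitter[1]; pb[, 2] <- pb[, 2] + jitter[2]
  x0 <- max(0, floor(min(pb[, 1])) - 1); x1 <- min(w - 1, ceiling(max(pb[, 1])) + 1)
  y0 <- max(0, floor(min(pb[, 2])) - 1); y1 <- min(h - 1, ceiling(max(pb[, 2])) + 1)
  if (x1 < x0 || y1 < y0) return(img)
  nx <- (x1 - x0 + 1) * ss; ny <- (y1 - y0 + 1) * ss
  sx <- x0 - 0.5 + (seq_len(nx) - 0.5) / ss  # supersample x coords
  sy <- y0 - 0.5 + (seq_len(ny) - 0.5) / ss
  g <- cbind(rep(sx, times = ny), rep(sy, each = nx))
  # remove jitter before casting: the object renders displaced by +jitter
  g[, 1] <- g[, 1] - jitter[1]; g[, 2] <- g[, 2] - jitter[2]
  if (any(cam$dist != 0)) g <- undistort_points(cam, g)
  rays <- pixel_ray(cam, g)
  nrm <- c(0, 0, 1)
  denom <- as.numeric(rays$direction %*% nrm)
  tt <- sum((ctr - rays$origin) * nrm) / denom
  px <- matrix(rays$origin, length(tt), 3, byrow = TRUE) + rays$direction * tt
  du <- px[, 1] - obj$x; dv <- px[, 2] - obj$y
  u <- du * ca + dv * sa; v <- -du * sa + dv * ca
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cov <- matrix(inside, ny, nx, byrow = TRUE)
  alpha <- block_mean(cov, ss)
  rows <- (y0 + 1):(y1 + 1); cols <- (x0 + 1):(x1 + 1)
  img[rows, cols] <- img[rows, cols] * (1 - alpha) + obj$intensity * alpha
  img
}

block_mean <- function(m, ss) {
  if (ss == 1) return(m * 1)
  nr <- nrow(m) / ss; nc <- ncol(m) / ss
  a <- array(m, dim = c(ss, nr, ss, nc))
  apply(a, c(2, 4), mean)
}
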