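#' Detect blob features with Maximally Stable Extremal Regions (MSER)
#'
#' Extremal regions at threshold t are the 4-connected components of
#' pixels with intensity <= t (dark polarity) or of the inverted image
#' (bright polarity). A region is reported where its relative area change
#' across +/- `delta` threshold levels is locally minimal along its branch
#' of the component tree and does not exceed `max_variation`, subject to
#' the area bounds. Co-located nested regions are all kept: a dark mole
#' with a darker core is deliberately reported at both scales, and
#' de-duplication is deferred to the 3D outlier-removal stage.
#'
#' Feature location is the region's binary centroid and its scale is
#' `sqrt(area / pi)` (the radius of the equivalent disc). Features are
#' sorted by (y, x, scale) and indexed 1..n so ensembles are
#' deterministic.
#'
#' @param image Grayscale image matrix, values in 0..255.
#' @param roi Optional region of interest `c(x, y, width, height)`
#'   (0-based corner), or NULL for the whole image.
#' @param delta Stability test threshold step (levels). Default 2.
#' @param min_area,max_area Region area bounds in pixels; `max_area = NULL`
#'   defaults to 1% of the ROI area.
#' @param max_variation Maximum relative area variation. Default 0.25.
#' @param polarity `"both"` (default), `"dark"` or `"bright"`.
#' @param camera_id Optional camera id stored with the features.
#' @param region_pixels If TRUE, attach the pixel set of every region as
#'   a list attribute `"regions"` (list of Nx2 x,y matrices).
#' @return A `feature_ensemble` data frame with columns `camera_id`,
#'   `index`, `x`, `y`, `scale`, `detector`, `response` (negative area
#'   variation: larger is more stable), `polarity`, `level`, `area`.
#' @examples
#' img <- matrix(200, 32, 32)
#' yy <- matrix(0:31, 32, 32); xx <- t(yy)
#' img[(xx - 16)^2 + (yy - 16)^2 <= 36] <- 40
#' detect_mser(img)
#' @export
detect_mser <- function(image, roi = NULL, delta = 2, min_area = 10,
                        max_area = NULL, max_variation = 0.25,
                        polarity = c("both", "dark", "bright"),
                        camera_id = NA_integer_, region_pixels = FALSE) {
  stopifnot_image(image)
  polarity <- match.arg(polarity)
  stopifnot(delta >= 1, min_area > 0, max_variation > 0)
  cr <- crop_roi(image, roi)
  if (is.null(cr)) return(empty_ensemble(camera_id, "MSER"))
  sub <- cr$img
  if (is.null(max_area)) max_area <- 0.01 * length(sub)
  iv <- as.integer(clamp(round(sub), 0, 255))

  run_one <- function(pol) {
    v <- if (pol == "dark") iv else 255L - iv
    df <- mser_detect_cpp(v, nrow(sub), ncol(sub), as.integer(delta),
                          min_area, max_area, max_variation)
    if (nrow(df) == 0) return(NULL)
    df$polarity <- pol
    if (pol == "bright") df$level <- 255L - df$level
    df
  }
  parts <- list()
  if (polarity %in% c("both", "dark")) parts$dark <- run_one("dark")
  if (polarity %in% c("both", "bright")) parts$bright <- run_one("bright")
  res <- do.call(rbind, parts)
  if (is.null(res) || nrow(res) == 0) return(empty_ensemble(camera_id, "MSER"))

  ens <- data.frame(camera_id = camera_id,
                    index = 0L,
                    x = res$x + cr$off[1],
                    y = res$y + cr$off[2],
                    scale = sqrt(res$area / pi),
                    detector = "MSER",
                    response = -res$q,
                    polarity = res$polarity,
                    level = res$level,
                    area = res$area,
                    stringsAsFactors = FALSE)
  ord <- order(ens$y, ens$x, ens$scale)
  ens <- ens[ord, , drop = FALSE]
  ens$index <- seq_len(nrow(ens))
  rownames(ens) <- NULL
  if (region_pixels) {
    seeds <- res$seed[ord]
    levels_cropped <- ifelse(ens$polarity == "bright", 255L - ens$level, ens$level)
    regions <- lapply(seq_len(nrow(ens)), function(k) {
      v <- if (ens$polarity[k] == "dark") iv else 255L - iv
      p <- mser_region_pixels_cpp(v, nrow(sub), ncol(sub),
                                  seeds[k], as.integer(levels_cropped[k]))
      cbind(x = p %/% nrow(sub) + cr$off[1], y = p %% nrow(sub) + cr$off[2])
    })
    attr(ens, "regions") <- regions
  }
  class(ens) <- c("feature_ensemble", "data.frame")
  ens
}

crop_roi <- function(image, roi) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(roi)) return(list(img = image, off = c(0, 0)))
  if (is.list(roi)) roi <- unlist(roi)
  if (!is.null(names(roi)) && all(c("x", "y", "w", "h") %in% names(roi)))
    roi <- roi[c("x", "y", "w", "h")]
  roi <- as.numeric(roi)[1:4]
  if (any(is.na(roi))) stop("roi must supply x, y, w, h", call. = FALSE)
  x0 <- max(0, floor(roi[1])); y0 <- max(0, floor(roi[2]))
  x1 <- min(w - 1, ceiling(roi[1] + roi[3] - 1))
  y1 <- min(h - 1, ceiling(roi[2] + roi[4] - 1))
  if (roi[3] <= 0 || roi[4] <= 0 || x1 < x0 || y1 < y0) return(NULL)
  list(img = image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
       off = c(x0, y0))
}

empty_ensemble <- function(camera_id, detector) {
  ens <- data.frame(camera_id = integer(0), index = integer(0),
                    x = numeric(0), y = numeric(0), scale = numeric(0),
                    detector = character(0), response = numeric(0),
                    polarity = character(0), level = integer(0),
                    area = numeric(0), stringsAsFactors = FALSE)
  class(ens) <- c("feature_ensemble", "data.frame")
  ens
}

#' @export
print.feature_ensemble <- function(x, ...) {
  cat(sprintf("<feature_ensemble> %d feature(s)%s\n", nrow(x),
              if (nrow(x) && !is.na(x$camera_id[1]))
                sprintf(" from camera %d", x$camera_id[1]) else ""))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
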