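#' Read and write 8-bit grayscale images
#'
#' PNG is read natively; TIFF support uses the `tiff` package when
#' available. Color inputs are converted to luma by channel averaging.
#' Images are exchanged as numeric matrices in 0..255 (see package
#' conventions).
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @return `read_image()`: a grayscale image matrix in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE],
                                      c(1, 2), mean)
  round(a * 255)
}

#' @param image Grayscale image matrix in 0..255.
#' @rdname read_image
#' @export
write_image <- function(image, path) {
  stopifnot_image(image)
  ext <- tolower(tools::file_ext(path))
  a <- clamp(image, 0, 255) / 255
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package", call. = FALSE)
    tiff::writeTIFF(a, path, bits.per.sample = 8)
  } else {
    png::writePNG(a, path)
  }
  invisible(path)
}

#' Export a triangulated feature cloud
#'
#' Writes an ASCII PLY with per-vertex triangulation error, and/or the
#' CSV twin with pair and index columns.
#'
#' @param tri_set A `triangulation_set`.
#' @param path Output path (`.ply` or `.csv` decides the format).
#' @export
write_cloud <- function(tri_set, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    pair <- attr(tri_set, "pair")
    df <- cbind(pair = paste(pair, collapse = "|"),
                as.data.frame(tri_set)[, c("index", "x", "y", "z", "e")])
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  n <- nrow(tri_set)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", n),
           "property float x", "property float y", "property float z",
           "property float error", "end_header")
  body <- sprintf("%.6f %.6f %.6f %.6f", tri_set$x, tri_set$y, tri_set$z, tri_set$e)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and write region-of-interest files
#'
#' ROI files are JSON lists of `{camera_id, x, y, w, h}` records
#' (0-based pixel boxes).
#'
#' @param path File path.
#' @return `read_rois()`: data frame with columns `camera_id, x, y, w, h`.
#' @export
read_rois <- function(path) {
  recs <- jsonlite::fromJSON(path)
  as.data.frame(recs)[, c("camera_id", "x", "y", "w", "h")]
}

#' @param rois Data frame with columns `camera_id, x, y, w, h`.
#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `clahe`, `mser`,
#' `surf`, `match`, `plane`, `refine`, `seed`, `roi_center`; missing keys
#' keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Write a run report to disk
#'
#' Persists the summary table as CSV and the full report (statistics,
#' configuration snapshot, version) as JSON alongside it.
#'
#' @param report A `localization_report`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- summary(report)
  if (!is.null(tab))
    utils::write.csv(tab, file.path(dir, "region_stats.csv"), row.names = FALSE)
  js <- list(totals = report$totals,
             regions = lapply(report$regions, function(r) {
               list(region_id = r$region_id, detector = r$detector,
                    pair = r$pair, n_detected = r$n_detected,
                    n_matched = r$n_matched, stats = r$stats)
             }),
             config = unclass(report$config), version = report$version)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(dir)
}

#' Write a synthetic scene to disk in pipeline-ready formats
#'
#' PNG images, the calibration JSON, and ground-truth CSVs — exactly the
#' formats the localization pipeline consumes.
#'
#' @param scene A `synthetic_scene` from [render_scene()].
#' @param dir Output directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(scene$images))
    write_image(scene$images[[i]], file.path(dir, sprintf("camera%d.png", i)))
  write_calibration(scene$cameras, file.path(dir, "calibration.json"))
  utils::write.csv(scene$ground_truth$blobs, file.path(dir, "gt_blobs.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$ground_truth$markers, file.path(dir, "gt_markers.csv"),
                   row.names = FALSE)
  invisible(dir)
}
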