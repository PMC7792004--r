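# Small image and rig builders shared across tests.

# Disc of a given intensity on a constant background; 0-based center.
disc_image <- function(size = c(32, 32), center = c(16, 16), radius = 6,
                       fg = 40, bg = 200) {
  yy <- matrix(0:(size[1] - 1), size[1], size[2])
  xx <- matrix(0:(size[2] - 1), size[1], size[2], byrow = TRUE)
  img <- matrix(bg, size[1], size[2])
  img[(xx - center[1])^2 + (yy - center[2])^2 <= radius^2] <- fg
  img
}

# Anti-aliased Gaussian dark blob.
gaussian_blob_image <- function(size = 32, center = c(16, 16), sigma = 3,
                                depth = 150, bg = 200) {
  yy <- matrix(0:(size - 1), size, size)
  xx <- t(yy)
  round(bg - depth * exp(-((xx - center[1])^2 + (yy - center[2])^2) / (2 * sigma^2)))
}

# Two identical-intrinsics cameras related by a pure x-translation.
pure_translation_pair <- function(baseline = 50, f = 1000,
                                  pp = c(255.5, 191.5)) {
  list(camera_model(1, f, f, pp[1], pp[2]),
       camera_model(2, f, f, pp[1], pp[2], t = c(-baseline, 0, 0)))
}

# Random 3D points in front of both cameras of a small converging rig.
rig_cloud <- function(n, seed = 1, spread = c(30, 20, 2)) {
  set.seed(seed)
  cbind(runif(n, -spread[1], spread[1]),
        runif(n, -spread[2], spread[2]),
        runif(n, -spread[3], spread[3]))
}

fast_scene <- function(seed = 1, ...) {
  scene_config(seed = seed, supersample = 4, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Descriptor set built directly from raw vectors (rows are normalized;
# zero rows are flagged unmatchable), for matching tests.
fake_set <- function(vectors, y_row, x = NULL, camera_id = 1L) {
  n <- nrow(vectors)
  norms <- sqrt(rowSums(vectors^2))
  vectors[norms > 0, ] <- vectors[norms > 0, , drop = FALSE] / norms[norms > 0]
  ens <- data.frame(camera_id = camera_id, index = seq_len(n),
                    x = x %||% rep(0, n), y = y_row, scale = 2,
                    detector = "MSER", response = 1, polarity = "dark",
                    level = 0L, area = 12, stringsAsFactors = FALSE)
  class(ens) <- c("feature_ensemble", "data.frame")
  dermatrack:::new_descriptor_set(vectors, y_row, x %||% rep(0, n),
                                  norms == 0, ens)
}
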