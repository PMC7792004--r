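test_that("rig combinatorics and convergence hold", {
  rig <- make_rig()
  expect_length(rig, 4)
  expect_equal(nrow(camera_pairs(4)), 6)
  expect_equal(nrow(camera_pairs(2)), 1)
  # all cameras point at the target
  for (cm in rig) {
    z <- cm$R[3, ]
    to_target <- -camera_center(cm) / sqrt(sum(camera_center(cm)^2))
    expect_equal(as.numeric(z), as.numeric(to_target), tolerance = 1e-9)
  }
  # pairwise vergence exceeds 5 degrees
  prs <- camera_pairs(4)
  for (k in seq_len(nrow(prs))) {
    v1 <- camera_center(rig[[prs[k, 1]]]); v2 <- camera_center(rig[[prs[k, 2]]])
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_gt(ang, 5)
  }
})

test_that("every ground-truth object projects inside at least two images", {
  sc <- render_scene(fast_scene(seed = 3))
  w <- ncol(sc$images[[1]]); h <- nrow(sc$images[[1]])
  inside <- sapply(sc$ground_truth$projections, function(pr)
    pr$px >= 0 & pr$px <= w - 1 & pr$py >= 0 & pr$py <= h - 1)
  expect_true(all(rowSums(inside) >= 2))
  # projection consistency with the rig calibration
  gt <- rbind(sc$ground_truth$blobs, sc$ground_truth$markers)
  for (ci in 1:4) {
    pp <- project_points(sc$cameras[[ci]], as.matrix(gt[, c("x", "y", "z")]))
    pr <- sc$ground_truth$projections[[ci]]
    expect_lt(max(abs(pp - cbind(pr$px, pr$py))), 1e-9)
  }
})

test_that("empty scenes render the illumination-graded background only", {
  cfg <- fast_scene(seed = 1, n_blobs = 0, n_markers = 0, illumination = 0,
                    image_size = c(64, 48))
  sc <- render_scene(cfg)
  for (img in sc$images) expect_true(all(img == cfg$background))
})

test_that("a centered blob's rendered centroid matches the analytic projection", {
  cfg <- scene_config(seed = 2, n_blobs = 1, n_markers = 0, tilt_sd = 0,
                      blob_radius = c(1.5, 1.5), blob_elongation = c(1, 1),
                      illumination = 0, supersample = 8)
  sc <- render_scene(cfg)
  gt <- sc$ground_truth
  for (ci in 1:4) {
    img <- sc$images[[ci]]
    pr <- gt$projections[[ci]]
    w <- which(img < cfg$background - 20, arr.ind = TRUE)
    wt <- cfg$background - img[w]
    cx <- sum((w[, 2] - 1) * wt) / sum(wt)
    cy <- sum((w[, 1] - 1) * wt) / sum(wt)
    expect_lt(sqrt((cx - pr$px[1])^2 + (cy - pr$py[1])^2), 0.2)
  }
})

test_that("rendering is bit-identical for the same seed and differs across seeds", {
  a <- render_scene(fast_scene(seed = 5, noise_intensity = 2, noise_px = 0.3,
                               image_size = c(128, 96)))
  b <- render_scene(fast_scene(seed = 5, noise_intensity = 2, noise_px = 0.3,
                               image_size = c(128, 96)))
  cc <- render_scene(fast_scene(seed = 6, noise_intensity = 2, noise_px = 0.3,
                                image_size = c(128, 96)))
  for (ci in 1:4) expect_identical(a$images[[ci]], b$images[[ci]])
  expect_false(identical(a$images[[1]], cc$images[[1]]))
  expect_identical(a$ground_truth$blobs, b$ground_truth$blobs)
})

test_that("scene files round-trip through the pipeline formats", {
  sc <- render_scene(fast_scene(seed = 9, image_size = c(96, 72), n_blobs = 3,
                                n_markers = 2))
  dir <- tempfile()
  write_scene(sc, dir)
  img <- read_image(file.path(dir, "camera1.png"))
  expect_equal(img, sc$images[[1]])
  cams <- read_calibration(file.path(dir, "calibration.json"))
  expect_equal(cams[[2]]$R, sc$cameras[[2]]$R, tolerance = 1e-12)
  gtm <- read.csv(file.path(dir, "gt_markers.csv"))
  expect_equal(nrow(gtm), 2)
})
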