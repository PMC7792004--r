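test_that("undistortion is the identity for zero coefficients and preserves constants", {
  img <- matrix(runif(64 * 48, 0, 255), 48, 64)
  cam <- camera_model(1, 800, 800, 31.5, 23.5)
  expect_identical(correct_intrinsics(img, cam), img)

  camd <- camera_model(1, 800, 800, 31.5, 23.5, dist = c(-0.2, 0.05, 0, 0, 0))
  const <- matrix(120, 48, 64)
  out <- correct_intrinsics(const, camd)
  # interior pixels stay at the constant value
  expect_equal(out[10:38, 10:54], const[10:38, 10:54])
  expect_error(correct_intrinsics(matrix(numeric(0), 0, 0), cam), "nonempty")
})

test_that("a bright pixel moves by the closed-form radial map under undistortion", {
  # evaluate the distortion polynomial directly to predict where the
  # undistorted image must place a source pixel
  h <- 41; w <- 41
  cam <- camera_model(1, 30, 30, 20, 20, dist = c(0.6, 0, 0, 0, 0))
  src <- c(38, 20)  # bright pixel in the distorted input, on the x-axis
  img <- matrix(0, h, w); img[src[2] + 1, src[1] + 1] <- 255
  out <- correct_intrinsics(img, cam)
  # output pixel (ideal coords) maps back to src via forward distortion:
  # xd = xn (1 + k1 xn^2) with yn = 0 -> solve directly on a fine grid
  xn_grid <- seq(0, 1, by = 1e-6)
  xd_grid <- xn_grid * (1 + 0.6 * xn_grid^2)
  xn_star <- xn_grid[which.min(abs(xd_grid - (src[1] - 20) / 30))]
  expect_x <- 20 + 30 * xn_star
  peak <- which(out == max(out), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak[["col"]] - 1 - expect_x), 0.75)
  expect_equal(peak[["row"]] - 1, 20)
})

test_that("pixel rays obey axis, round-trip and normalization properties", {
  rig <- make_rig()
  cam <- rig[[2]]
  # principal point ray equals the optical axis
  r <- pixel_ray(cam, c(cam$cx, cam$cy))
  expect_equal(as.numeric(r$direction), as.numeric(cam$R[3, ]), tolerance = 1e-12)
  # project then cast: the point lies on the ray
  X <- c(12.3, -8.1, 0.4)
  px <- project_points(cam, X)
  r <- pixel_ray(cam, px)
  tpar <- sum((X - r$origin) * r$direction[1, ])
  expect_lt(sqrt(sum((r$origin + tpar * r$direction[1, ] - X)^2)), 1e-9)
  # unit norm for 100 random pixels
  set.seed(42)
  px100 <- cbind(runif(100, 0, 511), runif(100, 0, 383))
  r100 <- pixel_ray(cam, px100)
  expect_equal(rowSums(r100$direction^2), rep(1, 100), tolerance = 1e-12)
})

test_that("point undistortion inverts the forward model", {
  cam <- camera_model(1, 900, 880, 256, 192, dist = c(-0.15, 0.03, 1e-3, -5e-4, 0))
  set.seed(3)
  ideal <- cbind(runif(50, 50, 450), runif(50, 50, 330))
  xn <- (ideal[, 1] - cam$cx) / cam$fx
  yn <- (ideal[, 2] - cam$cy) / cam$fy
  d <- dermatrack:::distort_normalized(xn, yn, cam$dist)
  observed <- cbind(cam$fx * d[, 1] + cam$cx, cam$fy * d[, 2] + cam$cy)
  back <- undistort_points(cam, observed)
  expect_equal(back, ideal, tolerance = 1e-6)
})

test_that("calibration files round-trip through JSON", {
  rig <- make_rig(dist = c(-0.1, 0.02, 0, 0, 0))
  path <- tempfile(fileext = ".json")
  write_calibration(rig, path)
  back <- read_calibration(path)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(back[[i]]$R, rig[[i]]$R, tolerance = 1e-12)
    expect_equal(back[[i]]$t, rig[[i]]$t, tolerance = 1e-12)
    expect_equal(back[[i]]$dist, rig[[i]]$dist)
  }
  expect_error(camera_model(1, -5, 5, 0, 0), "positive")
  expect_error(camera_model(1, 5, 5, 0, 0, R = diag(c(1, 1, -1))), "orthonormal")
})
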