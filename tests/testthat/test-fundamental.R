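test_that("pure x-translation recovers the analytic fundamental matrix", {
  cams <- pure_translation_pair()
  X <- rig_cloud(12, seed = 5)
  X[, 3] <- X[, 3] + 400  # in front of both cameras
  p1 <- project_points(cams[[1]], X)
  p2 <- project_points(cams[[2]], X)
  F <- estimate_fundamental(p1, p2)
  target <- matrix(c(0, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3) / sqrt(2)
  # compare up to the overall sign
  d <- min(max(abs(unclass(F) - target)), max(abs(unclass(F) + target)))
  expect_lt(d, 1e-6)
})

test_that("noiseless correspondences give tiny residuals and exact rank 2", {
  rig <- make_rig()
  X <- rig_cloud(25, seed = 11)
  p1 <- project_points(rig[[1]], X)
  p3 <- project_points(rig[[3]], X)
  F <- estimate_fundamental(p1, p3)
  expect_lt(max(epipolar_residuals(F, p1, p3)), 1e-6)
  sv <- svd(unclass(F))$d
  expect_gt(sv[1], 0); expect_gt(sv[2], 0)
  expect_identical(sv[3] < 1e-14, TRUE)
  expect_equal(sqrt(sum(F^2)), 1, tolerance = 1e-12)
  # agrees with the calibrated fundamental matrix up to sign/scale
  Fc <- fundamental_from_cameras(rig[[1]], rig[[3]])
  d <- min(max(abs(unclass(F) - unclass(Fc))), max(abs(unclass(F) + unclass(Fc))))
  expect_lt(d, 1e-6)
})

test_that("input validation rejects short and collinear configurations", {
  p <- cbind(1:7, 1:7)
  expect_error(estimate_fundamental(p, p), "at least 8")
  line <- cbind(1:10, 2 * (1:10) + 3)
  expect_error(estimate_fundamental(line, line + 1), "collinear")
})

test_that("normalization improves accuracy under pixel noise", {
  rig <- make_rig()
  X <- rig_cloud(40, seed = 2)
  p1 <- project_points(rig[[1]], X)
  p2 <- project_points(rig[[2]], X)
  # noiseless: both variants agree on the epipolar constraint
  Fn <- estimate_fundamental(p1, p2, normalize = TRUE)
  Fu <- estimate_fundamental(p1, p2, normalize = FALSE)
  expect_lt(max(epipolar_residuals(Fn, p1, p2)), 1e-6)
  expect_lt(max(epipolar_residuals(Fu, p1, p2)), 1e-4)
  # with 0.5 px noise the normalized variant has a smaller median
  # Sampson (first-order geometric) residual on noiseless projections
  sampson <- function(F, a, b) {
    F <- unclass(F)
    xa <- cbind(a, 1); xb <- cbind(b, 1)
    num <- rowSums((xb %*% F) * xa)^2
    l1 <- xa %*% t(F); l2 <- xb %*% F
    sqrt(num / (l2[, 1]^2 + l2[, 2]^2 + l1[, 1]^2 + l1[, 2]^2))
  }
  med_norm <- med_raw <- numeric(20)
  for (s in 1:20) {
    set.seed(100 + s)
    n1 <- p1 + matrix(rnorm(length(p1), sd = 0.5), ncol = 2)
    n2 <- p2 + matrix(rnorm(length(p2), sd = 0.5), ncol = 2)
    med_norm[s] <- median(sampson(
      estimate_fundamental(n1, n2, normalize = TRUE), p1, p2))
    med_raw[s] <- median(sampson(
      estimate_fundamental(n1, n2, normalize = FALSE), p1, p2))
  }
  expect_lt(median(med_norm), median(med_raw))
})

test_that("epipolar residuals shrink as noise decreases", {
  rig <- make_rig()
  X <- rig_cloud(30, seed = 9)
  p1 <- project_points(rig[[1]], X)
  p4 <- project_points(rig[[4]], X)
  res <- vapply(c(1, 0.5, 0.1, 0), function(s) {
    m <- numeric(5)
    for (k in 1:5) {
      set.seed(k)
      n1 <- p1 + matrix(rnorm(length(p1), sd = s), ncol = 2)
      n2 <- p4 + matrix(rnorm(length(p4), sd = s), ncol = 2)
      m[k] <- median(epipolar_residuals(estimate_fundamental(n1, n2), n1, n2))
    }
    mean(m)
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-12))  # non-increasing toward zero noise
  expect_lt(res[4], 1e-8)
})
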