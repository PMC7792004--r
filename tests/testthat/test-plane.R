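test_that("exact planes and minimal samples are recovered perfectly", {
  set.seed(1)
  P <- cbind(runif(50, -20, 20), runif(50, -20, 20), 0)
  pl <- msac_plane_fit(P, threshold = 0.5)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(abs(pl$offset), 0, tolerance = 1e-9)
  expect_true(all(pl$inliers))
  expect_lt(max(abs(pl$residuals)), 1e-9)
  # three non-collinear points: the plane passes through them exactly
  tri <- rbind(c(0, 0, 0), c(1, 0, 1), c(0, 1, 2))
  pl3 <- msac_plane_fit(tri, threshold = 0.1)
  expect_lt(max(abs(pl3$residuals)), 1e-9)
  expect_error(msac_plane_fit(rbind(c(0, 0, 0), c(1, 1, 1)), 1), "at least 3")
  expect_error(msac_plane_fit(cbind(1:5, 1:5, 1:5), 1), "collinear")
})

msac_fixture <- function(seed) {
  set.seed(seed)
  inl <- cbind(runif(80, -25, 25), runif(80, -25, 25), rnorm(80, 0, 0.05))
  out <- cbind(runif(20, -25, 25), runif(20, -25, 25), runif(20, -10, 10))
  keep <- abs(out[, 3]) > 0.5  # keep gross outliers genuinely off-plane
  list(P = rbind(inl, out), true_inlier = c(rep(TRUE, 80), !keep & rep(TRUE, 20)))
}

test_that("MSAC recovers a noisy plane among gross outliers over 10 seeds", {
  for (s in 1:10) {
    fx <- msac_fixture(s)
    pl <- msac_plane_fit(fx$P, threshold = 0.3, iterations = 500, seed = s)
    expect_gte(sum(pl$inliers[1:80]), 78)
    angle <- acos(min(abs(pl$normal[3]), 1)) * 180 / pi
    expect_lt(angle, 1)
  }
})

test_that("MSAC equals the exhaustive-triple oracle on small instances", {
  for (s in 1:6) {
    set.seed(300 + s)
    n <- sample(10:25, 1)
    P <- cbind(runif(n, -10, 10), runif(n, -10, 10), rnorm(n, 0, 0.1))
    P[sample(n, 3), 3] <- runif(3, 2, 6)
    pl <- msac_plane_fit(P, threshold = 0.3, iterations = choose(n, 3), seed = 1)
    orc <- oracle_msac(P, threshold = 0.3)
    sgn <- sign(sum(pl$normal * orc$normal))
    expect_equal(pl$normal, sgn * orc$normal, tolerance = 1e-9)
    expect_equal(pl$offset, sgn * orc$offset, tolerance = 1e-9)
    expect_identical(pl$inliers, orc$inliers)
  }
})

test_that("increasing the threshold never loses inliers", {
  fx <- msac_fixture(4)
  counts <- vapply(c(0.1, 0.3, 0.5, 1, 2), function(th)
    sum(msac_plane_fit(fx$P, threshold = th, iterations = 500, seed = 2)$inliers),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the orientation prior rejects off-axis hypotheses", {
  set.seed(9)
  P <- cbind(runif(30, -10, 10), runif(30, -10, 10), rnorm(30, 0, 0.02))
  pl <- msac_plane_fit(P, threshold = 0.1, axis = c(0, 0, 1), axis_max_angle = 30)
  expect_gt(abs(pl$normal[3]), cos(30 * pi / 180))
  expect_error(msac_plane_fit(P, threshold = 0.1, axis = c(1, 0, 0),
                              axis_max_angle = 5), "orientation prior")
})

test_that("outlier filtering reports the discard ratio as matched per inlier", {
  tri <- dermatrack:::empty_triangulation_set(c(1L, 2L))
  set.seed(2)
  df <- data.frame(index = 1:40, x = runif(40), y = runif(40),
                   z = c(rep(0, 10), rep(5, 30)), e = 0.1, cheirality = TRUE)
  attr(df, "pair") <- c(1L, 2L)
  class(df) <- class(tri)
  pl <- structure(list(normal = c(0, 0, 1), offset = 0,
                       inliers = df$z == 0, residuals = df$z,
                       threshold = 1, cost = 0), class = "plane_model")
  f <- filter_outliers(df, pl)
  expect_equal(nrow(f$inliers), 10)
  expect_equal(f$discard_ratio, 4.0)
  # all inliers: ratio 1
  pl2 <- structure(list(normal = c(0, 0, 1), offset = 0,
                        inliers = rep(TRUE, 40), residuals = rep(0, 40),
                        threshold = 10, cost = 0), class = "plane_model")
  expect_equal(filter_outliers(df, pl2)$discard_ratio, 1.0)
})

test_that("area estimation matches closed-form figures", {
  plane <- structure(list(normal = c(0, 0, 1), offset = 0), class = "plane_model")
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10, 10, 0))
  a <- estimate_area(sq, plane)
  expect_equal(a$area_cm2, 1.00, tolerance = 1e-9)
  # 200 points in a 20 x 30 mm rectangle including its corners
  set.seed(6)
  R <- rbind(cbind(runif(196, 0, 20), runif(196, 0, 30), 0),
             c(0, 0, 0), c(20, 0, 0), c(0, 30, 0), c(20, 30, 0))
  a2 <- estimate_area(R, plane)
  expect_lt(abs(a2$area_cm2 - 6.0) / 6.0, 0.02)
  # collinear projections give zero area with a warning
  line <- cbind(seq(0, 5, length.out = 5), 0, 0)
  expect_warning(a0 <- estimate_area(line, plane), "collinear")
  expect_equal(a0$area_cm2, 0)
})

test_that("area is rigid-transform invariant and tiles the convex hull", {
  set.seed(8)
  P <- cbind(runif(60, 0, 25), runif(60, 0, 15), 0)
  plane <- structure(list(normal = c(0, 0, 1), offset = 0), class = "plane_model")
  a1 <- estimate_area(P, plane)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3, 3)
  Rot <- R2 %*% R
  P2 <- P %*% t(Rot) + matrix(c(5, -3, 11), 60, 3, byrow = TRUE)
  n2 <- as.numeric(Rot %*% c(0, 0, 1))
  plane2 <- structure(list(normal = n2, offset = sum(n2 * c(5, -3, 11))),
                      class = "plane_model")
  a2 <- estimate_area(P2, plane2)
  expect_equal(a2$area_cm2, a1$area_cm2, tolerance = 1e-6)
  # Delaunay triangle sum equals the hull polygon area
  hull <- grDevices::chull(P[, 1], P[, 2])
  hx <- P[hull, 1]; hy <- P[hull, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  expect_equal(a1$area_cm2, hull_area / 100, tolerance = 1e-6)
})
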