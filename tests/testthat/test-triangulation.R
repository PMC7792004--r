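test_that("the symmetric skew-line case gives the exact midpoint and error", {
  tri <- triangulate(list(origin = c(0, 0, 0), direction = c(1, 0, 0)),
                     list(origin = c(0, 0, 1), direction = c(0, 1, 0)))
  expect_equal(tri$point, c(0, 0, 0.5))
  expect_equal(tri$e, 1.0)
})

test_that("intersecting rays triangulate to the intersection with zero error", {
  X <- c(3, -2, 7)
  o1 <- c(0, 0, 0); o2 <- c(10, 0, 0)
  tri <- triangulate(list(origin = o1, direction = X - o1),
                     list(origin = o2, direction = X - o2))
  expect_lt(sqrt(sum((tri$point - X)^2)), 1e-9)
  expect_lt(tri$e, 1e-9)
  expect_true(tri$cheirality)
})

test_that("random skew rays agree with the numerical minimization oracle", {
  set.seed(21)
  for (k in 1:50) {
    o1 <- runif(3, -50, 50); o2 <- runif(3, -50, 50)
    d1 <- rnorm(3); d2 <- rnorm(3)
    if (sqrt(sum((dermatrack:::cross3(d1 / sqrt(sum(d1^2)),
                                      d2 / sqrt(sum(d2^2))))^2)) < 1e-3) next
    tri <- triangulate(list(origin = o1, direction = d1),
                       list(origin = o2, direction = d2))
    orc <- oracle_triangulate(o1, d1, o2, d2)
    expect_lt(max(abs(tri$point - orc$point)), 1e-6)
    expect_lt(abs(tri$e - orc$e), 1e-6)
  }
})

test_that("triangulation error is invariant to ray order and rigid transforms", {
  set.seed(5)
  o1 <- c(0, 0, 0); d1 <- c(1, 0.2, 0.1)
  o2 <- c(5, 1, -2); d2 <- c(-0.3, 1, 0.2)
  t1 <- triangulate(list(origin = o1, direction = d1),
                    list(origin = o2, direction = d2))
  t2 <- triangulate(list(origin = o2, direction = d2),
                    list(origin = o1, direction = d1))
  expect_equal(t1$e, t2$e, tolerance = 1e-12)
  expect_equal(t1$point, t2$point, tolerance = 1e-12)
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3, 3)
    Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, 3)
    R <- Rz %*% Rx; tt <- runif(3, -20, 20)
    tr <- triangulate(list(origin = R %*% o1 + tt, direction = R %*% d1),
                      list(origin = R %*% o2 + tt, direction = R %*% d2))
    expect_equal(tr$e, t1$e, tolerance = 1e-9)
    expect_equal(as.numeric(tr$point), as.numeric(R %*% t1$point + tt),
                 tolerance = 1e-9)
  }
  # midpoint sits on the common perpendicular: equidistant from both rays
  pt_dist_to_ray <- function(p, o, d) {
    d <- d / sqrt(sum(d^2))
    v <- p - o
    sqrt(sum((v - sum(v * d) * d)^2))
  }
  expect_equal(pt_dist_to_ray(t1$point, o1, d1),
               t1$e / 2, tolerance = 1e-12)
  expect_equal(pt_dist_to_ray(t1$point, o2, d2),
               t1$e / 2, tolerance = 1e-12)
})

test_that("parallel rays raise a degeneracy error", {
  expect_error(triangulate(list(origin = c(0, 0, 0), direction = c(1, 0, 0)),
                           list(origin = c(0, 1, 0), direction = c(1, 0, 0))),
               "parallel")
})

test_that("triangulating matches reproduces exact geometry on noiseless data", {
  rig <- make_rig()
  X <- rig_cloud(30, seed = 13)
  p1 <- project_points(rig[[1]], X)
  p2 <- project_points(rig[[2]], X)
  ms <- data.frame(index_i = 1:30, index_j = 1:30,
                   row_i = p1[, 2], row_j = p2[, 2], ssd = 0)
  attr(ms, "pair") <- c(1L, 2L)
  class(ms) <- c("match_set", "data.frame")
  tri <- triangulate_matches(ms, rig[1:2], points_i = p1, points_j = p2)
  expect_equal(nrow(tri), 30)
  expect_lt(max(tri$e), 1e-6)
  expect_lt(max(abs(as.matrix(tri[, c("x", "y", "z")]) - X)), 1e-6)
  # mean error increases once pixel noise corrupts the projections
  noiseless <- mean_triangulation_error(tri)
  noisy <- vapply(1:10, function(s) {
    set.seed(s)
    tri_n <- triangulate_matches(ms, rig[1:2],
                                 points_i = p1 + matrix(rnorm(60, sd = 0.5), ncol = 2),
                                 points_j = p2 + matrix(rnorm(60, sd = 0.5), ncol = 2))
    mean_triangulation_error(tri_n)
  }, numeric(1))
  expect_true(all(noisy > noiseless))
  # empty match set propagates to an empty triangulation set
  empty <- dermatrack:::empty_match_set(c(1L, 2L))
  expect_equal(nrow(triangulate_matches(empty, rig[1:2])), 0)
})

test_that("mean triangulation error is the arithmetic mean", {
  expect_equal(mean_triangulation_error(c(0.1, 0.3)), 0.2)
  expect_equal(mean_triangulation_error(rep(0.42, 7)), 0.42)
  set.seed(2)
  e <- runif(1000)
  expect_equal(mean_triangulation_error(e), sum(e) / 1000, tolerance = 1e-12)
  expect_error(mean_triangulation_error(numeric(0)), "empty")
})

test_that("pair selection maximizes vergence among admissible pairs", {
  rig <- make_rig()
  # forced choice: only cameras 1 and 3 see the region
  p <- select_pair(rig, c(0, 0, 0), visible = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.integer(p), c(1L, 3L))
  # all pairs admissible: diagonal pairs have the widest vergence angle
  p2 <- select_pair(rig, c(0, 0, 0), visible = rep(TRUE, 4))
  ang <- function(i, j) {
    v1 <- camera_center(rig[[i]]); v2 <- camera_center(rig[[j]])
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  best <- which.max(apply(camera_pairs(4), 1, function(pr) ang(pr[1], pr[2])))
  expect_equal(as.integer(p2), as.integer(camera_pairs(4)[best, ]))
  expect_equal(attr(p2, "angle"), ang(p2[1], p2[2]), tolerance = 1e-9)
  # a region outside every frustum errors
  expect_error(select_pair(rig, c(500, 500, 0), image_size = c(512, 384)),
               "no camera pair")
})
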