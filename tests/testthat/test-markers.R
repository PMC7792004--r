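test_that("segmentation thresholds separate markers and reject specks", {
  dark <- matrix(20, 30, 30)
  m0 <- segment_markers(dark, intensity_threshold = 128)
  expect_false(any(m0))
  img <- matrix(30, 40, 40)
  yy <- matrix(0:39, 40, 40); xx <- t(yy)
  disc <- (xx - 12)^2 + (yy - 12)^2 <= 25
  img[disc] <- 250
  m1 <- segment_markers(img, intensity_threshold = 128)
  expect_identical(unname(which(m1)), which(disc))
  # two discs plus salt noise specks, min_area filter
  img2 <- matrix(30, 48, 48)
  yy <- matrix(0:47, 48, 48); xx <- t(yy)
  d1 <- (xx - 12)^2 + (yy - 12)^2 <= 25
  d2 <- (xx - 35)^2 + (yy - 30)^2 <= 16
  img2[d1 | d2] <- 250
  set.seed(4)
  clear <- (xx - 12)^2 + (yy - 12)^2 > 49 & (xx - 35)^2 + (yy - 30)^2 > 49
  specks <- sample(which(clear), 15)
  img2[specks] <- 255
  m2 <- segment_markers(img2, intensity_threshold = 128, min_area = 5)
  lab <- attr(m2, "labels")
  expect_equal(max(lab), 2)
  # equals label-propagation oracle on the clean component structure
  orc <- oracle_label(d1 | d2)
  got <- split(which(m2), lab[m2])
  expect_setequal(unname(lapply(got, sort)), unname(lapply(orc, sort)))
})

test_that("marker detection returns one sub-pixel center per component", {
  img <- matrix(30, 64, 64)
  yy <- matrix(0:63, 64, 64); xx <- t(yy)
  img[(xx - 20.3)^2 + (yy - 33.6)^2 <= 36] <- 250
  mask <- segment_markers(img, intensity_threshold = 128)
  det <- detect_markers(img, mask)
  expect_equal(nrow(det), 1)
  expect_lt(sqrt((det$cx - 20.3)^2 + (det$cy - 33.6)^2), 0.5)
  # empty mask
  det0 <- detect_markers(img, segment_markers(matrix(0, 8, 8),
                                              intensity_threshold = 128))
  expect_equal(nrow(det0), 0)
  # 3x3 grid of discs: one detection each
  img3 <- matrix(30, 96, 96)
  yy <- matrix(0:95, 96, 96); xx <- t(yy)
  for (gx in c(16, 48, 80)) for (gy in c(16, 48, 80))
    img3[(xx - gx)^2 + (yy - gy)^2 <= 25] <- 250
  det3 <- detect_markers(img3, segment_markers(img3, intensity_threshold = 128))
  expect_equal(nrow(det3), 9)
  expect_equal(sort(round((det3$cx - 16) / 32)), rep(c(0, 1, 2), each = 3))
})

test_that("ground-truth comparison distances follow the definitions", {
  G <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  cmp <- compare_to_ground_truth(G, G)
  expect_equal(cmp$euclidean_distance, rep(0, 3))
  cmp2 <- compare_to_ground_truth(matrix(c(0.3, 0.4, 0), 1), matrix(0, 1, 3))
  expect_equal(cmp2$euclidean_distance, 0.5)
})

test_that("greedy assignment equals the exhaustive optimum for small n", {
  set.seed(12)
  for (k in 1:5) {
    n <- sample(3:6, 1)
    G <- cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, -2, 2))
    D <- G + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    D <- D[sample(n), , drop = FALSE]
    cmp <- compare_to_ground_truth(D, G, max_assign_dist = 2)
    orc <- oracle_assignment(D, G, cap = 2)
    expect_equal(nrow(cmp), length(orc$det))
    expect_setequal(paste(cmp$det_id, cmp$marker_id),
                    paste(orc$det, orc$gt))
  }
})

test_that("comparison distances are symmetric and rigid-invariant", {
  set.seed(3)
  G <- cbind(runif(5, 0, 30), runif(5, 0, 30), runif(5, -1, 1))
  D <- G + matrix(rnorm(15, sd = 0.2), 5, 3)
  d1 <- sort(compare_to_ground_truth(D, G)$euclidean_distance)
  d2 <- sort(compare_to_ground_truth(G, D)$euclidean_distance)
  expect_equal(d1, d2, tolerance = 1e-12)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(4, -7, 2)
  d3 <- sort(compare_to_ground_truth(D %*% t(R) + matrix(shift, 5, 3, byrow = TRUE),
                                     G %*% t(R) + matrix(shift, 5, 3, byrow = TRUE)
                                     )$euclidean_distance)
  expect_equal(d3, d1, tolerance = 1e-9)
})
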