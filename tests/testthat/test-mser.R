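test_that("constant images yield no extremal regions", {
  expect_equal(nrow(detect_mser(matrix(100, 20, 20))), 0)
})

test_that("a single dark disc is found at its center, matching the sweep oracle", {
  img <- disc_image(size = c(32, 32), center = c(16, 16), radius = 6,
                    fg = 40, bg = 200)
  ens <- detect_mser(img, max_area = 300, region_pixels = TRUE)
  dark <- ens[ens$polarity == "dark", ]
  expect_equal(nrow(dark), 1)
  expect_lt(sqrt((dark$x - 16)^2 + (dark$y - 16)^2), 0.5)
  expect_equal(dark$scale, sqrt(dark$area / pi))
  orc <- oracle_mser(img, max_area = 300)
  expect_identical(detect_signature(ens), mser_signature(orc))
})

test_that("nested concentric discs give co-located regions at both scales", {
  img <- matrix(200, 32, 32)
  yy <- matrix(0:31, 32, 32); xx <- t(yy)
  img[(xx - 16)^2 + (yy - 16)^2 <= 64] <- 120  # outer, r = 8
  img[(xx - 16)^2 + (yy - 16)^2 <= 16] <- 40   # inner, r = 4
  ens <- detect_mser(img, max_area = 400, region_pixels = TRUE)
  dark <- ens[ens$polarity == "dark", ]
  expect_gte(nrow(dark), 2)
  d <- sqrt((dark$x - 16)^2 + (dark$y - 16)^2)
  expect_true(all(d < 0.5))
  expect_identical(detect_signature(ens), mser_signature(oracle_mser(img, max_area = 400)))
})

test_that("MSER equals the exhaustive threshold-sweep oracle on random images", {
  # randomized suite; smoothed noise keeps a nontrivial region structure
  for (s in 1:20) {
    set.seed(s)
    h <- sample(12:24, 1); w <- sample(12:24, 1)
    img <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    if (s %% 2 == 0) {  # alternate: smoothed images with larger regions
      k <- matrix(1 / 9, 3, 3)
      pad <- rbind(img[1, ], img, img[h, ])
      pad <- cbind(pad[, 1], pad, pad[, w])
      sm <- matrix(0, h, w)
      for (r in 1:h) for (cc in 1:w)
        sm[r, cc] <- sum(pad[r:(r + 2), cc:(cc + 2)] * k)
      img <- round(sm)
    }
    prm <- list(delta = sample(1:3, 1), min_area = sample(c(3, 5, 10), 1),
                max_area = round(0.5 * h * w), max_variation = sample(c(0.25, 0.5, 1), 1))
    ens <- detect_mser(img, delta = prm$delta, min_area = prm$min_area,
                       max_area = prm$max_area, max_variation = prm$max_variation,
                       region_pixels = TRUE)
    orc <- oracle_mser(img, delta = prm$delta, min_area = prm$min_area,
                       max_area = prm$max_area, max_variation = prm$max_variation)
    expect_identical(detect_signature(ens), mser_signature(orc))
  }
})

test_that("ensembles are deterministically ordered and ROI-aware", {
  img <- matrix(200, 40, 60)
  yy <- matrix(0:39, 40, 60); xx <- matrix(0:59, 40, 60, byrow = TRUE)
  img[(xx - 15)^2 + (yy - 10)^2 <= 16] <- 50
  img[(xx - 45)^2 + (yy - 30)^2 <= 16] <- 50
  ens <- detect_mser(img, max_area = 200)
  expect_equal(ens$index, seq_len(nrow(ens)))
  expect_true(!is.unsorted(ens$y))
  # ROI restricted to the first blob only
  roi_ens <- detect_mser(img, roi = c(0, 0, 30, 20), max_area = 200)
  expect_true(all(roi_ens$x < 30))
  expect_gte(nrow(roi_ens), 1)
  # empty ROI is an empty ensemble, not an error
  expect_equal(nrow(detect_mser(img, roi = c(0, 0, 0, 0))), 0)
})
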