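test_that("Gaussian encoding writes unit peaks with the closed-form profile", {
  hm <- encodeHeatmap(data.frame(x = numeric(0), y = numeric(0)), 16, 16)
  expect_equal(heatmapValues(hm), matrix(0, 16, 16))

  hm <- encodeHeatmap(data.frame(x = 5, y = 5), 16, 16, sigma = 1)
  v <- heatmapValues(hm)
  expect_identical(v[6, 6], 1)                     # 0-based (5,5)
  expect_equal(v[6, 7], exp(-0.5))                 # one pixel right
  expect_equal(v[7, 7], exp(-1))                   # diagonal neighbour
  expect_equal(v[6, 10], 0)                        # beyond 3-sigma truncation

  # overlapping bumps combine by max: both annotated pixels stay exactly 1
  hm2 <- encodeHeatmap(data.frame(x = c(5, 6), y = c(5, 5)), 16, 16)
  v2 <- heatmapValues(hm2)
  expect_identical(v2[6, 6], 1)
  expect_identical(v2[6, 7], 1)
  expect_true(max(v2) <= 1)
})

test_that("encoding is permutation-invariant and validates its inputs", {
  set.seed(31)
  pts <- data.frame(x = runif(20, 0, 31), y = runif(20, 0, 31))
  a <- encodeHeatmap(pts, 32, 32)
  b <- encodeHeatmap(pts[sample(20), ], 32, 32)
  expect_equal(heatmapValues(a), heatmapValues(b))

  expect_error(encodeHeatmap(data.frame(x = 40, y = 5), 32, 32), "outside")
  expect_error(encodeHeatmap(data.frame(x = 5, y = -1), 32, 32), "outside")
  expect_error(encodeHeatmap(data.frame(x = 5, y = 5), 0, 32), "positive")
  expect_error(encodeHeatmap(data.frame(x = 5, y = 5), 32, 32, sigma = 0))
  expect_error(encodeHeatmap(data.frame(x = 5, y = 5), 32, 32,
                             truncationRadius = 1), "truncationRadius")
})

test_that("peak decoding returns exactly the thresholded local maxima", {
  expect_identical(keypointCount(decodePeaks(matrix(0, 8, 8))), 0L)

  m <- matrix(0, 8, 8); m[4, 5] <- 0.9              # 0-based (3, 4)
  res <- decodePeaks(m, threshold = 0.5)
  expect_identical(keypointCount(res), 1L)
  expect_equal(detections(res), data.frame(row = 3L, col = 4L, score = 0.9))

  # equal-valued plateau within one window: both points are kept
  p <- matrix(0, 10, 10); p[6, 6] <- 0.8; p[6, 7] <- 0.8
  res <- decodePeaks(p, threshold = 0.5)
  expect_identical(keypointCount(res), 2L)
  expect_setequal(paste(detections(res)$row, detections(res)$col),
                  c("5 5", "5 6"))

  expect_error(decodePeaks(m, windowSize = 4L), "odd")
  expect_error(decodePeaks(m, threshold = 1.5), "threshold")
  expect_error(decodePeaks(matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("decoding agrees with the brute-force neighbourhood scan", {
  set.seed(202)
  for (i in 1:10) {
    v <- random_heatmap(32, 32)
    for (win in c(3L, 5L)) {
      got <- detections(decodePeaks(v, windowSize = win, threshold = 0.5))
      want <- brute_force_peaks(v, windowSize = win, threshold = 0.5)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("raising the threshold never adds detections", {
  set.seed(77)
  v <- random_heatmap(40, 40)
  counts <- vapply(seq(0.1, 0.9, by = 0.1), function(th)
    keypointCount(decodePeaks(v, threshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("well-separated points survive the encode/decode round trip exactly", {
  res <- heatmapRoundTrip(data.frame(x = c(10, 20), y = c(10, 20)), 64, 64)
  d <- detections(res)
  expect_identical(keypointCount(res), 2L)
  expect_equal(d$row, c(10, 20))
  expect_equal(d$col, c(10, 20))
  expect_equal(d$score, c(1, 1))

  expect_identical(keypointCount(heatmapRoundTrip(
    data.frame(x = numeric(0), y = numeric(0)), 32, 32)), 0L)

  set.seed(12)
  pts <- separated_points(30, 128, 128, sep = 8)
  res <- heatmapRoundTrip(pts, 128, 128)
  expect_identical(keypointCount(res), 30L)
  d <- detections(res)
  expect_setequal(paste(d$col, d$row), paste(pts$x, pts$y))
  expect_true(all(d$score == 1))
})

test_that("downsampling quantisation error is bounded by factor - 1", {
  expect_identical(quantizedCoordError(517, 4), 1)
  expect_identical(quantizedCoordError(512, 4), 0)
  expect_true(max(quantizedCoordError(0:1023, 4)) <= 3)
  for (f in c(2, 3, 4, 8)) {
    expect_true(all(quantizedCoordError(0:500, f) < f))
  }
  expect_error(quantizedCoordError(5, 0), "factor")
})

test_that("heatmap containers validate and serialise", {
  expect_error(keypointHeatmap(matrix(c(0.5, 1.2), 1, 2)), "\\[0, 1\\]")
  hm <- encodeHeatmap(data.frame(x = 3, y = 4), 12, 12)
  path <- tempfile(fileext = ".csv")
  writeHeatmap(hm, path)
  expect_equal(heatmapValues(readHeatmap(path)), heatmapValues(hm),
               ignore_attr = TRUE)
  png_path <- tempfile(fileext = ".png")
  writeHeatmap(hm, png_path)
  expect_true(file.exists(png_path))

  res <- decodePeaks(hm)
  csv <- tempfile(fileext = ".csv")
  writeCountResult(res, csv)
  expect_equal(read.csv(csv)$row, detections(res)$row)
  js <- tempfile(fileext = ".json")
  writeCountResult(res, js)
  expect_equal(jsonlite::fromJSON(js)$count, 1L)
})
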