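labelme_fixture <- function(shapes, path = tempfile(fileext = ".json")) {
  doc <- list(version = "5.0.0", shapes = shapes, imagePath = "img.png",
              imageHeight = 64, imageWidth = 64)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  path
}

point_shape <- function(x, y, label = "fry")
  list(label = label, points = list(c(x, y)), shape_type = "point")

test_that("Labelme point shapes parse with stored coordinates", {
  path <- labelme_fixture(list(point_shape(3.5, 7.25), point_shape(10, 20),
                               point_shape(0, 0)))
  pts <- readLabelmePoints(path)
  expect_identical(nrow(pts), 3L)
  expect_equal(pts$x, c(3.5, 10, 0))
  expect_equal(pts$y, c(7.25, 20, 0))
  expect_identical(attr(pts, "skipped"), 0L)

  empty <- readLabelmePoints(labelme_fixture(list()))
  expect_identical(nrow(empty), 0L)
})

test_that("non-point shapes are skipped with a warning count", {
  poly <- list(label = "blob",
               points = list(c(1, 2), c(3, 4), c(5, 6)),
               shape_type = "polygon")
  path <- labelme_fixture(list(point_shape(1, 1), poly, point_shape(2, 2)))
  expect_warning(pts <- readLabelmePoints(path), "skipped 1")
  expect_identical(nrow(pts), 2L)
  expect_identical(attr(pts, "skipped"), 1L)
})

test_that("malformed documents are rejected", {
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(readLabelmePoints(bad))
  noshapes <- tempfile(fileext = ".json")
  jsonlite::write_json(list(imageHeight = 4), noshapes, auto_unbox = TRUE)
  expect_error(readLabelmePoints(noshapes), "shapes")
})

test_that("write/read of Labelme points is the identity on point sets", {
  pts <- data.frame(x = c(0.5, 10.25, 63), y = c(1, 2.75, 63),
                    label = c("a", "b", "c"))
  path <- tempfile(fileext = ".json")
  writeLabelmePoints(pts, path, imageHeight = 64, imageWidth = 64)
  back <- readLabelmePoints(path)
  expect_equal(back$x, pts$x)
  expect_equal(back$y, pts$y)
  expect_identical(back$label, pts$label)
})

test_that("the reference manifest reproduces the published batch totals", {
  m <- referenceFryManifest()
  expect_identical(nrow(m@images), 200L)
  expect_equal(manifestInstanceTotal(m), 137390)
  expect_equal(manifestInstanceTotal(m, "train"), 103840)
  expect_equal(manifestInstanceTotal(m, "val"), 33550)
  # splits partition consistently: train + val covers all annotated images
  expect_equal(manifestInstanceTotal(m, "train") + manifestInstanceTotal(m, "val"),
               manifestInstanceTotal(m))
  expect_length(intersect(m@splits$train, m@splits$val), 0)
  # per-batch instance totals as annotated
  per_batch <- tapply(m@images$count, m@images$batch_id, sum)
  expect_equal(as.numeric(per_batch[as.character(1:8)]),
               c(9180, 19710, 2955, 28890, 3560, 4380, 59040, 9675))
  expect_error(manifestInstanceTotal(m, "test"), "unknown split")
})

test_that("manifests survive the YAML round trip and enforce invariants", {
  m <- referenceFryManifest()
  path <- tempfile(fileext = ".yaml")
  writeManifest(m, path)
  back <- readManifest(path)
  expect_equal(manifestInstanceTotal(back), manifestInstanceTotal(m))
  expect_setequal(back@splits$train, m@splits$train)

  bad <- data.frame(batch_id = c(1, 1), density = "low", count = c(5, 6),
                    n_images = 1,
                    image_ids = I(list("a", "b")))
  expect_error(datasetManifest(bad), "share")
})

test_that("resize maps points with the image and inverts exactly", {
  img <- array(runif(40 * 30 * 3), c(40, 30, 3))
  pts <- data.frame(x = c(0, 29, 12.5), y = c(0, 39, 7))
  same <- resizeWithPoints(img, pts, 40, 30)
  expect_equal(same$points$x, pts$x)
  expect_equal(dim(same$image), dim(img))

  # corner-to-corner: the far corner of a 3024x4032 frame lands within the
  # last pixel of the 1024x1024 target
  big_pts <- data.frame(x = 4031, y = 3023)
  tr <- frycount:::resize_transform(1024 / 4032, 1024 / 3024)
  mapped <- tr$forward(big_pts)
  expect_true(mapped$x >= 1023 - 1 && mapped$x < 1024)
  expect_true(mapped$y >= 1023 - 1 && mapped$y < 1024)

  set.seed(13)
  down <- resizeWithPoints(img, pts, 13, 57)
  rt <- down$transform$inverse(down$transform$forward(pts))
  expect_lt(max(abs(rt$x - pts$x)), 1e-6)
  expect_lt(max(abs(rt$y - pts$y)), 1e-6)
  expect_equal(dim(down$image)[1:2], c(13, 57))
  expect_error(resizeWithPoints(img, pts, 0, 10), "positive")
})

test_that("overlay PNGs mark every detection", {
  img <- array(0.2, c(16, 16, 3))
  res <- decodePeaks({
    m <- matrix(0, 16, 16); m[5, 9] <- 1; m
  })
  path <- tempfile(fileext = ".png")
  writeOverlayPNG(img, res, path)
  back <- png::readPNG(path)
  expect_equal(back[5, 9, 2], 1)   # green marker at the detection
})
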