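test_that("heatmap loss follows the per-value mean-squared-error definition", {
  a <- matrix(runif(64), 8, 8)
  expect_identical(mseHeatmapLoss(a, a), 0)

  target <- matrix(0, 8, 8); target[3, 4] <- 1
  pred <- matrix(0, 8, 8)
  expect_equal(mseHeatmapLoss(pred, target), 1 / 64)        # one unit residual over N values
  expect_equal(mseHeatmapLoss(pred, target, lambdaFactor = 2),
               2 * mseHeatmapLoss(pred, target))

  expect_error(mseHeatmapLoss(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
  expect_error(mseHeatmapLoss(a, a, lambdaFactor = 0), "lambda")
})

test_that("the milestone schedule drops the rate at epochs 20 and 60", {
  expect_equal(lrAtEpoch(0), 1.5e-3)
  expect_equal(lrAtEpoch(19), 1.5e-3)
  expect_equal(lrAtEpoch(20), 1.5e-4)
  expect_equal(lrAtEpoch(59), 1.5e-4)
  expect_equal(lrAtEpoch(60), 1.5e-5)
  expect_equal(lrAtEpoch(400), 1.5e-5)
  expect_error(lrAtEpoch(5, milestones = list(c(20, 2e-3))), "decrease")
})

test_that("degenerate augmentation is the identity and flips mirror exactly", {
  set.seed(20)
  img <- array(runif(32 * 1024 * 3), c(32, 1024, 3))
  pts <- data.frame(x = c(0, 17, 1023), y = c(3, 10, 20))
  id_cfg <- augmentationConfig(horizontalFlipProb = 0,
                               scaleRange = c(1, 1),
                               rotationRangeDeg = c(0, 0))
  out <- augmentSample(img, pts, id_cfg)
  expect_identical(out$image, img)
  expect_equal(out$points$x, pts$x)

  flip_cfg <- augmentationConfig(horizontalFlipProb = 1,
                                 scaleRange = c(1, 1),
                                 rotationRangeDeg = c(0, 0))
  out <- augmentSample(img, pts, flip_cfg)
  expect_equal(out$points$x, 1023 - pts$x)
  expect_equal(out$points$y, pts$y)
  expect_identical(out$image[, 1024:1, ], img)
})

test_that("rotation can push a corner point off the canvas, which drops it", {
  H <- 64; W <- 64
  img <- array(0.5, c(H, W, 3))
  # corner point plus a safely central point; rotate by exactly 30 degrees
  pts <- data.frame(x = c(62, 32), y = c(1, 32))
  cfg <- augmentationConfig(horizontalFlipProb = 0, scaleRange = c(1, 1),
                            rotationRangeDeg = c(30, 30))
  # oracle: apply the same affine arithmetic directly
  ang <- 30 * pi / 180
  A <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  q <- t(A %*% (t(as.matrix(pts)) - ctr) + ctr)
  inside <- round(q[, 1]) >= 0 & round(q[, 1]) <= W - 1 &
            round(q[, 2]) >= 0 & round(q[, 2]) <= H - 1
  expect_identical(inside, c(FALSE, TRUE))   # the corner leaves the canvas

  set.seed(4)
  out <- augmentSample(img, pts, cfg)
  expect_identical(nrow(out$points), 1L)
  expect_equal(out$points$x, q[2, 1], tolerance = 1e-6)
  expect_equal(out$points$y, q[2, 2], tolerance = 1e-6)
})

test_that("image and points undergo the same transform (marker relocation)", {
  set.seed(21)
  H <- 64; W <- 64
  img <- array(0, c(H, W, 3))
  p <- data.frame(x = 40, y = 22)
  img[p$y + 1, p$x + 1, ] <- 1       # render a bright marker at the point
  cfg <- augmentationConfig(horizontalFlipProb = 0,
                            scaleRange = c(1.2, 1.2),
                            rotationRangeDeg = c(15, 15))
  out <- augmentSample(img, p, cfg)
  expect_identical(nrow(out$points), 1L)
  hit <- which(out$image[, , 2] == max(out$image[, , 2]), arr.ind = TRUE)[1, ]
  expect_lt(abs(hit["row"] - 1 - out$points$y), 1.5)
  expect_lt(abs(hit["col"] - 1 - out$points$x), 1.5)
})

test_that("a tiny training run is finite, logged and reproducible", {
  scenes <- lapply(1:2, function(i)
    renderScene(sceneConfig(imageSize = c(32L, 32L), nObjects = 4L,
                            lengthRange = c(6, 9), widthRange = c(2, 3),
                            minSeparation = 6, seed = i)))
  run <- function() {
    net <- buildModel(tiny_config(), seed = 5)
    trainModel(net, scenes, epochs = 2L, batchSize = 2L, augment = NULL,
               inputSize = c(32L, 32L), seed = 3, verbose = FALSE)
  }
  fit <- run()
  expect_identical(nrow(fit$log), 2L)
  expect_identical(fit$log$epoch, c(0L, 1L))
  expect_true(all(is.finite(fit$log$mean_loss)))
  expect_true(all(fit$log$mean_loss > 0))
  expect_equal(fit$log$lr, c(1.5e-3, 1.5e-3))

  fit2 <- run()
  expect_identical(fit$log$mean_loss, fit2$log$mean_loss)

  expect_error(trainModel(buildModel(tiny_config(), seed = 5), list()),
               "empty")
})

test_that("validation tracking restores the best-MAE weights", {
  scenes <- lapply(1:2, function(i)
    renderScene(sceneConfig(imageSize = c(32L, 32L), nObjects = 3L,
                            lengthRange = c(6, 9), widthRange = c(2, 3),
                            minSeparation = 6, seed = 10 + i)))
  net <- buildModel(tiny_config(), seed = 6)
  fit <- trainModel(net, scenes, valSamples = scenes, epochs = 2L,
                    batchSize = 2L, augment = NULL, inputSize = c(32L, 32L),
                    seed = 3)
  expect_true(all(is.finite(fit$log$val_mae)))
  log_path <- tempfile(fileext = ".csv")
  writeTrainLog(fit$log, log_path)
  expect_identical(nrow(read.csv(log_path)), 2L)
})
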