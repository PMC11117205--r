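fc <- asNamespace("frycount")

# closed-form parameter count assembled independently from the layer shapes
# (convs carry no bias except the final 1x1; batch norm has scale + shift)
expected_param_count <- function(stem = 64, blocks = 4, s1out = 256,
                                 c1 = 48, c2 = 96, stages = 3, hc = 48,
                                 head = "TDM") {
  bn <- function(c) 2 * c
  conv <- function(cin, k, cout) cin * k * k * cout
  mid <- s1out / 4
  stem_p <- conv(3, 3, stem) + bn(stem) + conv(stem, 3, stem) + bn(stem)
  bottleneck <- function(cin) {
    p <- conv(cin, 1, mid) + bn(mid) + conv(mid, 3, mid) + bn(mid) +
      conv(mid, 1, s1out) + bn(s1out)
    if (cin != s1out) p <- p + conv(cin, 1, s1out) + bn(s1out)
    p
  }
  s1_p <- bottleneck(stem) + (blocks - 1) * bottleneck(s1out)
  trans_p <- conv(s1out, 3, c1) + bn(c1) + conv(s1out, 3, c2) + bn(c2)
  basic <- function(c) 2 * (conv(c, 3, c) + bn(c))
  fuse_up <- conv(c2, 1, c1) + bn(c1)
  fuse_down <- conv(c1, 3, c2) + bn(c2)
  stage_p <- stages * (4 * basic(c1) + 4 * basic(c2) + fuse_up) +
    (stages - 1) * fuse_down
  head_p <- switch(head,
    NONE = 0,
    ODM1 = conv(hc, 4, c1) + bn(hc),
    ODM2 = conv(hc, 4, c1) + bn(hc),
    TDM  = conv(hc, 4, c1) + bn(hc) + conv(hc, 4, hc) + bn(hc))
  final_in <- if (head == "NONE") c1 else hc
  stem_p + s1_p + trans_p + stage_p + head_p + (final_in + 1)
}

test_that("the default architecture has the published 3.32M parameter budget", {
  net <- buildModel(modelConfig(), seed = 1)
  n <- countParameters(net)
  expect_identical(n, expected_param_count())
  expect_equal(round(n / 1e6, 2), 3.32)
})

test_that("head-only parameters match the closed-form layer-shape sum", {
  tdm <- countParameters(buildModel(modelConfig(headVariant = "TDM"), seed = 1))
  none <- countParameters(buildModel(modelConfig(headVariant = "NONE"), seed = 1))
  # two 4x4 48->48 transposed convs + their batch norms (the final 1x1 conv
  # is present in both variants)
  expect_identical(tdm - none, 2 * (4 * 4 * 48 * 48 + 2 * 48))
})

test_that("parameter count grows with width and depth but not input size", {
  base <- countParameters(buildModel(tiny_config(), seed = 1))
  wider <- tiny_config(); wider@branch1Channels <- 8L; wider@branch2Channels <- 16L
  deeper <- tiny_config(); deeper@dualStages <- 2L
  taller <- tiny_config(); taller@stage1Blocks <- 2L
  bigger_input <- tiny_config(inputSize = c(64L, 64L))
  expect_gt(countParameters(buildModel(wider, seed = 1)), base)
  expect_gt(countParameters(buildModel(deeper, seed = 1)), base)
  expect_gt(countParameters(buildModel(taller, seed = 1)), base)
  expect_identical(countParameters(buildModel(bigger_input, seed = 1)), base)

  half <- countParameters(buildModel(modelConfig(branch1Channels = 24L,
                                                 headChannels = 24L), seed = 1))
  expect_lt(half, countParameters(buildModel(modelConfig(), seed = 1)))
})

test_that("each head variant produces its documented output resolution", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  sizes <- list(NONE = 16L, ODM1 = 32L, ODM2 = 64L, TDM = 64L)
  for (hv in names(sizes)) {
    net <- buildModel(tiny_config(hv, inputSize = c(64L, 64L)), seed = 2)
    hm <- predictHeatmap(net, img)
    expect_identical(dim(hm), c(sizes[[hv]], sizes[[hv]]))
    v <- heatmapValues(hm)
    expect_true(min(v) >= 0 && max(v) <= 1)
  }
})

test_that("the dual branches run at 1/4 and 1/8 of the input resolution", {
  net <- buildModel(tiny_config(inputSize = c(64L, 64L)), seed = 3)
  s <- net@state
  x <- fc$vnode(array(runif(3 * 64 * 64), c(3L, 64L, 64L, 1L)))
  y <- fc$op_relu(NULL, fc$op_bn(NULL, fc$op_conv(NULL, x, s$stem$c1), s$stem$n1, FALSE))
  y <- fc$op_relu(NULL, fc$op_bn(NULL, fc$op_conv(NULL, y, s$stem$c2), s$stem$n2, FALSE))
  for (b in s$stage1) y <- fc$fwd_bottleneck(NULL, y, b, FALSE)
  b1 <- fc$op_conv(NULL, y, s$trans$t1)
  b2 <- fc$op_conv(NULL, y, s$trans$t2)
  expect_equal(dim(b1$v)[2:3], c(16L, 16L))   # input / 4
  expect_equal(dim(b2$v)[2:3], c(8L, 8L))     # input / 8
})

test_that("forward pass is deterministic, bounded and validates input size", {
  net <- buildModel(tiny_config(), seed = 4)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  a <- predictHeatmap(net, img)
  b <- predictHeatmap(net, img)
  expect_identical(heatmapValues(a), heatmapValues(b))

  net2 <- buildModel(tiny_config(), seed = 4)
  expect_identical(heatmapValues(predictHeatmap(net2, img)), heatmapValues(a))

  expect_error(predictHeatmap(net, array(runif(30 * 32 * 3), c(30, 32, 3))),
               "divisible by 8")
  expect_error(modelConfig(branch2Channels = 50L), "twice")
})

test_that("checkpoints restore forward passes exactly", {
  net <- buildModel(tiny_config(), seed = 9)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  before <- heatmapValues(predictHeatmap(net, img))
  path <- tempfile(fileext = ".rds")
  saveModel(net, path)
  restored <- loadModel(path)
  expect_identical(heatmapValues(predictHeatmap(restored, img)), before)
  expect_identical(restored@config@headVariant, "TDM")
})
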