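#' Create a network architecture configuration
#'
#' Defaults reproduce the published fry-counting architecture (about 3.32
#' million trainable parameters): a two-convolution stride-4 stem at 64
#' channels, four bottleneck residual blocks expanding to 256 channels, a
#' 48-channel 1/4-resolution branch running in parallel with a 96-channel
#' 1/8-resolution branch over three stages of four basic residual blocks
#' each with additive cross-branch fusion, and a head of two 4x4 stride-2
#' transposed convolutions (`"TDM"`) restoring full input resolution before
#' the 1x1 convolution + sigmoid that emits the single-channel heatmap.
#'
#' @param stemChannels,stage1Blocks,stage1OutChannels,branch1Channels,dualStages,headChannels
#'   architecture sizes, see [ModelConfig-class].
#' @param branch2Channels must equal `2 * branch1Channels` (the second
#'   branch doubles the channels as it halves the resolution).
#' @param headVariant `"NONE"`, `"ODM1"`, `"ODM2"` or `"TDM"`.
#' @param inputSize default (height, width) for training and prediction.
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(stemChannels = 64L, stage1Blocks = 4L,
                        stage1OutChannels = 256L, branch1Channels = 48L,
                        branch2Channels = 2L * branch1Channels,
                        dualStages = 3L, headVariant = "TDM",
                        headChannels = 48L, inputSize = c(1024L, 1024L)) {
  new("ModelConfig",
      stemChannels = as.integer(stemChannels),
      stage1Blocks = as.integer(stage1Blocks),
      stage1OutChannels = as.integer(stage1OutChannels),
      branch1Channels = as.integer(branch1Channels),
      branch2Channels = as.integer(branch2Channels),
      dualStages = as.integer(dualStages),
      headVariant = headVariant,
      headChannels = as.integer(headChannels),
      inputSize = as.integer(inputSize))
}

#' Desk-scale reduced configuration
#'
#' A narrow variant of the architecture (16/32-channel branches, two
#' bottlenecks to 64 channels, a single dual-branch stage, 16-channel head)
#' sized so that training on a few hundred 160x160 synthetic scenes runs in
#' minutes on one CPU core while exercising every architectural element of
#' the full model.
#'
#' @param headVariant head variant, default `"TDM"`.
#' @param inputSize default input size, (160, 160).
#' @return A [ModelConfig-class].
#' @export
reducedModelConfig <- function(headVariant = "TDM", inputSize = c(160L, 160L)) {
  modelConfig(stemChannels = 16L, stage1Blocks = 2L, stage1OutChannels = 64L,
              branch1Channels = 16L, dualStages = 1L,
              headVariant = headVariant, headChannels = 16L,
              inputSize = inputSize)
}

# output stride of the heatmap relative to the input, per head variant
head_stride <- function(headVariant) {
  switch(headVariant, NONE = 4L, ODM1 = 2L, ODM2 = 1L, TDM = 1L,
         stop("unknown head variant"))
}

mk_basic_block <- function(c) {
  list(c1 = mk_conv(c, c, 3L), n1 = mk_bn(c),
       c2 = mk_conv(c, c, 3L), n2 = mk_bn(c))
}

mk_bottleneck <- function(cin, cmid, cout) {
  b <- list(c1 = mk_conv(cin, cmid, 1L), n1 = mk_bn(cmid),
            c2 = mk_conv(cmid, cmid, 3L), n2 = mk_bn(cmid),
            c3 = mk_conv(cmid, cout, 1L), n3 = mk_bn(cout))
  if (cin != cout) {
    b$down <- mk_conv(cin, cout, 1L); b$ndown <- mk_bn(cout)
  }
  b
}

#' Build the keypoint-counting network
#'
#' Instantiates all layers of the configured architecture with fan-in-scaled
#' random initial weights. The final 1x1 convolution starts with small
#' weights and a negative bias so the initial heatmap is close to the empty
#' background, which stabilises the first training steps of the very sparse
#' regression target.
#'
#' @param config a [ModelConfig-class] (default: the full published
#'   architecture).
#' @param seed optional integer; when given, initialisation is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A [KeypointCountNet-class].
#' @examples
#' net <- buildModel(reducedModelConfig(), seed = 1)
#' countParameters(net)
#' @export
buildModel <- function(config = modelConfig(), seed = NULL) {
  validObject(config)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  s <- new.env(parent = emptyenv())
  ch_stem <- config@stemChannels
  c1 <- config@branch1Channels; c2 <- config@branch2Channels
  c_s1 <- config@stage1OutChannels
  c_mid <- max(1L, c_s1 %/% 4L)   # bottleneck expansion factor 4

  s$stem <- list(c1 = mk_conv(3L, ch_stem, 3L, stride = 2L), n1 = mk_bn(ch_stem),
                 c2 = mk_conv(ch_stem, ch_stem, 3L, stride = 2L), n2 = mk_bn(ch_stem))
  s$stage1 <- lapply(seq_len(config@stage1Blocks), function(i)
    mk_bottleneck(if (i == 1L) ch_stem else c_s1, c_mid, c_s1))
  s$trans <- list(t1 = mk_conv(c_s1, c1, 3L), tn1 = mk_bn(c1),
                  t2 = mk_conv(c_s1, c2, 3L, stride = 2L), tn2 = mk_bn(c2))
  s$stages <- lapply(seq_len(config@dualStages), function(r) {
    st <- list(b1 = lapply(1:4, function(i) mk_basic_block(c1)),
               b2 = lapply(1:4, function(i) mk_basic_block(c2)),
               up = mk_conv(c2, c1, 1L), upn = mk_bn(c1))
    if (r < config@dualStages) {
      st$down <- mk_conv(c1, c2, 3L, stride = 2L); st$downn <- mk_bn(c2)
    }
    st
  })
  hc <- config@headChannels
  s$head <- switch(config@headVariant,
    NONE = list(deconvs = list()),
    ODM1 = list(deconvs = list(list(d = mk_deconv(c1, hc, 4L, 2L, 1L), n = mk_bn(hc)))),
    ODM2 = list(deconvs = list(list(d = mk_deconv(c1, hc, 4L, 4L, 0L), n = mk_bn(hc)))),
    TDM  = list(deconvs = list(list(d = mk_deconv(c1, hc, 4L, 2L, 1L), n = mk_bn(hc)),
                               list(d = mk_deconv(hc, hc, 4L, 2L, 1L), n = mk_bn(hc)))))
  cfin <- if (config@headVariant == "NONE") c1 else hc
  # bias -4.6: initial heatmap ~ sigmoid(-4.6) = 0.01, i.e. near-empty
  s$head$final <- mk_conv(cfin, 1L, 1L, bias = TRUE, w_sd = 0.01)
  s$head$final$b$w[] <- -4.6

  s$params <- collect_params(s)
  new("KeypointCountNet", config = config, state = s)
}

collect_params <- function(s) {
  out <- list()
  layers <- list()
  grab <- function(x) {
    if (is.environment(x) && !is.null(x$type)) {
      layers[[length(layers) + 1L]] <<- x
    } else if (is.list(x)) lapply(x, grab)
    invisible(NULL)
  }
  grab(list(s$stem, s$stage1, s$trans, s$stages, s$head))
  for (l in layers) for (p in layer_params(l)) out[[length(out) + 1L]] <- p
  out
}

fwd_basic_block <- function(tape, x, b, train) {
  y <- op_relu(tape, op_bn(tape, op_conv(tape, x, b$c1), b$n1, train))
  y <- op_bn(tape, op_conv(tape, y, b$c2), b$n2, train)
  op_relu(tape, op_add(tape, y, x))
}

fwd_bottleneck <- function(tape, x, b, train) {
  y <- op_relu(tape, op_bn(tape, op_conv(tape, x, b$c1), b$n1, train))
  y <- op_relu(tape, op_bn(tape, op_conv(tape, y, b$c2), b$n2, train))
  y <- op_bn(tape, op_conv(tape, y, b$c3), b$n3, train)
  sc <- if (is.null(b$down)) x else
    op_bn(tape, op_conv(tape, x, b$down), b$ndown, train)
  op_relu(tape, op_add(tape, y, sc))
}

# full forward pass; x is a vnode holding [3, H, W, N]
fwd_net <- function(model, x, tape = NULL, train = FALSE) {
  s <- model@state
  d <- dim(x$v)
  if (d[2] %% 8L != 0L || d[3] %% 8L != 0L)
    stop(sprintf("input height and width must be divisible by 8, got %dx%d",
                 d[2], d[3]))
  y <- op_relu(tape, op_bn(tape, op_conv(tape, x, s$stem$c1), s$stem$n1, train))
  y <- op_relu(tape, op_bn(tape, op_conv(tape, y, s$stem$c2), s$stem$n2, train))
  for (b in s$stage1) y <- fwd_bottleneck(tape, y, b, train)
  b1 <- op_relu(tape, op_bn(tape, op_conv(tape, y, s$trans$t1), s$trans$tn1, train))
  b2 <- op_relu(tape, op_bn(tape, op_conv(tape, y, s$trans$t2), s$trans$tn2, train))
  for (st in s$stages) {
    for (bb in st$b1) b1 <- fwd_basic_block(tape, b1, bb, train)
    for (bb in st$b2) b2 <- fwd_basic_block(tape, b2, bb, train)
    up <- op_upsample2(tape, op_bn(tape, op_conv(tape, b2, st$up), st$upn, train))
    nb1 <- op_relu(tape, op_add(tape, b1, up))
    if (!is.null(st$down)) {
      dn <- op_bn(tape, op_conv(tape, b1, st$down), st$downn, train)
      b2 <- op_relu(tape, op_add(tape, b2, dn))
    }
    b1 <- nb1
  }
  h <- b1
  for (dc in s$head$deconvs)
    h <- op_relu(tape, op_bn(tape, op_deconv(tape, h, dc$d), dc$n, train))
  op_sigmoid(tape, op_conv(tape, h, s$head$final))
}

#' @describeIn countParameters total trainable scalars of a built network
#' @export
setMethod("countParameters", "KeypointCountNet", function(model) {
  sum(vapply(model@state$params, function(p) length(p$w), numeric(1)))
})

setMethod("show", "KeypointCountNet", function(object) {
  cfg <- object@config
  cat(sprintf(paste0(
    "KeypointCountNet (%s head)\n",
    "  stem %d ch, stage1 %d bottlenecks -> %d ch\n",
    "  branches %d/%d ch, %d dual stage(s)\n",
    "  %.2fM trainable parameters, heatmap at input/%d resolution\n"),
    cfg@headVariant, cfg@stemChannels, cfg@stage1Blocks,
    cfg@stage1OutChannels, cfg@branch1Channels, cfg@branch2Channels,
    cfg@dualStages, countParameters(object) / 1e6,
    head_stride(cfg@headVariant)))
})

# accept [H, W, 3] (or [H, W] grey) in [0,1] and return [3, H, W, 1]
image_to_input <- function(image) {
  if (length(dim(image)) == 2L)
    image <- array(rep(image, 3L), c(dim(image), 3L))
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be an [H, W, 3] array")
  x <- aperm(image[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
  dim(x) <- c(dim(x), 1L)
  x
}

#' Predict the keypoint heatmap for one image
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics)
#' on an image whose height and width must be divisible by 8. The heatmap
#' resolution is the input resolution divided by the head-variant stride
#' (1 for `"TDM"`/`"ODM2"`, 2 for `"ODM1"`, 4 for `"NONE"`).
#'
#' @param model a [KeypointCountNet-class].
#' @param image `[H, W, 3]` array with values in `[0, 1]`.
#' @return A [KeypointHeatmap-class] with all scores in `[0, 1]`.
#' @export
predictHeatmap <- function(model, image) {
  x <- vnode(image_to_input(image))
  y <- fwd_net(model, x, tape = NULL, train = FALSE)
  keypointHeatmap(matrix(y$v, dim(y$v)[2], dim(y$v)[3]))
}

#' Count objects in an image with a trained network
#'
#' Predict the heatmap, decode its local peaks, and (optionally) map the
#' detected coordinates back to the native resolution of the image when it
#' was resized for the network. Raising the threshold can only remove
#' detections.
#'
#' @param model a [KeypointCountNet-class].
#' @param image `[H, W, 3]` array in `[0, 1]` at any resolution.
#' @param windowSize,threshold decoder parameters, see [decodePeaks()].
#' @param inputSize (height, width) the image is resized to before the
#'   forward pass; defaults to the model config. Use `NULL` to forward at
#'   native resolution (must be divisible by 8).
#' @return A [CountResult-class]; detections are in native image pixels.
#' @export
predictCount <- function(model, image, windowSize = 3L, threshold = 0.5,
                         inputSize = model@config@inputSize) {
  native <- dim(image)[1:2]
  if (!is.null(inputSize) && !all(native == inputSize)) {
    image <- resize_image(image, inputSize[1], inputSize[2])
  } else {
    inputSize <- native
  }
  hm <- predictHeatmap(model, image)
  res <- decodePeaks(hm, windowSize = windowSize, threshold = threshold)
  stride <- head_stride(model@config@headVariant)
  sy <- native[1] / (inputSize[1] / stride)
  sx <- native[2] / (inputSize[2] / stride)
  det <- res@detections
  det$row <- pmin(round(det$row * sy), native[1] - 1L)
  det$col <- pmin(round(det$col * sx), native[2] - 1L)
  det <- det[!duplicated(det[, c("row", "col")]), , drop = FALSE]
  rownames(det) <- NULL
  countResult(det)
}

#' Save / load network weights
#'
#' The checkpoint stores the configuration, every trainable array, and the
#' batch-norm running statistics, so a reloaded model reproduces forward
#' passes exactly.
#'
#' @param model a [KeypointCountNet-class].
#' @param path checkpoint file (RDS container).
#' @return `saveModel`: `path` invisibly; `loadModel`: the restored model.
#' @export
saveModel <- function(model, path) {
  s <- model@state
  bn_layers <- collect_bn(s)
  ckpt <- list(
    config = lapply(setNames(slotNames(model@config), slotNames(model@config)),
                    function(nm) slot(model@config, nm)),
    weights = lapply(s$params, function(p) p$w),
    bn_stats = lapply(bn_layers, function(l) list(rm = l$rm, rv = l$rv)))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ckpt <- readRDS(path)
  cfg <- do.call(modelConfig, ckpt$config[setdiff(names(ckpt$config), "")])
  model <- buildModel(cfg, seed = 0L)
  s <- model@state
  stopifnot(length(s$params) == length(ckpt$weights))
  for (i in seq_along(s$params)) s$params[[i]]$w <- ckpt$weights[[i]]
  bn_layers <- collect_bn(s)
  stopifnot(length(bn_layers) == length(ckpt$bn_stats))
  for (i in seq_along(bn_layers)) {
    bn_layers[[i]]$rm <- ckpt$bn_stats[[i]]$rm
    bn_layers[[i]]$rv <- ckpt$bn_stats[[i]]$rv
  }
  model
}

collect_bn <- function(s) {
  layers <- list()
  grab <- function(x) {
    if (is.environment(x) && identical(x$type, "bn")) {
      layers[[length(layers) + 1L]] <<- x
    } else if (is.list(x)) lapply(x, grab)
    invisible(NULL)
  }
  grab(list(s$stem, s$stage1, s$trans, s$stages, s$head))
  layers
}

snapshot_weights <- function(model) {
  c(lapply(model@state$params, function(p) p$w),
    lapply(collect_bn(model@state), function(l) list(rm = l$rm, rv = l$rv)))
}

restore_weights <- function(model, snap) {
  np <- length(model@state$params)
  for (i in seq_len(np)) model@state$params[[i]]$w <- snap[[i]]
  bn <- collect_bn(model@state)
  for (i in seq_along(bn)) {
    bn[[i]]$rm <- snap[[np + i]]$rm
    bn[[i]]$rv <- snap[[np + i]]$rv
  }
  invisible(model)
}
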