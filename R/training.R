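#' Augmentation configuration
#'
#' The geometric augmentation protocol applied during training: optional
#' horizontal flip, then a uniform random scale, then a uniform random
#' rotation, all about the image centre (applied in that order; the output
#' canvas keeps the input size). Defaults follow the published training
#' protocol: flip with probability 0.5, scale in `[0.75, 1.5]`, rotation in
#' `[-30, 30]` degrees.
#'
#' @param horizontalFlipProb probability of a horizontal flip.
#' @param scaleRange `(low, high)` uniform scale factor range.
#' @param rotationRangeDeg `(low, high)` uniform rotation range in degrees.
#' @return a list of class `"fry_augmentation_config"`.
#' @export
augmentationConfig <- function(horizontalFlipProb = 0.5,
                               scaleRange = c(0.75, 1.5),
                               rotationRangeDeg = c(-30, 30)) {
  if (horizontalFlipProb < 0 || horizontalFlipProb > 1)
    stop("horizontalFlipProb must be in [0, 1]")
  if (scaleRange[1] > scaleRange[2]) stop("scaleRange must be ordered")
  if (rotationRangeDeg[1] > rotationRangeDeg[2])
    stop("rotationRangeDeg must be ordered")
  structure(list(horizontalFlipProb = horizontalFlipProb,
                 scaleRange = scaleRange,
                 rotationRangeDeg = rotationRangeDeg),
            class = "fry_augmentation_config")
}

#' Apply a random geometric augmentation to an image and its points
#'
#' Image and points undergo the identical transform (flip, then scale and
#' rotation about the image centre). Points that land outside the canvas
#' are dropped. Uses the current RNG stream; seed the caller for
#' reproducibility.
#'
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @param points data.frame with `x`, `y` (0-based pixels).
#' @param config an [augmentationConfig()].
#' @return list with `image` and `points`.
#' @export
augmentSample <- function(image, points, config = augmentationConfig()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  pts <- as_points(points)
  if (runif(1) < config$horizontalFlipProb) {
    image <- image[, W:1, , drop = FALSE]
    if (nrow(pts)) pts$x <- (W - 1) - pts$x
  }
  sc <- runif(1, config$scaleRange[1], config$scaleRange[2])
  ang <- runif(1, config$rotationRangeDeg[1], config$rotationRangeDeg[2]) * pi / 180
  if (abs(sc - 1) > 1e-12 || abs(ang) > 1e-12) {
    A <- sc * rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    # EBImage::affine works on continuous coords with pixel centres at
    # i - 0.5 (1-based); ctr05 is the canvas centre in those coordinates
    ctr05 <- c(W / 2, H / 2)
    t_eb <- ctr05 - as.vector(A %*% ctr05)
    m <- rbind(t(A), t_eb)
    bg <- mean(image)
    image <- from_ebimage(EBImage::affine(to_ebimage(image), m,
                                          output.dim = c(W, H), bg.col = bg))
    image[image < 0] <- 0; image[image > 1] <- 1
    if (nrow(pts)) {
      ctr <- c((W - 1) / 2, (H - 1) / 2)
      q <- t(A %*% t(as.matrix(pts[, c("x", "y")]) - rep(ctr, each = nrow(pts)))) +
        rep(ctr, each = nrow(pts))
      pts <- data.frame(x = q[, 1], y = q[, 2])
    }
  }
  if (nrow(pts)) {
    keep <- round(pts$x) >= 0 & round(pts$x) <= W - 1 &
            round(pts$y) >= 0 & round(pts$y) <= H - 1
    pts <- pts[keep, , drop = FALSE]
    rownames(pts) <- NULL
  }
  list(image = image, points = pts)
}

#' Mean-squared-error heatmap loss
#'
#' `lambda / n * sum((y - yhat)^2)` where `n` is the total number of
#' heatmap values (over the whole batch). With the per-value mean, the loss
#' factor `lambda = 1` is scale-free across image sizes.
#'
#' @param pred,target [KeypointHeatmap-class] objects, matrices or arrays
#'   of identical shape with values in `[0, 1]`.
#' @param lambdaFactor positive loss factor (default 1).
#' @return non-negative scalar loss.
#' @export
mseHeatmapLoss <- function(pred, target, lambdaFactor = 1) {
  if (is(pred, "KeypointHeatmap")) pred <- pred@values
  if (is(target, "KeypointHeatmap")) target <- target@values
  if (!identical(dim(pred), dim(target)))
    stop("pred and target must have identical shape")
  if (lambdaFactor <= 0) stop("lambdaFactor must be > 0")
  lambdaFactor * mean((pred - target)^2)
}

#' Learning rate at a given epoch under a milestone schedule
#'
#' Epochs are 0-based; the published schedule starts at 1.5e-3 and drops to
#' 1.5e-4 and 1.5e-5 at the 20th and 60th epoch.
#'
#' @param epoch 0-based epoch index.
#' @param baseLR learning rate before the first milestone.
#' @param milestones list of `c(epoch, lr)` pairs with strictly increasing
#'   epochs and strictly decreasing rates.
#' @return the learning rate in effect during `epoch`.
#' @examples
#' lrAtEpoch(19)  # 0.0015
#' lrAtEpoch(20)  # 0.00015
#' @export
lrAtEpoch <- function(epoch, baseLR = 1.5e-3,
                      milestones = list(c(20, 1.5e-4), c(60, 1.5e-5))) {
  eps <- vapply(milestones, `[`, numeric(1), 1L)
  lrs <- vapply(milestones, `[`, numeric(1), 2L)
  if (is.unsorted(eps, strictly = TRUE) || any(diff(c(baseLR, lrs)) >= 0))
    stop("milestone epochs must increase and rates must decrease")
  lr <- baseLR
  for (i in seq_along(eps)) if (epoch >= eps[i]) lr <- lrs[i]
  lr
}

# build the [3,h,w,n] input and [1,ho,wo,n] target arrays for one batch
prepare_batch <- function(samples, inputSize, stride, sigma, augment) {
  h <- inputSize[1]; w <- inputSize[2]
  ho <- h %/% stride; wo <- w %/% stride
  n <- length(samples)
  x <- array(0, c(3L, h, w, n))
  tg <- array(0, c(1L, ho, wo, n))
  for (i in seq_len(n)) {
    s <- samples[[i]]
    img <- s$image; pts <- as_points(s$points)
    if (!is.null(augment)) {
      a <- augmentSample(img, pts, augment)
      img <- a$image; pts <- a$points
    }
    if (!all(dim(img)[1:2] == c(h, w))) {
      r <- resizeWithPoints(img, pts, h, w)
      img <- r$image; pts <- r$points
    }
    x[, , , i] <- aperm(img[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
    if (stride > 1L && nrow(pts)) pts <- data.frame(x = pts$x / stride,
                                                    y = pts$y / stride)
    pts <- pts[round(pts$x) <= wo - 1 & round(pts$y) <= ho - 1 &
               pts$x >= 0 & pts$y >= 0, , drop = FALSE]
    tg[1L, , , i] <- encodeHeatmap(pts, ho, wo, sigma = sigma)@values
  }
  list(x = x, target = tg)
}

#' Train the counting network
#'
#' Runs the standard loop — augment, resize to the training input size,
#' encode the Gaussian target heatmap at the head-variant output
#' resolution, forward, per-value mean-squared-error loss, Adam step — with
#' a milestone learning-rate schedule. Fully reproducible given `seed`.
#' When validation samples are provided, counting MAE is tracked per epoch
#' and the weights of the best-MAE epoch are restored at the end.
#'
#' @param model a [KeypointCountNet-class]; weights are updated in place.
#' @param samples training samples: list of lists with `image`
#'   (`[H, W, 3]`, values in `[0, 1]`) and `points` (data.frame `x`, `y`).
#' @param valSamples optional validation samples in the same format.
#' @param epochs number of epochs.
#' @param batchSize images per optimisation step (default 4).
#' @param baseLR,lrMilestones Adam learning-rate schedule, see
#'   [lrAtEpoch()].
#' @param sigma Gaussian target spread on the heatmap grid (default 1).
#' @param lambdaFactor loss factor (default 1).
#' @param augment an [augmentationConfig()], or `NULL` to disable.
#' @param inputSize training (height, width); defaults to the model config.
#' @param threshold,windowSize decoder settings used for validation MAE.
#' @param seed integer seed for shuffling and augmentation.
#' @param verbose print one line per epoch.
#' @return list with `model` and `log`, a data.frame with columns `epoch`
#'   (0-based), `lr`, `mean_loss` and `val_mae` (`NA` without validation).
#' @export
trainModel <- function(model, samples, valSamples = NULL, epochs = 10L,
                       batchSize = 4L, baseLR = 1.5e-3,
                       lrMilestones = list(c(20, 1.5e-4), c(60, 1.5e-5)),
                       sigma = 1, lambdaFactor = 1,
                       augment = augmentationConfig(),
                       inputSize = model@config@inputSize,
                       threshold = 0.5, windowSize = 3L,
                       seed = 1L, verbose = FALSE) {
  if (length(samples) == 0L) stop("empty training set")
  stride <- head_stride(model@config@headVariant)
  params <- model@state$params
  log_rows <- vector("list", epochs)
  best_mae <- Inf; best_snap <- NULL
  step <- 0L
  with_seed(seed, {
    for (e in seq_len(epochs) - 1L) {
      lr <- lrAtEpoch(e, baseLR, lrMilestones)
      idx <- sample(length(samples))
      losses <- c()
      for (b0 in seq(1L, length(idx), by = batchSize)) {
        bi <- idx[b0:min(b0 + batchSize - 1L, length(idx))]
        batch <- prepare_batch(samples[bi], inputSize, stride, sigma, augment)
        tape <- new_tape()
        pred <- fwd_net(model, vnode(batch$x, tape_id(tape)), tape, train = TRUE)
        n_tot <- length(pred$v)
        resid <- pred$v - batch$target
        loss <- lambdaFactor * sum(resid * resid) / n_tot
        tape_backward(tape, pred$id, (2 * lambdaFactor / n_tot) * resid)
        step <- step + 1L
        adam_step(params, lr, t = step)
        zero_grads(params)
        losses <- c(losses, loss)
      }
      val_mae <- NA_real_
      if (!is.null(valSamples)) {
        pv <- vapply(valSamples, function(s)
          keypointCount(predictCount(model, s$image, windowSize = windowSize,
                                     threshold = threshold,
                                     inputSize = inputSize)), numeric(1))
        gv <- vapply(valSamples, function(s) nrow(as_points(s$points)), numeric(1))
        val_mae <- countMAE(gv, pv)
        if (val_mae < best_mae) {
          best_mae <- val_mae
          best_snap <- snapshot_weights(model)
        }
      }
      log_rows[[e + 1L]] <- data.frame(epoch = e, lr = lr,
                                       mean_loss = mean(losses),
                                       val_mae = val_mae)
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  loss %.6f  val MAE %s",
                        e, lr, mean(losses),
                        ifelse(is.na(val_mae), "-", sprintf("%.2f", val_mae))))
    }
  })
  if (!is.null(best_snap)) restore_weights(model, best_snap)
  list(model = model, log = do.call(rbind, log_rows))
}

#' Calibrate the counting threshold on held-out samples
#'
#' The inference score threshold is a free parameter of the decoder. This
#' selects, from a grid, the threshold minimising counting MAE on the given
#' (validation) samples — the standard way to fix it when the training
#' protocol leaves it unspecified. Heatmaps are predicted once and decoded
#' at every candidate threshold.
#'
#' @param model a trained [KeypointCountNet-class].
#' @param samples validation samples (as in [trainModel()]).
#' @param thresholds candidate grid in `[0, 1]`.
#' @param windowSize decoder window.
#' @param inputSize forward-pass size; defaults to the model config.
#' @return the selected threshold, with the per-candidate MAE attached as
#'   attribute `"mae"`.
#' @export
calibrateThreshold <- function(model, samples,
                               thresholds = seq(0.2, 0.8, by = 0.05),
                               windowSize = 3L,
                               inputSize = model@config@inputSize) {
  gt <- vapply(samples, function(s) nrow(as_points(s$points)), numeric(1))
  hms <- lapply(samples, function(s) {
    img <- s$image
    if (!all(dim(img)[1:2] == inputSize)) img <- resize_image(img, inputSize[1], inputSize[2])
    predictHeatmap(model, img)
  })
  maes <- vapply(thresholds, function(th) {
    pred <- vapply(hms, function(h)
      keypointCount(decodePeaks(h, windowSize = windowSize, threshold = th)),
      numeric(1))
    countMAE(gt, pred)
  }, numeric(1))
  # ties broken toward the 0.5 default, the most conservative choice
  best <- thresholds[maes == min(maes)]
  th <- best[which.min(abs(best - 0.5))]
  attr(th, "mae") <- setNames(maes, thresholds)
  th
}

#' Write a training log as CSV
#'
#' @param log the `log` data.frame returned by [trainModel()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeTrainLog <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}
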