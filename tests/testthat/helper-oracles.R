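# Independent oracles and small fixture builders shared across tests.

# brute-force local-peak scan: double loop over every position, explicit
# neighbourhood max with border clipping -- deliberately naive
brute_force_peaks <- function(v, windowSize = 3L, threshold = 0.5) {
  H <- nrow(v); W <- ncol(v); r <- windowSize %/% 2L
  hits <- list()
  for (h in seq_len(H)) {
    for (w in seq_len(W)) {
      nb <- v[max(1, h - r):min(H, h + r), max(1, w - r):min(W, w + r)]
      val <- v[h, w]
      if (val == max(nb) && val >= threshold)
        hits[[length(hits) + 1L]] <- data.frame(row = h - 1L, col = w - 1L,
                                                score = val)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(row = integer(0), col = integer(0), score = numeric(0))
}

# random heatmap with values in [0, 1]
random_heatmap <- function(h, w) matrix(runif(h * w), h, w)

# n integer points with pairwise Chebyshev separation > sep on an h x w grid
separated_points <- function(n, h, w, sep) {
  pts <- matrix(numeric(0), 0, 2)
  while (nrow(pts) < n) {
    cand <- c(sample.int(w, 1) - 1L, sample.int(h, 1) - 1L)
    if (!nrow(pts) || all(pmax(abs(pts[, 1] - cand[1]),
                               abs(pts[, 2] - cand[2])) > sep))
      pts <- rbind(pts, cand)
  }
  data.frame(x = pts[, 1], y = pts[, 2])
}

# an easy high-contrast synthetic scene (the regime the end-to-end
# recovery test trains in)
easy_scene <- function(n, seed, size = 160L) {
  renderScene(sceneConfig(
    imageSize = c(size, size), nObjects = as.integer(n),
    lengthRange = c(12, 20), widthRange = c(3, 4.5),
    headDarkness = 0.7, backgroundLevel = 0.88,
    illuminationGradient = 0.1, noiseSd = 0.01, turbidity = 0.05,
    minSeparation = 8, seed = as.integer(seed)))
}

# tiny architecture for fast training/forward tests
tiny_config <- function(headVariant = "TDM", inputSize = c(32L, 32L)) {
  modelConfig(stemChannels = 4L, stage1Blocks = 1L, stage1OutChannels = 8L,
              branch1Channels = 4L, dualStages = 1L,
              headVariant = headVariant, headChannels = 4L,
              inputSize = inputSize)
}

# central-difference numerical gradient of f at x
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
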