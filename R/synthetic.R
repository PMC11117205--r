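# Synthetic fry-scene simulator. Emulates the variability of overhead
# photographs of fry on a bright plate -- density, illumination gradient,
# water turbidity, pixel noise -- with exact head-point ground truth, so the
# whole pipeline can be trained and evaluated without any external data.

#' Create a synthetic scene configuration
#'
#' Defaults produce a "desk-scale" scene: a 256x256 canvas with up to a few
#' dozen dark elongated fry (capsule bodies with a distinctly darker round
#' head, the annotated keypoint) on a bright background with a linear
#' illumination gradient, mild turbidity blur and sensor noise. Fry in the
#' published benchmark occupy roughly 1-2% of the frame diagonal; the
#' default length range keeps that proportion on the small canvas.
#'
#' @param imageSize (height, width), default `c(256, 256)`.
#' @param nObjects number of fry, default 60.
#' @param lengthRange,widthRange body dimensions in pixels.
#' @param headDarkness extra darkening of the head blob (0-1); higher is
#'   easier to learn.
#' @param backgroundLevel base plate brightness (0-1).
#' @param illuminationGradient amplitude of the linear shading across the
#'   canvas.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param turbidity 0-1; scales a Gaussian blur emulating muddy water.
#' @param minSeparation minimum distance between head centres in pixels
#'   (0 = bodies and heads may overlap, as in dense real scenes).
#' @param seed integer seed; the scene is a pure function of the config.
#' @return A [SceneConfig-class].
#' @export
sceneConfig <- function(imageSize = c(256L, 256L), nObjects = 60L,
                        lengthRange = c(12, 22), widthRange = c(2.5, 4.5),
                        headDarkness = 0.55, backgroundLevel = 0.85,
                        illuminationGradient = 0.15, noiseSd = 0.02,
                        turbidity = 0.15, minSeparation = 0, seed = 1L) {
  new("SceneConfig", imageSize = as.integer(imageSize),
      nObjects = as.integer(nObjects), lengthRange = as.numeric(lengthRange),
      widthRange = as.numeric(widthRange), headDarkness = headDarkness,
      backgroundLevel = backgroundLevel,
      illuminationGradient = illuminationGradient, noiseSd = noiseSd,
      turbidity = turbidity, minSeparation = minSeparation,
      seed = as.integer(seed))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' @describeIn renderScene render the configured scene
#' @export
setMethod("renderScene", "SceneConfig", function(object) {
  validObject(object)
  with_seed(object@seed, render_scene_impl(object))
})

render_scene_impl <- function(cfg) {
  H <- cfg@imageSize[1]; W <- cfg@imageSize[2]
  n <- cfg@nObjects
  margin <- 3

  # head centres, optionally with a minimum pairwise separation
  heads <- matrix(numeric(0), 0, 2)
  tries <- 0L; budget <- max(200L * max(n, 1L), 1000L)
  while (nrow(heads) < n) {
    cand <- c(runif(1, margin, W - 1 - margin), runif(1, margin, H - 1 - margin))
    ok <- TRUE
    if (cfg@minSeparation > 0 && nrow(heads)) {
      d2 <- (heads[, 1] - cand[1])^2 + (heads[, 2] - cand[2])^2
      ok <- all(d2 >= cfg@minSeparation^2)
    }
    if (ok) heads <- rbind(heads, cand)
    tries <- tries + 1L
    if (tries > budget)
      stop(sprintf("could not place %d objects with minSeparation %.1f on a %dx%d canvas",
                   n, cfg@minSeparation, H, W))
  }

  # darkening layer accumulated by element-wise max (overlap keeps darkest)
  dark <- matrix(0, H, W)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)   # x = col coordinate grid
  ys <- matrix(rep(0:(H - 1), W), H, W)
  for (i in seq_len(n)) {
    hx <- heads[i, 1]; hy <- heads[i, 2]
    theta <- runif(1, 0, 2 * pi)
    len <- runif(1, cfg@lengthRange[1], cfg@lengthRange[2])
    wid <- runif(1, cfg@widthRange[1], cfg@widthRange[2])
    # body: capsule from just behind the head to the tail
    tx <- hx + len * cos(theta); ty <- hy + len * sin(theta)
    r0 <- max(1, floor(min(hy, ty) - wid - 2)); r1 <- min(H - 1, ceiling(max(hy, ty) + wid + 2))
    c0 <- max(1, floor(min(hx, tx) - wid - 2)); c1 <- min(W - 1, ceiling(max(hx, tx) + wid + 2))
    if (r0 > r1 || c0 > c1) next
    rr <- (r0:r1) + 1L; cc <- (c0:c1) + 1L
    px <- xs[rr, cc]; py <- ys[rr, cc]
    # distance from each pixel to the head->tail segment
    vx <- tx - hx; vy <- ty - hy
    tproj <- ((px - hx) * vx + (py - hy) * vy) / (vx * vx + vy * vy)
    tproj[tproj < 0] <- 0; tproj[tproj > 1] <- 1
    dx <- px - (hx + tproj * vx); dy <- py - (hy + tproj * vy)
    dseg <- sqrt(dx * dx + dy * dy)
    body <- pmax(0, pmin(1, (wid / 2 + 0.75 - dseg) / 1.5)) * 0.7 * cfg@headDarkness
    # head blob: darker disc centred on the annotation point
    rh <- 0.9 * wid
    dhead <- sqrt((px - hx)^2 + (py - hy)^2)
    headb <- pmax(0, pmin(1, (rh + 0.75 - dhead) / 1.5)) * cfg@headDarkness
    dark[rr, cc] <- pmax(dark[rr, cc], pmax(body, headb))
  }

  # background: base level + linear illumination gradient
  gdir <- runif(1, 0, 2 * pi)
  gx <- cos(gdir); gy <- sin(gdir)
  ramp <- (xs * gx + ys * gy)
  ramp <- if (diff(range(ramp)) > 0) (ramp - min(ramp)) / diff(range(ramp)) - 0.5 else ramp * 0
  bg <- cfg@backgroundLevel + cfg@illuminationGradient * ramp
  img <- bg - dark
  img[img < 0] <- 0; img[img > 1] <- 1

  if (cfg@turbidity > 0)
    img <- from_ebimage(EBImage::gblur(to_ebimage(img), sigma = 0.5 + 1.5 * cfg@turbidity))
  if (cfg@noiseSd > 0)
    img <- img + matrix(rnorm(H * W, sd = cfg@noiseSd), H, W)
  img[img < 0] <- 0; img[img > 1] <- 1

  # mild per-channel tint so the RGB image is not perfectly grey
  image <- array(0, c(H, W, 3))
  tint <- c(0.98, 1.0, 0.96)
  for (ch in 1:3) image[, , ch] <- pmin(1, img * tint[ch])

  list(image = image,
       points = data.frame(x = heads[, 1], y = heads[, 2]),
       config = cfg)
}

#' Generate a benchmark directory of synthetic scenes
#'
#' Writes PNG images, Labelme-style JSON point annotations and a YAML
#' manifest -- the same formats the real-data readers consume, so synthetic
#' and real datasets are interchangeable. Every image of a batch has the
#' same object count, mirroring how the real benchmark was photographed.
#'
#' @param dir output directory (created if needed).
#' @param batches data.frame with columns `batch_id`, `density`, `count`,
#'   `n_images`; or `NULL` to derive one batch per entry of `densities`.
#' @param densities named list of count ranges, e.g.
#'   `list(low = c(10, 30), high = c(55, 80))`; used when `batches` is
#'   `NULL` (one batch per density, count drawn from the range).
#' @param imagesPerDensity images per derived batch.
#' @param imageSize canvas size, default `c(256, 256)`.
#' @param seed master seed; every scene gets a sub-seed derived from it.
#' @param ... further [sceneConfig()] parameters applied to every scene.
#' @return the [DatasetManifest-class], invisibly; files on disk.
#' @export
makeBenchmark <- function(dir, batches = NULL,
                          densities = list(low = c(10, 30),
                                           medium = c(30, 55),
                                           high = c(55, 80)),
                          imagesPerDensity = 2L,
                          imageSize = c(256L, 256L), seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(batches)) {
    batches <- with_seed(seed, data.frame(
      batch_id = seq_along(densities),
      density = names(densities),
      count = vapply(densities, function(r)
        as.integer(round(runif(1, r[1], r[2]))), integer(1)),
      n_images = imagesPerDensity))
  }
  manifest <- datasetManifest(batches)
  im <- manifest@images
  for (i in seq_len(nrow(im))) {
    cfg <- sceneConfig(imageSize = imageSize, nObjects = im$count[i],
                       seed = (seed * 10007L + i) %% .Machine$integer.max, ...)
    sc <- renderScene(cfg)
    png::writePNG(sc$image, file.path(dir, paste0(im$image_id[i], ".png")))
    writeLabelmePoints(sc$points,
                       file.path(dir, paste0(im$image_id[i], ".json")),
                       imageHeight = imageSize[1], imageWidth = imageSize[2],
                       imagePath = paste0(im$image_id[i], ".png"))
  }
  writeManifest(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Load a benchmark directory into memory
#'
#' @param dir a directory written by [makeBenchmark()] (or arranged the
#'   same way from real data).
#' @param split optional split name to subset to.
#' @return list with `manifest` and `samples`, each sample a list of
#'   `image`, `points`, `image_id`, `count`.
#' @export
loadBenchmark <- function(dir, split = NULL) {
  manifest <- readManifest(file.path(dir, "manifest.yaml"))
  im <- manifest@images
  if (!is.null(split)) {
    if (!split %in% names(manifest@splits))
      stop(sprintf("unknown split '%s'", split))
    im <- im[im$image_id %in% manifest@splits[[split]], , drop = FALSE]
  }
  samples <- lapply(seq_len(nrow(im)), function(i) {
    png <- png::readPNG(file.path(dir, paste0(im$image_id[i], ".png")))
    if (length(dim(png)) == 2L) png <- array(rep(png, 3), c(dim(png), 3L))
    list(image = png[, , 1:3, drop = FALSE],
         points = readLabelmePoints(file.path(dir, paste0(im$image_id[i], ".json"))),
         image_id = im$image_id[i],
         count = im$count[i])
  })
  list(manifest = manifest, samples = samples)
}
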