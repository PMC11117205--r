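# Annotation and image I/O. Internal images are [H, W, 3] arrays in [0, 1]
# with 0-based (row, col) pixel indexing; Labelme stores continuous (x, y) =
# (col, row). The axis swap happens exactly once, in these readers/writers.

#' Read point annotations from a Labelme-style JSON file
#'
#' Returns one annotation per shape of type `"point"`. Shapes of any other
#' type are skipped; their number is attached as attribute `"skipped"` and
#' reported with a warning.
#'
#' @param path a Labelme JSON document.
#' @return data.frame with columns `x`, `y` (0-based continuous pixel
#'   coordinates, x = column axis) and `label`.
#' @export
readLabelmePoints <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("not a Labelme document: missing 'shapes'")
  pts <- list(); skipped <- 0L
  for (sh in doc$shapes) {
    if (identical(sh$shape_type, "point")) {
      p <- sh$points[[1]]
      pts[[length(pts) + 1L]] <- data.frame(
        x = as.numeric(p[[1]]), y = as.numeric(p[[2]]),
        label = if (is.null(sh$label)) "point" else sh$label)
    } else {
      skipped <- skipped + 1L
    }
  }
  out <- if (length(pts)) do.call(rbind, pts) else
    data.frame(x = numeric(0), y = numeric(0), label = character(0))
  if (skipped)
    warning(sprintf("%s: skipped %d non-point shape(s)", basename(path), skipped))
  attr(out, "skipped") <- skipped
  out
}

#' Write point annotations as a Labelme-style JSON file
#'
#' @param points data.frame with columns `x`, `y` and optionally `label`.
#' @param path output JSON file.
#' @param imageHeight,imageWidth image dimensions recorded in the document.
#' @param imagePath image file name recorded in the document.
#' @return `path`, invisibly.
#' @export
writeLabelmePoints <- function(points, path, imageHeight, imageWidth,
                               imagePath = "") {
  pts <- as_points(points)
  labels <- if ("label" %in% names(points)) points$label else
    rep("fry", nrow(pts))
  shapes <- lapply(seq_len(nrow(pts)), function(i) list(
    label = labels[i],
    points = list(c(pts$x[i], pts$y[i])),
    group_id = NULL,
    shape_type = "point",
    flags = structure(list(), names = character(0))))
  doc <- list(version = "5.0.0",
              flags = structure(list(), names = character(0)),
              shapes = shapes,
              imagePath = imagePath,
              imageData = NULL,
              imageHeight = imageHeight,
              imageWidth = imageWidth)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Construct a dataset manifest
#'
#' @param batches data.frame with columns `batch_id`, `density` (one of
#'   `"low"`, `"medium"`, `"high"`), `count` (objects per image) and
#'   `n_images`; image ids are generated as `b<batch>_<i>` unless an
#'   `image_ids` list-column is supplied.
#' @param splits named list of character vectors of image ids.
#' @return A [DatasetManifest-class].
#' @export
datasetManifest <- function(batches, splits = list()) {
  rows <- lapply(seq_len(nrow(batches)), function(i) {
    ids <- if ("image_ids" %in% names(batches)) batches$image_ids[[i]] else
      sprintf("b%s_%03d", batches$batch_id[i], seq_len(batches$n_images[i]))
    data.frame(image_id = ids,
               batch_id = batches$batch_id[i],
               density = batches$density[i],
               count = batches$count[i])
  })
  new("DatasetManifest", images = do.call(rbind, rows), splits = splits)
}

#' @describeIn manifestInstanceTotal sum of per-image counts over a split
#'   (or all images)
#' @export
setMethod("manifestInstanceTotal", "DatasetManifest", function(object, split = NULL) {
  im <- object@images
  if (is.null(im) || nrow(im) == 0L) return(0)
  if (!is.null(split)) {
    if (!split %in% names(object@splits))
      stop(sprintf("unknown split '%s'", split))
    im <- im[im$image_id %in% object@splits[[split]], , drop = FALSE]
  }
  sum(im$count)
})

setMethod("show", "DatasetManifest", function(object) {
  im <- object@images
  cat(sprintf("DatasetManifest: %d image(s), %d batch(es), %s instance(s)\n",
              nrow(im), length(unique(im$batch_id)),
              format(manifestInstanceTotal(object), big.mark = ",")))
  for (s in names(object@splits))
    cat(sprintf("  split %-6s %4d image(s), %s instance(s)\n", s,
                length(object@splits[[s]]),
                format(manifestInstanceTotal(object, s), big.mark = ",")))
})

#' The published fry-counting benchmark bookkeeping
#'
#' The 8-batch annotation structure of the FishFry-2023 benchmark: batches
#' 1-3 low density (204, 438, 591 fry per image), 4-6 medium (642, 712,
#' 876), 7-8 high (1312, 1935), with 45/45/5/45/5/5/45/5 annotated images —
#' 200 images and 137,390 annotated fry in total. The train split takes 40
#' images from each of the four 45-image batches (103,840 instances); the
#' validation split takes the remaining 5 of those plus all 5 images of the
#' small batches (40 images, 33,550 instances).
#'
#' @return A [DatasetManifest-class].
#' @examples
#' m <- referenceFryManifest()
#' manifestInstanceTotal(m)            # 137390
#' manifestInstanceTotal(m, "train")   # 103840
#' @export
referenceFryManifest <- function() {
  batches <- data.frame(
    batch_id = 1:8,
    density = rep(c("low", "medium", "high"), c(3, 3, 2)),
    count = c(204L, 438L, 591L, 642L, 712L, 876L, 1312L, 1935L),
    n_images = c(45L, 45L, 5L, 45L, 5L, 5L, 45L, 5L))
  m <- datasetManifest(batches)
  big <- batches$batch_id[batches$n_images == 45L]
  train <- unlist(lapply(big, function(b) sprintf("b%d_%03d", b, 1:40)))
  val <- c(unlist(lapply(big, function(b) sprintf("b%d_%03d", b, 41:45))),
           unlist(lapply(setdiff(1:8, big),
                         function(b) sprintf("b%d_%03d", b, 1:5))))
  m@splits <- list(train = train, val = val)
  validObject(m)
  m
}

#' Write / read a manifest as YAML
#'
#' @param manifest a [DatasetManifest-class].
#' @param path YAML file.
#' @return `writeManifest`: `path` invisibly; `readManifest`: the manifest.
#' @export
writeManifest <- function(manifest, path) {
  im <- manifest@images
  by_batch <- split(im, im$batch_id)
  doc <- list(
    batches = lapply(by_batch, function(b) list(
      batch_id = b$batch_id[1], density = b$density[1],
      count = b$count[1], image_ids = as.list(b$image_id))),
    splits = lapply(manifest@splits, as.list))
  names(doc$batches) <- NULL
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  doc <- yaml::read_yaml(path)
  rows <- lapply(doc$batches, function(b) data.frame(
    image_id = unlist(b$image_ids), batch_id = b$batch_id,
    density = b$density, count = b$count))
  new("DatasetManifest", images = do.call(rbind, rows),
      splits = lapply(doc$splits, unlist))
}

# EBImage round trip for an [H, W, (3)] array; x/y swap handled here
to_ebimage <- function(image) {
  if (length(dim(image)) == 2L) EBImage::Image(t(image)) else
    EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
}

from_ebimage <- function(img) {
  a <- as.array(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

resize_image <- function(image, h, w) {
  if (h < 1L || w < 1L) stop("target dimensions must be positive")
  out <- from_ebimage(EBImage::resize(to_ebimage(image), w = w, h = h))
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Resize an image together with its point annotations
#'
#' The image is resampled bilinearly; points are scaled by
#' `(sx, sy) = (targetW / sourceW, targetH / sourceH)` (aspect distortion is
#' accepted — dense counting benchmarks commonly square non-square frames).
#' The returned transform supports mapping detections back to native
#' coordinates.
#'
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @param points data.frame with `x`, `y` columns, 0-based pixels.
#' @param targetH,targetW target size in pixels.
#' @return list with `image`, `points`, and `transform` (list `sx`, `sy`
#'   with `forward`/`inverse` point mappers).
#' @export
resizeWithPoints <- function(image, points, targetH, targetW) {
  sh <- dim(image)[1]; sw <- dim(image)[2]
  if (targetH < 1 || targetW < 1) stop("target dimensions must be positive")
  sx <- targetW / sw; sy <- targetH / sh
  tr <- resize_transform(sx, sy)
  pts <- as_points(points)
  out_pts <- tr$forward(pts)
  if ("label" %in% names(points)) out_pts$label <- points$label
  list(image = resize_image(image, targetH, targetW),
       points = out_pts, transform = tr)
}

resize_transform <- function(sx, sy) {
  if (sx <= 0 || sy <= 0) stop("scale factors must be positive")
  list(sx = sx, sy = sy,
       forward = function(p) data.frame(x = p$x * sx, y = p$y * sy),
       inverse = function(p) data.frame(x = p$x / sx, y = p$y / sy))
}

#' Write an overlay PNG with one marker per detection
#'
#' Draws a small cross at every detection on top of the image — the visual
#' audit used to spot-check counting results.
#'
#' @param image `[H, W, 3]` array in `[0, 1]`.
#' @param result a [CountResult-class] with detections in image pixels.
#' @param path output PNG.
#' @param color marker colour, length-3 RGB in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
writeOverlayPNG <- function(image, result, path, color = c(0, 1, 0)) {
  if (length(dim(image)) == 2L)
    image <- array(rep(image, 3L), c(dim(image), 3L))
  H <- dim(image)[1]; W <- dim(image)[2]
  det <- detections(result)
  for (i in seq_len(nrow(det))) {
    r <- det$row[i] + 1L; c0 <- det$col[i] + 1L
    rows <- pmax(1L, pmin(H, r + (-1:1)))
    cols <- pmax(1L, pmin(W, c0 + (-1:1)))
    for (ch in 1:3) {
      image[rows, c0, ch] <- color[ch]
      image[r, cols, ch] <- color[ch]
    }
  }
  png::writePNG(image, path)
  invisible(path)
}
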