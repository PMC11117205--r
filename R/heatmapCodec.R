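#' Encode point annotations as a Gaussian target heatmap
#'
#' Writes a truncated 2-D Gaussian bump `exp(-((dr)^2 + (dc)^2) / (2 sigma^2))`
#' of peak value exactly 1 at each annotated point. Where bumps overlap they
#' are combined by the element-wise maximum, which keeps every value in
#' `[0, 1]` and preserves a peak of 1 at every annotated pixel (summing
#' would not). Continuous coordinates are rounded to the nearest integer
#' pixel centre.
#'
#' @param points data.frame with columns `x` (column axis) and `y` (row
#'   axis), 0-based pixel coordinates; or a two-column matrix. May have zero
#'   rows.
#' @param height,width heatmap dimensions in pixels.
#' @param sigma Gaussian spread in pixels (default 1, the value used to
#'   train the published fry counter).
#' @param truncationRadius integer radius beyond which the bump is not
#'   written; defaults to `ceiling(3 * sigma)` (contributions beyond 3 sigma
#'   are below 0.012 and irrelevant to peak decoding).
#' @return A [KeypointHeatmap-class].
#' @examples
#' hm <- encodeHeatmap(data.frame(x = 5, y = 5), 16, 16)
#' heatmapValues(hm)[6, 6]   # 1 at the annotated pixel (0-based (5,5))
#' @export
encodeHeatmap <- function(points, height, width, sigma = 1,
                          truncationRadius = ceiling(3 * sigma)) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L)
    stop("heatmap dimensions must be positive integers")
  if (sigma <= 0) stop("sigma must be > 0")
  if (truncationRadius < ceiling(3 * sigma))
    stop("truncationRadius must be at least ceiling(3 * sigma)")
  pts <- as_points(points)
  if (nrow(pts)) {
    bad <- pts$x < 0 | pts$x >= width | pts$y < 0 | pts$y >= height
    if (any(bad))
      stop(sprintf("%d point(s) outside the %dx%d image, first offender (x=%g, y=%g)",
                   sum(bad), height, width,
                   pts$x[which(bad)[1]], pts$y[which(bad)[1]]))
  }
  hm <- matrix(0, height, width)
  r <- as.integer(truncationRadius)
  off <- -r:r
  bump <- exp(-(outer(off^2, off^2, `+`)) / (2 * sigma^2))
  for (i in seq_len(nrow(pts))) {
    pr <- round(pts$y[i]); pc <- round(pts$x[i])
    rows <- (pr - r):(pr + r); cols <- (pc - r):(pc + r)
    keep_r <- rows >= 0 & rows < height
    keep_c <- cols >= 0 & cols < width
    sub <- bump[keep_r, keep_c, drop = FALSE]
    ri <- rows[keep_r] + 1L; ci <- cols[keep_c] + 1L
    hm[ri, ci] <- pmax(hm[ri, ci], sub)
  }
  keypointHeatmap(hm)
}

as_points <- function(points) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  if (is.null(points) || nrow(points) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0)))
  if (!all(c("x", "y") %in% names(points)))
    stop("points must have columns x and y")
  points[, c("x", "y")]
}

decode_peaks_matrix <- function(v, windowSize, threshold) {
  windowSize <- as.integer(windowSize)
  if (windowSize %% 2L == 0L || windowSize < 3L)
    stop("windowSize must be an odd integer >= 3")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (anyNA(v) || min(v) < 0 || max(v) > 1)
    stop("heatmap values must lie in [0, 1]")
  mx <- local_window_max(v, windowSize)
  hit <- which(v == mx & v >= threshold, arr.ind = TRUE)
  det <- data.frame(row = hit[, 1] - 1L, col = hit[, 2] - 1L,
                    score = v[hit])
  # row-major traversal order, as the decoding loop walks the heatmap
  det <- det[order(det$row, det$col), , drop = FALSE]
  rownames(det) <- NULL
  countResult(det)
}

#' @rdname decodePeaks
#' @export
setMethod("decodePeaks", "KeypointHeatmap",
          function(object, windowSize = 3L, threshold = 0.5, ...)
            decode_peaks_matrix(object@values, windowSize, threshold))

#' @rdname decodePeaks
#' @export
setMethod("decodePeaks", "matrix",
          function(object, windowSize = 3L, threshold = 0.5, ...)
            decode_peaks_matrix(object, windowSize, threshold))

#' Encode points to a heatmap and decode them back
#'
#' Composition of [encodeHeatmap()] and [decodePeaks()]. When all points are
#' mutually separated (Chebyshev distance) by more than
#' `max(windowSize, 2 * truncationRadius)` pixels, the decoded set equals
#' the input point set exactly, with scores 1.
#'
#' @inheritParams encodeHeatmap
#' @inheritParams decodePeaks
#' @return A [CountResult-class].
#' @export
heatmapRoundTrip <- function(points, height, width, sigma = 1,
                             truncationRadius = ceiling(3 * sigma),
                             windowSize = 3L, threshold = 0.5) {
  decodePeaks(encodeHeatmap(points, height, width, sigma, truncationRadius),
              windowSize = windowSize, threshold = threshold)
}

#' Per-axis coordinate error of predicting on a downsampled heatmap
#'
#' A keypoint at full-resolution coordinate `coord` lands at
#' `floor(coord / factor)` on a 1/`factor`-resolution heatmap; mapping back
#' by multiplying with `factor` loses `coord - factor * floor(coord / factor)`
#' pixels. The error is at most `factor - 1` per axis (3 px at the common
#' factor 4), which is the quantisation argument for predicting the heatmap
#' at full input resolution.
#'
#' @param coord non-negative integer coordinate(s) at full resolution.
#' @param factor integer downsampling factor >= 1.
#' @return integer absolute reconstruction error(s), same length as `coord`.
#' @examples
#' quantizedCoordError(517, 4)   # 1
#' max(quantizedCoordError(0:1023, 4))  # 3
#' @export
quantizedCoordError <- function(coord, factor) {
  if (any(factor < 1)) stop("factor must be >= 1")
  if (any(coord < 0)) stop("coord must be >= 0")
  abs(coord - factor * floor(coord / factor))
}

#' @describeIn detections detections of a CountResult
#' @export
setMethod("detections", "CountResult", function(object) object@detections)

#' @describeIn detections count of a CountResult
#' @export
setMethod("keypointCount", "CountResult", function(object) object@count)

#' @rdname heatmapValues
#' @export
setMethod("heatmapValues", "KeypointHeatmap", function(object) object@values)

#' @export
setMethod("dim", "KeypointHeatmap", function(x) dim(x@values))

setMethod("show", "KeypointHeatmap", function(object) {
  v <- object@values
  cat(sprintf("KeypointHeatmap %d x %d, scores in [%.3f, %.3f]\n",
              nrow(v), ncol(v), min(v), max(v)))
})

setMethod("show", "CountResult", function(object) {
  cat(sprintf("CountResult: %d keypoint(s)\n", object@count))
  if (object@count) {
    print(head(object@detections, 5))
    if (object@count > 5) cat(sprintf("... and %d more\n", object@count - 5L))
  }
})

#' Write a counting result to CSV or JSON
#'
#' CSV has columns `row`, `col`, `score`; JSON carries the same records plus
#' the total count.
#'
#' @param result a [CountResult-class].
#' @param path output file; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
writeCountResult <- function(result, path) {
  stopifnot(is(result, "CountResult"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(count = result@count,
                              detections = result@detections),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(result@detections, path, row.names = FALSE)
  }
  invisible(path)
}

#' Save a heatmap for inspection
#'
#' Writes the raw scores as a headerless CSV matrix and/or a greyscale PNG.
#'
#' @param heatmap a [KeypointHeatmap-class].
#' @param path output file (.csv or .png).
#' @return `path`, invisibly.
#' @export
writeHeatmap <- function(heatmap, path) {
  stopifnot(is(heatmap, "KeypointHeatmap"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(heatmap@values, path)
  } else {
    utils::write.table(heatmap@values, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a heatmap written by [writeHeatmap()]
#'
#' @param path a CSV file of scores.
#' @return A [KeypointHeatmap-class].
#' @export
readHeatmap <- function(path) {
  keypointHeatmap(as.matrix(utils::read.table(path, sep = ",")))
}
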