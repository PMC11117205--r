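#' Keypoint score heatmap
#'
#' A 2-D grid of scores in `[0, 1]`. Rows index image rows, columns index
#' image columns; pixel centres sit at integer 0-based coordinates. The
#' heatmap is both the training target (Gaussian bumps of peak 1 at each
#' annotated head point) and the network output (per-pixel keypoint scores).
#'
#' @slot values numeric matrix with all entries in `[0, 1]`.
#' @seealso [encodeHeatmap()], [decodePeaks()]
#' @export
setClass("KeypointHeatmap", representation(values = "matrix"))

setValidity("KeypointHeatmap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("heatmap must have positive dimensions")
  if (anyNA(v)) return("heatmap contains NA")
  if (min(v) < 0 || max(v) > 1) return("heatmap values must lie in [0, 1]")
  TRUE
})

#' Construct a KeypointHeatmap from a score matrix
#'
#' @param values numeric matrix of scores in `[0, 1]`.
#' @return A [KeypointHeatmap-class] object.
#' @export
keypointHeatmap <- function(values) new("KeypointHeatmap", values = values)

#' Decoded counting result
#'
#' The output of the local-peak decoder: one detection per local maximum of
#' the heatmap that reaches the score threshold. `count` always equals the
#' number of detections — counting and locating are the same operation.
#'
#' @slot detections data.frame with columns `row`, `col` (0-based pixel
#'   coordinates) and `score`.
#' @slot count integer, number of detections.
#' @seealso [decodePeaks()], [predictCount()]
#' @export
setClass("CountResult",
         representation(detections = "data.frame", count = "integer"))

setValidity("CountResult", function(object) {
  d <- object@detections
  if (!all(c("row", "col", "score") %in% names(d)))
    return("detections must have columns row, col, score")
  if (object@count != nrow(d)) return("count must equal nrow(detections)")
  if (nrow(d) && anyDuplicated(d[, c("row", "col")]))
    return("detections must be unique (row, col) pairs")
  TRUE
})

countResult <- function(detections) {
  new("CountResult", detections = detections, count = nrow(detections))
}

#' Network architecture configuration
#'
#' Hyper-parameters of the dual-branch high-resolution feature extractor and
#' its deconvolution head. The defaults reproduce the published
#' architecture: a stride-4 stem into four bottleneck blocks, a 48/96-channel
#' branch pair refined over three dual-branch stages with cross-branch
#' fusion, and a head of two stride-2 transposed convolutions (`"TDM"`) that
#' restores full input resolution before a 1x1 convolution and sigmoid
#' produce the single-channel heatmap.
#'
#' @slot stemChannels channels of the two stride-2 stem convolutions.
#' @slot stage1Blocks number of bottleneck residual blocks in stage 1.
#' @slot stage1OutChannels output channels of stage 1 (bottleneck expansion).
#' @slot branch1Channels channels of the 1/4-resolution branch.
#' @slot branch2Channels channels of the 1/8-resolution branch; must be twice
#'   `branch1Channels`.
#' @slot dualStages number of dual-branch rounds (4 basic blocks per branch
#'   each, followed by cross-branch fusion).
#' @slot headVariant one of `"NONE"`, `"ODM1"`, `"ODM2"`, `"TDM"`: zero, one
#'   (stride 2), one (stride 4) or two (stride 2 each) transposed-convolution
#'   modules in the head. Output resolution is input/4, input/2, input and
#'   input respectively.
#' @slot headChannels channels carried through the head deconvolutions.
#' @slot inputSize default (height, width) used by training and prediction.
#' @export
setClass("ModelConfig", representation(
  stemChannels = "integer", stage1Blocks = "integer",
  stage1OutChannels = "integer", branch1Channels = "integer",
  branch2Channels = "integer", dualStages = "integer",
  headVariant = "character", headChannels = "integer",
  inputSize = "integer"))

setValidity("ModelConfig", function(object) {
  if (!object@headVariant %in% c("NONE", "ODM1", "ODM2", "TDM"))
    return("headVariant must be one of NONE, ODM1, ODM2, TDM")
  if (object@branch2Channels != 2L * object@branch1Channels)
    return("branch2Channels must be exactly twice branch1Channels")
  ints <- c(object@stemChannels, object@stage1Blocks, object@stage1OutChannels,
            object@branch1Channels, object@dualStages, object@headChannels,
            object@inputSize)
  if (any(ints < 1L)) return("all size parameters must be positive")
  if (length(object@inputSize) != 2L) return("inputSize must be length 2")
  TRUE
})

#' Keypoint-counting network
#'
#' A built network: its configuration plus all trainable weights. Weights
#' live in an environment so that training can update them in place. Use
#' [buildModel()] to construct, [predictHeatmap()] / [predictCount()] for
#' inference, [trainModel()] to fit, and [countParameters()] for the size of
#' the model.
#'
#' @slot config a [ModelConfig-class].
#' @slot state environment holding the layer graph and parameters.
#' @export
setClass("KeypointCountNet",
         representation(config = "ModelConfig", state = "environment"))

#' Batch-structured dataset manifest
#'
#' Bookkeeping for a point-annotated counting dataset organised in batches:
#' every image in a batch contains the same known number of objects (the way
#' the fry-counting benchmark was photographed: a fixed population on the
#' plate, many shots). Splits are named lists of image ids.
#'
#' @slot images data.frame with columns `image_id`, `batch_id`, `density`
#'   (one of low/medium/high), `count`.
#' @slot splits named list mapping split name to a character vector of
#'   image ids.
#' @export
setClass("DatasetManifest",
         representation(images = "data.frame", splits = "list"))

setValidity("DatasetManifest", function(object) {
  im <- object@images
  need <- c("image_id", "batch_id", "density", "count")
  if (!all(need %in% names(im)))
    return("images must have columns image_id, batch_id, density, count")
  if (anyDuplicated(im$image_id)) return("duplicate image ids")
  per_batch <- tapply(im$count, im$batch_id, function(x) length(unique(x)))
  if (length(per_batch) && any(per_batch != 1L))
    return("all images of a batch must share the batch per-image count")
  ids <- unlist(object@splits, use.names = FALSE)
  if (length(ids) && !all(ids %in% im$image_id))
    return("split references unknown image id")
  if (!is.null(object@splits$train) && !is.null(object@splits$val) &&
      length(intersect(object@splits$train, object@splits$val)))
    return("train and val splits must be disjoint")
  TRUE
})

#' Synthetic fry-scene configuration
#'
#' Parameters of the simulator that emulates overhead photographs of fish
#' fry on a bright plate: dark elongated capsule bodies with a darker
#' circular head blob (the annotated keypoint), on a background with a
#' linear illumination gradient, pixel noise, and a turbidity blur.
#'
#' @slot imageSize (height, width) in pixels.
#' @slot nObjects number of fry to render.
#' @slot lengthRange body length range, pixels.
#' @slot widthRange body half-thickness is half this width, pixels.
#' @slot headDarkness extra darkening of the head blob, in `[0, 1]`.
#' @slot backgroundLevel base background intensity in `[0, 1]`.
#' @slot illuminationGradient peak-to-peak amplitude of the linear shading.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise.
#' @slot turbidity water turbidity in `[0, 1]`; scales a Gaussian blur.
#' @slot minSeparation minimum distance between head centres (0 = overlap
#'   freely).
#' @slot seed integer seed; scenes are bit-for-bit reproducible.
#' @export
setClass("SceneConfig", representation(
  imageSize = "integer", nObjects = "integer",
  lengthRange = "numeric", widthRange = "numeric",
  headDarkness = "numeric", backgroundLevel = "numeric",
  illuminationGradient = "numeric", noiseSd = "numeric",
  turbidity = "numeric", minSeparation = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (length(object@imageSize) != 2L || any(object@imageSize < 8L))
    return("imageSize must be two values >= 8")
  if (object@nObjects < 0L) return("nObjects must be >= 0")
  for (nm in c("lengthRange", "widthRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] > r[2] || r[1] <= 0)
      return(sprintf("%s must be an ordered positive range", nm))
  }
  if (object@headDarkness < 0 || object@headDarkness > 1)
    return("headDarkness must be in [0, 1]")
  if (object@turbidity < 0 || object@turbidity > 1)
    return("turbidity must be in [0, 1]")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@minSeparation < 0) return("minSeparation must be >= 0")
  TRUE
})
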