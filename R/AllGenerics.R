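#' @name frycount-generics
#' @title Generics for the keypoint-counting classes
#' @description S4 generics with methods on the package's core classes.
#' @param object,model the object to operate on
#' @param ... passed to methods
NULL

#' Number of trainable parameters
#'
#' Counts every trainable scalar weight of a built network: convolution and
#' transposed-convolution kernels, batch-normalisation scale/shift pairs, and
#' the final 1x1 convolution with its bias. Running batch-norm statistics
#' are not trainable and are not counted. The count depends only on the
#' architecture, never on the input size (the network is fully
#' convolutional).
#'
#' @param model a [KeypointCountNet-class].
#' @return integer (double for safety) total parameter count.
#' @examples
#' cfg <- modelConfig(branch1Channels = 8L, headChannels = 8L)
#' net <- buildModel(cfg, seed = 1)
#' countParameters(net)
#' @export
setGeneric("countParameters", function(model) standardGeneric("countParameters"))

#' Decode heatmap local peaks into a counting result
#'
#' A pixel is a detection iff its score equals the maximum over the
#' \code{windowSize x windowSize} neighbourhood centred on it (the window is
#' clipped at the borders, i.e. max-pooling with stride 1 and implicit
#' padding) and the score reaches \code{threshold}. Plateau pixels of equal
#' value within one window are all kept. Detections are returned in
#' row-major traversal order.
#'
#' @param object a [KeypointHeatmap-class] or a numeric matrix of scores in
#'   `[0, 1]`.
#' @param windowSize odd integer >= 3, neighbourhood side length (default 3).
#' @param threshold counting score threshold in `[0, 1]` (default 0.5).
#' @param ... unused.
#' @return A [CountResult-class]; `keypointCount(x)` is the object count.
#' @examples
#' m <- matrix(0, 8, 8); m[4, 5] <- 0.9
#' decodePeaks(m)
#' @export
setGeneric("decodePeaks",
           function(object, windowSize = 3L, threshold = 0.5, ...)
             standardGeneric("decodePeaks"))

#' Total annotated instances covered by a manifest
#'
#' Sums the batch per-image count over the selected images — the way the
#' number of annotated objects in a batch-structured dataset is book-kept
#' (and how ground truth for unlabelled test images of a known batch is
#' obtained).
#'
#' @param object a [DatasetManifest-class].
#' @param split a split name, or `NULL` for all images.
#' @return numeric total instance count.
#' @examples
#' manifestInstanceTotal(referenceFryManifest())
#' @export
setGeneric("manifestInstanceTotal",
           function(object, split = NULL) standardGeneric("manifestInstanceTotal"))

#' Render one synthetic fry scene
#'
#' @param object a [SceneConfig-class] from [sceneConfig()].
#' @return list with `image` (height x width x 3 array in `[0, 1]`),
#'   `points` (data.frame of head coordinates `x`, `y`, 0-based pixels) and
#'   `config`.
#' @examples
#' sc <- renderScene(sceneConfig(nObjects = 5L, seed = 3L))
#' nrow(sc$points)
#' @export
setGeneric("renderScene", function(object) standardGeneric("renderScene"))

#' Accessors for counting results
#'
#' @param object a [CountResult-class].
#' @return `detections()`: the data.frame of (row, col, score) triples;
#'   `keypointCount()`: the integer count.
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname detections
#' @export
setGeneric("keypointCount", function(object) standardGeneric("keypointCount"))

#' Heatmap values accessor
#'
#' @param object a [KeypointHeatmap-class].
#' @return the numeric score matrix.
#' @export
setGeneric("heatmapValues", function(object) standardGeneric("heatmapValues"))
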