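#' @import methods
#' @importFrom stats rnorm runif rpois lm coef vcov setNames
#' @importFrom utils head tail write.csv read.csv
#' @useDynLib dicentricAssay, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Bounding boxes travel as plain data.frames throughout the package:
## columns x_min, y_min, x_max, y_max (pixels, 0-based, half-open) and
## class_id (0 = normal, 1 = dicentric). Detections add score and per-class
## probability columns. emptyBoxes() / validateBoxes() define the contract.

#' Empty bounding-box table
#'
#' Returns a zero-row data.frame with the package's bounding-box columns:
#' `x_min`, `y_min`, `x_max`, `y_max` (pixels, 0-based, half-open interval,
#' x along columns, y along rows) and `class_id` (0 = normal chromosome,
#' 1 = dicentric).
#'
#' @return A zero-row data.frame with the five box columns.
#' @export
emptyBoxes <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0),
             class_id = integer(0))
}

validateBoxes <- function(boxes, imageSize = NULL, what = "boxes") {
  required <- c("x_min", "y_min", "x_max", "y_max", "class_id")
  if (!is.data.frame(boxes) || !all(required %in% names(boxes)))
    stop(what, " must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (nrow(boxes) == 0L) return(invisible(boxes))
  if (any(boxes$x_max <= boxes$x_min) || any(boxes$y_max <= boxes$y_min))
    stop(what, ": degenerate box (zero or negative extent)", call. = FALSE)
  if (!is.null(imageSize)) {
    w <- imageSize[1]; h <- if (length(imageSize) > 1) imageSize[2] else imageSize[1]
    if (any(boxes$x_min < 0) || any(boxes$y_min < 0) ||
        any(boxes$x_max > w) || any(boxes$y_max > h))
      stop(what, ": box outside image bounds", call. = FALSE)
  }
  invisible(boxes)
}

#' Scene specification for the synthetic metaphase generator
#'
#' An S4 container describing one synthetic Giemsa-stained metaphase spread:
#' the canvas size, how many chromosomes to place, how many of them are
#' dicentric (two centromeric constrictions instead of one), the geometry
#' ranges the renderer samples from, and the photometric parameters. The
#' Giemsa convention is dark chromosomes on a light background;
#' `invert = TRUE` flips it.
#'
#' @slot imageSize integer, pixels per side of the square canvas.
#' @slot nChromosomes integer, chromosomes to place (46 in a normal human
#'   metaphase).
#' @slot nDicentric integer, how many of them carry two centromeres.
#' @slot lengthRange numeric(2), chromosome length range in pixels.
#' @slot widthRange numeric(2), chromosome width range in pixels.
#' @slot constrictionDepth numeric in (0, 1), fraction of the width removed
#'   at a centromere.
#' @slot curvatureRange numeric(2), bend of the medial axis in radians.
#' @slot intensityForeground numeric gray level (0-255) of the chromatin.
#' @slot intensityBackground numeric gray level (0-255) of the slide.
#' @slot noiseSd numeric, standard deviation of the additive Gaussian noise
#'   in gray levels.
#' @slot minGap integer, minimum pixel gap enforced between placed
#'   chromosomes.
#' @slot invert logical, render light-on-dark instead of the Giemsa
#'   dark-on-light convention.
#' @slot seed integer, RNG seed recorded with the scene.
#' @export
setClass("SceneSpec",
  representation(imageSize = "integer", nChromosomes = "integer",
                 nDicentric = "integer", lengthRange = "numeric",
                 widthRange = "numeric", constrictionDepth = "numeric",
                 curvatureRange = "numeric", intensityForeground = "numeric",
                 intensityBackground = "numeric", noiseSd = "numeric",
                 minGap = "integer", invert = "logical", seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16")
  if (object@nChromosomes < 0L) msg <- c(msg, "nChromosomes must be >= 0")
  if (object@nDicentric < 0L || object@nDicentric > object@nChromosomes)
    msg <- c(msg, "nDicentric must be in [0, nChromosomes]")
  if (any(object@lengthRange <= 0) || any(object@widthRange <= 0))
    msg <- c(msg, "length and width ranges must be positive")
  if (diff(object@lengthRange) < 0 || diff(object@widthRange) < 0)
    msg <- c(msg, "ranges must be ordered (min, max)")
  if (min(object@lengthRange) <= max(object@widthRange))
    msg <- c(msg, "chromosomes must be elongated: min length > max width")
  if (object@constrictionDepth <= 0 || object@constrictionDepth >= 1)
    msg <- c(msg, "constrictionDepth must be in (0, 1)")
  if (object@minGap < 0L) msg <- c(msg, "minGap must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@invert &&
      object@intensityForeground >= object@intensityBackground)
    msg <- c(msg, "foreground must be darker than background (Giemsa); set invert = TRUE otherwise")
  if (any(c(object@intensityForeground, object@intensityBackground) < 0) ||
      any(c(object@intensityForeground, object@intensityBackground) > 255))
    msg <- c(msg, "intensities must be gray levels in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Construct a scene specification
#'
#' Defaults describe a 640x640 spread with 46 chromosomes, the normal human
#' complement, at a scale where a mid-sized chromosome is roughly 60 pixels
#' long. `deskSceneSpec()` is a scaled-down 320-pixel preset used for fast
#' desk experiments and training demos.
#'
#' @param imageSize pixels per side (default 640).
#' @param nChromosomes chromosomes per metaphase (default 46).
#' @param nDicentric number of dicentric chromosomes (default 0).
#' @param lengthRange,widthRange geometry ranges in pixels.
#' @param constrictionDepth fraction of width removed at a centromere.
#' @param curvatureRange bend range in radians.
#' @param intensityForeground,intensityBackground gray levels in 0-255.
#' @param noiseSd additive Gaussian noise SD in gray levels.
#' @param minGap minimum pixel gap between chromosomes.
#' @param invert light-on-dark rendering if TRUE.
#' @param seed RNG seed recorded in the spec.
#' @return A [SceneSpec-class] object.
#' @examples
#' spec <- sceneSpec(nDicentric = 1, seed = 7)
#' spec
#' @export
sceneSpec <- function(imageSize = 640, nChromosomes = 46, nDicentric = 0,
                      lengthRange = c(40, 90), widthRange = c(10, 16),
                      constrictionDepth = 0.55, curvatureRange = c(0, 0.9),
                      intensityForeground = 60, intensityBackground = 220,
                      noiseSd = 6, minGap = 2, invert = FALSE, seed = 1L) {
  new("SceneSpec", imageSize = as.integer(imageSize),
      nChromosomes = as.integer(nChromosomes),
      nDicentric = as.integer(nDicentric),
      lengthRange = as.numeric(lengthRange),
      widthRange = as.numeric(widthRange),
      constrictionDepth = as.numeric(constrictionDepth),
      curvatureRange = as.numeric(curvatureRange),
      intensityForeground = as.numeric(intensityForeground),
      intensityBackground = as.numeric(intensityBackground),
      noiseSd = as.numeric(noiseSd), minGap = as.integer(minGap),
      invert = isTRUE(invert), seed = as.integer(seed))
}

#' @rdname sceneSpec
#' @param ... overrides passed on to [sceneSpec()].
#' @export
deskSceneSpec <- function(...) {
  args <- list(imageSize = 320, nChromosomes = 12, nDicentric = 3,
               lengthRange = c(28, 44), widthRange = c(9, 13),
               noiseSd = 5, minGap = 3)
  args[names(list(...))] <- list(...)
  do.call(sceneSpec, args)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px, %d chromosomes (%d dicentric), seed %d\n",
              object@imageSize, object@imageSize, object@nChromosomes,
              object@nDicentric, object@seed))
  cat(sprintf("  length %g-%g px, width %g-%g px, constriction %.2f, curvature %g-%g rad\n",
              object@lengthRange[1], object@lengthRange[2],
              object@widthRange[1], object@widthRange[2],
              object@constrictionDepth, object@curvatureRange[1],
              object@curvatureRange[2]))
  cat(sprintf("  gray fg %g / bg %g, noise sd %g, min gap %d px%s\n",
              object@intensityForeground, object@intensityBackground,
              object@noiseSd, object@minGap,
              if (object@invert) ", inverted" else ""))
})

#' Synthetic metaphase sample with exact ground truth
#'
#' Holds one rendered metaphase image together with its ground truth: the
#' bounding-box table and a per-pixel instance label matrix (0 = background,
#' k = pixel belongs to chromosome k, in box order). Because every pixel
#' carries at most one instance id, placed chromosomes are overlap-free by
#' construction.
#'
#' @slot image numeric matrix of gray levels in \[0, 255\]; rows are y,
#'   columns are x.
#' @slot boxes data.frame of ground-truth boxes (see [emptyBoxes()]).
#' @slot labels integer matrix, same shape as `image`, instance ids.
#' @slot spec the [SceneSpec-class] the sample was generated from.
#' @seealso [generateMetaphase()], [sampleMasks()]
#' @export
setClass("MetaphaseSample",
  representation(image = "matrix", boxes = "data.frame",
                 labels = "matrix", spec = "SceneSpec"))

setValidity("MetaphaseSample", function(object) {
  msg <- character(0)
  if (!all(dim(object@image) == dim(object@labels)))
    msg <- c(msg, "image and labels must have identical dimensions")
  if (min(object@image) < 0 || max(object@image) > 255)
    msg <- c(msg, "image gray levels must lie in [0, 255]")
  n <- nrow(object@boxes)
  lab <- object@labels
  if (length(lab) && max(lab) > n)
    msg <- c(msg, "label matrix refers to more instances than boxes")
  ok <- tryCatch({validateBoxes(object@boxes, dim(object@image)[c(2, 1)]); TRUE},
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (length(msg)) msg else TRUE
})

setMethod("show", "MetaphaseSample", function(object) {
  d <- dim(object@image)
  cat(sprintf("MetaphaseSample: %dx%d px, %d boxes (%d dicentric)\n",
              d[2], d[1], nrow(object@boxes),
              sum(object@boxes$class_id == 1L)))
})

#' @describeIn MetaphaseSample-class the image matrix.
#' @param x a `MetaphaseSample`.
#' @export
sampleImage <- function(x) x@image

#' @describeIn MetaphaseSample-class the ground-truth box table.
#' @export
sampleBoxes <- function(x) x@boxes

#' @describeIn MetaphaseSample-class the instance label matrix.
#' @export
sampleLabels <- function(x) x@labels

#' @describeIn MetaphaseSample-class per-chromosome binary masks, cropped to
#'   each box, as a list of logical matrices.
#' @export
sampleMasks <- function(x) {
  b <- x@boxes
  lapply(seq_len(nrow(b)), function(k) {
    rows <- (b$y_min[k] + 1):b$y_max[k]
    cols <- (b$x_min[k] + 1):b$x_max[k]
    x@labels[rows, cols, drop = FALSE] == k
  })
}

#' Segmented chromosome patch for copy-paste augmentation
#'
#' A tight crop of one chromosome with a binary transparency mask
#' (TRUE = chromatin). Only mask pixels are composited when the patch is
#' pasted into an image, so the patch carries no rectangular background
#' imprint.
#'
#' @slot image numeric matrix, the gray-level crop.
#' @slot mask logical matrix, same shape, the foreground.
#' @slot classId integer, 0 normal / 1 dicentric.
#' @slot source character, provenance note.
#' @seealso [extractPatch()], [pastePatch()]
#' @export
setClass("ChromosomePatch",
  representation(image = "matrix", mask = "matrix", classId = "integer",
                 source = "character"))

setValidity("ChromosomePatch", function(object) {
  msg <- character(0)
  if (!all(dim(object@image) == dim(object@mask)))
    msg <- c(msg, "image and mask must have identical dimensions")
  if (!any(object@mask)) msg <- c(msg, "mask must be nonempty")
  rr <- range(which(rowSums(object@mask) > 0))
  cc <- range(which(colSums(object@mask) > 0))
  if (rr[1] != 1L || cc[1] != 1L || rr[2] != nrow(object@mask) ||
      cc[2] != ncol(object@mask))
    msg <- c(msg, "crop must be tight around the mask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ChromosomePatch", function(object) {
  cat(sprintf("ChromosomePatch: %dx%d px, class %d (%s), %d fg pixels\n",
              ncol(object@image), nrow(object@image), object@classId,
              if (object@classId == 1L) "dicentric" else "normal",
              sum(object@mask)))
})

#' Anchor priors for the one-stage detector
#'
#' Anchor (width, height) priors per detection scale, estimated by k-means
#' on the training boxes under the IoU distance. Predictions are decoded as
#' offsets of a grid cell and log-scalings of these priors.
#'
#' @slot anchors list of numeric matrices, one per scale, columns w and h in
#'   input pixels, rows = anchors per cell.
#' @slot strides integer vector, pixels per grid cell at each scale.
#' @slot inputSize integer, square network input size in pixels.
#' @seealso [kmeansAnchors()], [decodeBox()]
#' @export
setClass("AnchorSet",
  representation(anchors = "list", strides = "integer", inputSize = "integer"))

setValidity("AnchorSet", function(object) {
  msg <- character(0)
  if (length(object@anchors) != length(object@strides))
    msg <- c(msg, "one anchor matrix per stride required")
  for (a in object@anchors) {
    if (!is.matrix(a) || ncol(a) != 2 || any(a <= 0))
      msg <- c(msg, "each anchor matrix needs positive w, h columns")
  }
  if (any(object@strides <= 0L)) msg <- c(msg, "strides must be positive")
  if (any(object@inputSize %% object@strides != 0L))
    msg <- c(msg, "inputSize must be divisible by every stride")
  if (length(msg)) msg else TRUE
})

#' @rdname AnchorSet-class
#' @param anchors list of w/h matrices, one per scale.
#' @param strides integer vector of strides.
#' @param inputSize network input size in pixels.
#' @export
anchorSet <- function(anchors, strides, inputSize) {
  anchors <- lapply(anchors, function(a) {
    a <- matrix(as.numeric(a), ncol = 2,
                dimnames = list(NULL, c("w", "h")))
    a
  })
  new("AnchorSet", anchors = anchors, strides = as.integer(strides),
      inputSize = as.integer(inputSize))
}

setMethod("show", "AnchorSet", function(object) {
  cat(sprintf("AnchorSet: input %d px, %d scale(s)\n", object@inputSize,
              length(object@strides)))
  for (s in seq_along(object@strides)) {
    a <- object@anchors[[s]]
    cat(sprintf("  stride %2d (grid %d): %s\n", object@strides[s],
                object@inputSize %/% object@strides[s],
                paste(sprintf("%.1fx%.1f", a[, 1], a[, 2]), collapse = ", ")))
  }
})

#' Compact anchor-based one-stage chromosome detector
#'
#' A small fully-convolutional detector: a strided convolutional backbone
#' producing feature maps at two strides, each followed by a convolutional
#' head that predicts, for every (grid cell, anchor) slot, the box offsets
#' (t_x, t_y, t_w, t_h), an objectness logit and per-class logits. Weights
#' live in ordinary R arrays; the convolution forward/backward passes run in
#' compiled code.
#'
#' @slot config list describing the layer topology and head layout.
#' @slot weights list of per-layer weight matrices and bias vectors.
#' @slot anchors the [AnchorSet-class] the model decodes against.
#' @slot nClasses integer number of object classes (2: normal, dicentric).
#' @seealso [chromosomeDetector()], [trainDetector()], [predictDetections()]
#' @export
setClass("ChromosomeDetector",
  representation(config = "list", weights = "list", anchors = "AnchorSet",
                 nClasses = "integer"))

setMethod("show", "ChromosomeDetector", function(object) {
  np <- sum(vapply(object@weights, function(w) length(w$W) + length(w$b), 0))
  cat(sprintf("ChromosomeDetector: input %d px, %d classes, %d layers, %s parameters\n",
              object@anchors@inputSize, object@nClasses,
              length(object@config$layers), format(np, big.mark = ",")))
  show(object@anchors)
})

#' @describeIn ChromosomeDetector-class number of trainable parameters.
#' @param object a `ChromosomeDetector`.
#' @export
nParameters <- function(object) {
  sum(vapply(object@weights, function(w) length(w$W) + length(w$b), 0))
}

#' Linear-quadratic dose-response model
#'
#' The cytogenetic dose-response model F(D) = alpha D^2 + beta D + gamma
#' linking the dicentric frequency per cell F to the absorbed dose D in
#' gray. `gamma` is the background frequency (about 1 per 1000 cells in
#' unexposed populations).
#'
#' @slot alpha numeric, dicentrics per cell per Gy^2.
#' @slot beta numeric, dicentrics per cell per Gy.
#' @slot gamma numeric, background dicentrics per cell.
#' @slot cov numeric matrix, covariance of the estimates (may be 0x0 when
#'   the model was specified rather than fitted).
#' @seealso [fitDoseResponse()], [estimateDose()], [doseResponse()]
#' @export
setClass("DoseResponseModel",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 cov = "matrix"))

setValidity("DoseResponseModel", function(object) {
  msg <- character(0)
  if (object@gamma < 0) msg <- c(msg, "gamma (background frequency) must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DoseResponseModel-class
#' @param alpha,beta,gamma model coefficients.
#' @param cov optional covariance matrix of the coefficients.
#' @export
doseResponseModel <- function(alpha, beta, gamma, cov = matrix(0, 0, 0)) {
  new("DoseResponseModel", alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), cov = cov)
}

setMethod("show", "DoseResponseModel", function(object) {
  cat(sprintf("DoseResponseModel: F(D) = %.4g D^2 + %.4g D + %.4g  [dicentrics/cell, D in Gy]\n",
              object@alpha, object@beta, object@gamma))
})

#' @describeIn DoseResponseModel-class predicted dicentric frequency F(D).
#' @param model a `DoseResponseModel`.
#' @param dose absorbed dose in Gy (vectorized).
#' @export
doseResponse <- function(model, dose) {
  model@alpha * dose^2 + model@beta * dose + model@gamma
}
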