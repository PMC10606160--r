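## R-side network plumbing: model construction, head tensor reshaping,
## decoding of raw head outputs into detections.

## (C x HW) activation (pixel q = y*W + x) -> (H, W, C) array and back.
headToArray <- function(A, H, W) {
  aperm(array(t(A), c(W, H, nrow(A))), c(2, 1, 3))
}
arrayToHead <- function(a) {
  d <- dim(a)
  t(matrix(aperm(a, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3]))
}
imageToInput <- function(image) {
  matrix(as.numeric(t(image)) / 255, nrow = 1)
}

defaultAnchors <- function(inputSize = 320L) {
  anchorSet(list(rbind(c(14, 14), c(28, 14), c(14, 28)),
                 rbind(c(36, 18), c(18, 36), c(34, 34))),
            strides = c(8L, 16L), inputSize = inputSize)
}

#' Construct a compact one-stage chromosome detector
#'
#' Builds the detector: a strided 3x3 convolutional backbone with
#' leaky-ReLU activations feeding two convolutional heads at strides 8 and
#' 16. Each head predicts, per (cell, anchor) slot, the 4 box offsets, an
#' objectness logit and one logit per class. Weights are He-initialized;
#' objectness biases start at -4 so the untrained model predicts a low
#' object prior, which stabilizes early training against the huge majority
#' of empty slots. About 38,000 parameters at the default widths.
#'
#' @param anchors an [AnchorSet-class]; default anchors cover the desk
#'   preset's chromosome sizes. Use [kmeansAnchorSet()] on training boxes
#'   for a fitted prior.
#' @param nClasses number of classes (default 2).
#' @param widths channel widths of the four backbone stages.
#' @param seed RNG seed for the weight initialization.
#' @param init optional path to a saved detector whose weights initialize
#'   this one (layer shapes must match) — the fine-tuning entry point for
#'   externally pretrained weights.
#' @return A [ChromosomeDetector-class].
#' @export
chromosomeDetector <- function(anchors = defaultAnchors(), nClasses = 2L,
                               widths = c(8L, 16L, 24L, 32L), seed = 1L,
                               init = NULL) {
  stopifnot(length(anchors@strides) == 2L)
  B <- vapply(anchors@anchors, nrow, 0L)
  headCh <- B * (5L + nClasses)
  w <- widths
  layers <- list(
    list(`in` = 1L,   out = w[1], k = 3L, stride = 2L, input = 0L, lrelu = TRUE),
    list(`in` = w[1], out = w[2], k = 3L, stride = 2L, input = 1L, lrelu = TRUE),
    list(`in` = w[2], out = w[3], k = 3L, stride = 2L, input = 2L, lrelu = TRUE),
    list(`in` = w[3], out = w[3], k = 3L, stride = 1L, input = 3L, lrelu = TRUE),
    list(`in` = w[3], out = w[3], k = 3L, stride = 1L, input = 4L, lrelu = TRUE),
    list(`in` = w[3], out = w[3], k = 3L, stride = 1L, input = 5L, lrelu = TRUE),
    list(`in` = w[3], out = headCh[1], k = 1L, stride = 1L, input = 6L,
         lrelu = FALSE),
    list(`in` = w[3], out = w[4], k = 3L, stride = 2L, input = 3L, lrelu = TRUE),
    list(`in` = w[4], out = w[4], k = 3L, stride = 1L, input = 8L, lrelu = TRUE),
    list(`in` = w[4], out = headCh[2], k = 1L, stride = 1L, input = 9L,
         lrelu = FALSE))
  heads <- c(7L, 10L)
  set.seed(seed)
  weights <- lapply(layers, function(l) {
    fanIn <- l$`in` * l$k^2
    list(W = matrix(rnorm(l$out * fanIn, 0, sqrt(2 / fanIn)), l$out, fanIn),
         b = rep(0, l$out))
  })
  for (s in 1:2) {
    step <- 5L + nClasses
    objCh <- (seq_len(B[s]) - 1L) * step + 5L
    boxCh <- as.vector(outer(1:4, (seq_len(B[s]) - 1L) * step, `+`))
    weights[[heads[s]]]$b[objCh] <- -4    # low objectness prior at init
    weights[[heads[s]]]$W[boxCh, ] <-     # near-anchor boxes at init
      weights[[heads[s]]]$W[boxCh, ] * 0.1
  }
  model <- new("ChromosomeDetector",
               config = list(layers = layers, heads = heads,
                             widths = widths, seed = seed),
               weights = weights, anchors = anchors,
               nClasses = as.integer(nClasses))
  if (!is.null(init)) {
    ref <- loadDetector(init)
    for (i in seq_along(model@weights)) {
      if (!all(dim(ref@weights[[i]]$W) == dim(model@weights[[i]]$W)))
        stop("init weights have incompatible layer shapes", call. = FALSE)
    }
    model@weights <- ref@weights
  }
  model
}

#' Save or load a detector checkpoint
#'
#' A checkpoint is a single RDS file holding the layer configuration,
#' weights, anchors and class count.
#'
#' @param model a [ChromosomeDetector-class].
#' @param path checkpoint file path.
#' @return `loadDetector()` returns the model; `saveDetector()` the path,
#'   invisibly.
#' @export
saveDetector <- function(model, path) {
  saveRDS(list(config = model@config, weights = model@weights,
               anchors = list(anchors = model@anchors@anchors,
                              strides = model@anchors@strides,
                              inputSize = model@anchors@inputSize),
               nClasses = model@nClasses), path)
  invisible(path)
}

#' @rdname saveDetector
#' @export
loadDetector <- function(path) {
  x <- readRDS(path)
  new("ChromosomeDetector", config = x$config, weights = x$weights,
      anchors = anchorSet(x$anchors$anchors, x$anchors$strides,
                          x$anchors$inputSize),
      nClasses = x$nClasses)
}

## Forward pass returning the two head tensors as (S, S, B*(5+C)) arrays.
forwardHeads <- function(model, image) {
  sz <- model@anchors@inputSize
  st <- net_forward(model@weights, model@config$layers,
                    imageToInput(image), sz, sz, TRUE)
  lapply(seq_along(model@config$heads), function(s) {
    i <- model@config$heads[s] + 1L       # acts[[1]] is the input image
    headToArray(st$acts[[i]], st$H[i], st$W[i])
  })
}

## Decode one head tensor into a detection table (input-pixel coordinates).
decodeHead <- function(head, anchors, stride, nClasses,
                       confThreshold = 0.001) {
  S <- dim(head)[1]
  B <- nrow(anchors)
  step <- 5L + nClasses
  out <- vector("list", B)
  cellX <- matrix(rep(0:(S - 1), each = S), S, S)   # column index
  cellY <- matrix(rep(0:(S - 1), times = S), S, S)  # row index
  for (b in seq_len(B)) {
    off <- (b - 1L) * step
    conf <- sigmoid(head[, , off + 5L])
    probs <- array(sigmoid(head[, , off + 5L + seq_len(nClasses)]),
                   c(S, S, nClasses))
    pmax <- apply(probs, c(1, 2), max)
    score <- conf * pmax
    sel <- which(score >= confThreshold)
    if (!length(sel)) { out[[b]] <- NULL; next }
    t4 <- cbind(head[, , off + 1L][sel], head[, , off + 2L][sel],
                head[, , off + 3L][sel], head[, , off + 4L][sel])
    dec <- decodeBox(t4, cbind(cellX[sel], cellY[sel]),
                     anchors[b, , drop = FALSE], stride)
    cls <- max.col(matrix(probs, S * S, nClasses)[sel, , drop = FALSE],
                   ties.method = "first") - 1L
    out[[b]] <- data.frame(x_min = dec$x_min, y_min = dec$y_min,
                           x_max = dec$x_max, y_max = dec$y_max,
                           class_id = cls, score = score[sel],
                           confidence = conf[sel])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(emptyBoxes(), score = numeric(0), confidence = numeric(0))
  res
}

#' Run the detector on an image
#'
#' Resizes the image to the model's input size if needed (with a warning),
#' runs the forward pass, decodes every (cell, anchor) slot against its
#' anchor prior, scores each candidate as objectness x best class
#' probability, drops candidates below `confThreshold`, applies per-class
#' [nms()], and maps the surviving boxes back to the original pixel frame,
#' clipped to the image.
#'
#' @param model a [ChromosomeDetector-class].
#' @param image numeric gray-level matrix.
#' @param confThreshold minimum score to keep (default 0.25).
#' @param nmsThreshold NMS IoU threshold (default 0.45).
#' @param nmsPerClass suppress within classes only (default TRUE);
#'   FALSE treats strong overlaps as duplicates regardless of class.
#' @return detection data.frame: box columns, `class_id`, `score`,
#'   `confidence`.
#' @export
predictDetections <- function(model, image, confThreshold = 0.25,
                              nmsThreshold = 0.45, nmsPerClass = TRUE) {
  sz <- model@anchors@inputSize
  h <- nrow(image); w <- ncol(image)
  if (h != sz || w != sz) {
    warning("resizing ", w, "x", h, " image to the network input size ",
            sz, "x", sz)
    image <- resizeWithBoxes(image, target = sz)$image
  }
  heads <- forwardHeads(model, image)
  det <- do.call(rbind, lapply(seq_along(heads), function(s)
    decodeHead(heads[[s]], model@anchors@anchors[[s]],
               model@anchors@strides[s], model@nClasses,
               confThreshold)))
  det <- det[det$score >= confThreshold, , drop = FALSE]
  if (nrow(det)) {
    det$x_min <- pmax(det$x_min, 0); det$y_min <- pmax(det$y_min, 0)
    det$x_max <- pmin(det$x_max, sz); det$y_max <- pmin(det$y_max, sz)
    det <- det[det$x_max - det$x_min >= 1 & det$y_max - det$y_min >= 1, ,
               drop = FALSE]
    det <- nms(det, nmsThreshold, perClass = nmsPerClass)
    det$x_min <- det$x_min * w / sz; det$x_max <- det$x_max * w / sz
    det$y_min <- det$y_min * h / sz; det$y_max <- det$y_max * h / sz
  }
  rownames(det) <- NULL
  det
}
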