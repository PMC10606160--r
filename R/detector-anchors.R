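## Anchor estimation, ground-truth-to-grid assignment and non-maximum
## suppression for the one-stage detector.

## IoU between (w, h) pairs placed concentric at the origin.
whIoU <- function(wh, centroids) {
  inter <- outer(wh[, 1], centroids[, 1], pmin) *
    outer(wh[, 2], centroids[, 2], pmin)
  areaA <- wh[, 1] * wh[, 2]
  areaB <- centroids[, 1] * centroids[, 2]
  inter / (outer(areaA, areaB, `+`) - inter)
}

#' Estimate anchor priors by k-means under the IoU distance
#'
#' Clusters the (width, height) of training boxes with k-means using
#' `d(box, centroid) = 1 - IoU` as the distance, both boxes placed
#' concentric, the standard way anchor priors are chosen for grid
#' detectors. Centroid updates are the per-cluster mean width/height; the
#' mean distance is non-increasing across iterations. Centroids are
#' returned sorted by area (ascending), so that small anchors go to the
#' fine-stride scale.
#'
#' @param boxes corner-form box table/matrix, or a two-column (w, h) matrix.
#' @param k number of anchors.
#' @param maxIters iteration cap (default 100).
#' @param seed RNG seed for the initial centroid draw.
#' @return list with `centroids` (k x 2 matrix, columns w, h, sorted by
#'   area), `meanIoU`, and `objective` (mean 1 - IoU per iteration).
#' @export
kmeansAnchors <- function(boxes, k, maxIters = 100, seed = 1L) {
  wh <- as.whMatrix(boxes)
  if (nrow(wh) < k) stop("need at least k boxes", call. = FALSE)
  if (nrow(unique(round(wh, 10))) < k)
    stop("fewer than k distinct box dimensions", call. = FALSE)
  set.seed(seed)
  centroids <- wh[sample(seq_len(nrow(wh)), k), , drop = FALSE]
  while (nrow(unique(centroids)) < k) {     # re-draw colliding initials
    dup <- duplicated(centroids)
    centroids[dup, ] <- wh[sample(seq_len(nrow(wh)), sum(dup)), , drop = FALSE]
  }
  objective <- numeric(0)
  assign <- rep(0L, nrow(wh))
  prev <- centroids
  for (it in seq_len(maxIters)) {
    d <- 1 - whIoU(wh, centroids)
    newAssign <- max.col(-d, ties.method = "first")
    obj <- mean(d[cbind(seq_len(nrow(wh)), newAssign)])
    if (length(objective) && obj > tail(objective, 1) + 1e-12) {
      centroids <- prev            # mean update overshot; keep the best
      break
    }
    objective <- c(objective, obj)
    if (all(newAssign == assign) && it > 1L) break
    assign <- newAssign
    prev <- centroids
    for (j in seq_len(k)) {
      members <- wh[assign == j, , drop = FALSE]
      if (nrow(members)) {
        centroids[j, ] <- colMeans(members)
      } else {                              # re-seed empty cluster at the worst box
        worst <- which.max(d[cbind(seq_len(nrow(wh)), assign)])
        centroids[j, ] <- wh[worst, ]
      }
    }
  }
  ord <- order(centroids[, 1] * centroids[, 2])
  centroids <- centroids[ord, , drop = FALSE]
  colnames(centroids) <- c("w", "h")
  d <- 1 - whIoU(wh, centroids)
  list(centroids = centroids,
       meanIoU = mean(1 - d[cbind(seq_len(nrow(wh)),
                                  max.col(-d, ties.method = "first"))]),
       objective = objective)
}

as.whMatrix <- function(boxes) {
  if (is.data.frame(boxes) && all(c("x_min", "x_max") %in% names(boxes))) {
    cbind(boxes$x_max - boxes$x_min, boxes$y_max - boxes$y_min)
  } else {
    m <- as.matrix(boxes)
    if (ncol(m) == 4) cbind(m[, 3] - m[, 1], m[, 4] - m[, 2]) else m[, 1:2]
  }
}

#' Build an AnchorSet from training boxes
#'
#' Runs [kmeansAnchors()] with `k = perScale * length(strides)` and
#' distributes the area-sorted centroids across the detection scales,
#' smallest anchors to the smallest stride.
#'
#' @param boxes training boxes (corner form or w/h matrix), in input-image
#'   pixels.
#' @param strides integer vector of scale strides (default `c(8, 16)`).
#' @param perScale anchors per grid cell at each scale (default 3).
#' @param inputSize network input size in pixels.
#' @param seed RNG seed for the clustering.
#' @return An [AnchorSet-class].
#' @export
kmeansAnchorSet <- function(boxes, strides = c(8L, 16L), perScale = 3L,
                            inputSize = 320L, seed = 1L) {
  k <- perScale * length(strides)
  km <- kmeansAnchors(boxes, k, seed = seed)
  split <- lapply(seq_along(strides), function(s)
    km$centroids[((s - 1) * perScale + 1):(s * perScale), , drop = FALSE])
  anchorSet(split, strides, inputSize)
}

#' Assign ground-truth boxes to grid cells and anchors
#'
#' For each detection scale the input image is divided into an S x S grid
#' (S = inputSize / stride) with B anchors per cell; the network predicts
#' one candidate box per (cell, anchor) slot. Each ground-truth box is
#' assigned, at every scale, to the cell containing its center and to the
#' anchor of highest concentric IoU with its width/height. If that slot is
#' already taken by another ground truth, the next-best free anchor in the
#' cell is used; if the whole cell is taken at one scale the box is simply
#' not assigned there (it keeps its slot at the other scales).
#'
#' Slot arrays are dimensioned (row = grid y, column = grid x, anchor) and
#' flattened in R's column-major order everywhere a flat slot vector is
#' used.
#'
#' @param gtBoxes ground-truth box table (see [emptyBoxes()]), coordinates
#'   in input-image pixels.
#' @param anchors an [AnchorSet-class].
#' @param nClasses number of classes (default 2).
#' @return list with per-scale lists `objectness` (S x S x B 0/1 arrays),
#'   `classTargets` (S^2 B x nClasses one-hot matrices), `slots`
#'   (data.frame per scale: `cell_x`, `cell_y`, `anchor`, box corners,
#'   `class_id`, `gt_id`, `slot` = flat index), plus `gridSizes` and the
#'   `anchors` used.
#' @export
assignTargets <- function(gtBoxes, anchors, nClasses = 2L) {
  validateBoxes(gtBoxes, rep(anchors@inputSize, 2), "gtBoxes")
  cx <- (gtBoxes$x_min + gtBoxes$x_max) / 2
  cy <- (gtBoxes$y_min + gtBoxes$y_max) / 2
  if (nrow(gtBoxes) &&
      (any(cx < 0) || any(cx >= anchors@inputSize) ||
       any(cy < 0) || any(cy >= anchors@inputSize)))
    stop("ground-truth box center outside the image", call. = FALSE)
  wh <- cbind(gtBoxes$x_max - gtBoxes$x_min, gtBoxes$y_max - gtBoxes$y_min)
  nScales <- length(anchors@strides)
  objectness <- classTargets <- slots <- vector("list", nScales)
  gridSizes <- integer(nScales)
  for (s in seq_len(nScales)) {
    S <- anchors@inputSize %/% anchors@strides[s]
    B <- nrow(anchors@anchors[[s]])
    gridSizes[s] <- S
    obj <- array(0, c(S, S, B))
    cls <- matrix(0, S * S * B, nClasses)
    rows <- list()
    if (nrow(gtBoxes)) {
      iouA <- whIoU(wh, anchors@anchors[[s]])
      stride <- anchors@strides[s]
      gx <- pmin(floor(cx / stride), S - 1)
      gy <- pmin(floor(cy / stride), S - 1)
      for (g in seq_len(nrow(gtBoxes))) {
        pref <- order(iouA[g, ], decreasing = TRUE)
        for (b in pref) {
          if (obj[gy[g] + 1, gx[g] + 1, b] == 0) {
            obj[gy[g] + 1, gx[g] + 1, b] <- 1
            flat <- (gy[g] + 1) + gx[g] * S + (b - 1) * S * S
            cls[flat, gtBoxes$class_id[g] + 1L] <- 1
            rows[[length(rows) + 1L]] <- data.frame(
              cell_x = gx[g], cell_y = gy[g], anchor = b,
              x_min = gtBoxes$x_min[g], y_min = gtBoxes$y_min[g],
              x_max = gtBoxes$x_max[g], y_max = gtBoxes$y_max[g],
              class_id = gtBoxes$class_id[g], gt_id = g, slot = flat)
            break
          }
        }
      }
    }
    objectness[[s]] <- obj
    classTargets[[s]] <- cls
    slots[[s]] <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cell_x = integer(0), cell_y = integer(0),
                 anchor = integer(0), x_min = numeric(0), y_min = numeric(0),
                 x_max = numeric(0), y_max = numeric(0),
                 class_id = integer(0), gt_id = integer(0), slot = integer(0))
  }
  list(objectness = objectness, classTargets = classTargets, slots = slots,
       gridSizes = gridSizes, anchors = anchors, nClasses = nClasses)
}

#' Non-maximum suppression
#'
#' Drops detections below the confidence threshold, then greedily keeps the
#' highest-confidence box and suppresses all remaining boxes of the same
#' class whose IoU with it exceeds `iouThreshold`, repeating until no box
#' is left. Confidence ties are broken by input order.
#'
#' @param detections data.frame with box columns, `class_id` and `score`.
#' @param iouThreshold suppression IoU threshold in \[0, 1\] (default 0.45).
#' @param confThreshold minimum score to keep (default 0).
#' @param perClass suppress within classes only (default TRUE).
#' @return the surviving rows, ordered by decreasing score.
#' @export
nms <- function(detections, iouThreshold = 0.45, confThreshold = 0,
                perClass = TRUE) {
  stopifnot(iouThreshold >= 0, iouThreshold <= 1,
            confThreshold >= 0, confThreshold <= 1)
  if (!nrow(detections)) return(detections)
  d <- detections[detections$score >= confThreshold, , drop = FALSE]
  if (!nrow(d)) return(d)
  ord <- order(-d$score, seq_len(nrow(d)))
  d <- d[ord, , drop = FALSE]
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  bm <- boxMatrix(d)
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    later <- which(alive & seq_len(nrow(d)) > i)
    if (!length(later)) next
    if (perClass) later <- later[d$class_id[later] == d$class_id[i]]
    if (!length(later)) next
    ious <- boxIoU(bm[i, , drop = FALSE], bm[later, , drop = FALSE])
    alive[later[ious > iouThreshold]] <- FALSE
  }
  d[keep, , drop = FALSE]
}
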