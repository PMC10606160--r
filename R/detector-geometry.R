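## Box geometry and the detector's loss primitives. Boxes are corner-form
## (x_min, y_min, x_max, y_max) in pixels unless a function says otherwise.

#' Intersection over union of axis-aligned boxes
#'
#' Computes IoU between two sets of boxes, elementwise after recycling a
#' single box against the other set. Boxes are corner-form vectors
#' `c(x_min, y_min, x_max, y_max)` or data.frames/matrices with those
#' columns. Disjoint boxes score 0; identical boxes score 1.
#'
#' @param a,b boxes (vector, matrix or data.frame).
#' @return numeric vector of IoU values in \[0, 1\].
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- boxMatrix(a); b <- boxMatrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (any(a[, 3] <= a[, 1]) || any(a[, 4] <= a[, 2]) ||
      any(b[, 3] <= b[, 1]) || any(b[, 4] <= b[, 2]))
    stop("boxIoU: degenerate (zero-area) box", call. = FALSE)
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (areaA + areaB - inter)
}

boxMatrix <- function(x) {
  if (is.data.frame(x))
    x <- as.matrix(x[, c("x_min", "y_min", "x_max", "y_max")])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

## Pairwise IoU matrix between two box sets (n x m).
boxIoUMatrix <- function(a, b) {
  a <- boxMatrix(a); b <- boxMatrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  iw <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  ih <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- iw * ih
  areaA <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  areaB <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(areaA, areaB, `+`) - inter)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Decode raw network outputs into a bounding box
#'
#' Transforms the raw per-slot outputs (t_x, t_y, t_w, t_h) into box
#' geometry: the center is the cell origin plus a sigmoid offset, the size
#' is the anchor prior scaled by exp of the output,
#' \deqn{b_x = \sigma(t_x) + C_x,\; b_y = \sigma(t_y) + C_y,\;
#'       b_w = p_w e^{t_w},\; b_h = p_h e^{t_h}.}
#' Center coordinates are in grid units and multiplied by the stride to
#' reach pixels; anchor dimensions are already in pixels. `t_w`, `t_h` are
#' clamped to |t| <= 12 so exp cannot overflow.
#'
#' @param t numeric length-4 vector or n x 4 matrix of raw outputs
#'   (t_x, t_y, t_w, t_h).
#' @param cell integer cell coordinates `c(C_x, C_y)` (0-based) or n x 2
#'   matrix.
#' @param anchor anchor prior `c(p_w, p_h)` in pixels or n x 2 matrix.
#' @param stride pixels per grid unit.
#' @return data.frame with center-size (`cx`, `cy`, `w`, `h`, pixels) and
#'   corner (`x_min`, `y_min`, `x_max`, `y_max`) forms.
#' @examples
#' decodeBox(c(0, 0, 0, 0), cell = c(3, 4), anchor = c(10, 20), stride = 8)
#' @export
decodeBox <- function(t, cell, anchor, stride) {
  t <- if (is.null(dim(t))) matrix(t, ncol = 4) else as.matrix(t)
  cell <- if (is.null(dim(cell))) matrix(cell, ncol = 2) else as.matrix(cell)
  anchor <- if (is.null(dim(anchor))) matrix(anchor, ncol = 2) else as.matrix(anchor)
  n <- max(nrow(t), nrow(cell), nrow(anchor))
  rep1 <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  t <- rep1(t); cell <- rep1(cell); anchor <- rep1(anchor)
  if (any(anchor <= 0)) stop("anchor dimensions must be positive", call. = FALSE)
  tw <- pmin(pmax(t[, 3], -12), 12)
  th <- pmin(pmax(t[, 4], -12), 12)
  cx <- (sigmoid(t[, 1]) + cell[, 1]) * stride
  cy <- (sigmoid(t[, 2]) + cell[, 2]) * stride
  w <- anchor[, 1] * exp(tw)
  h <- anchor[, 2] * exp(th)
  data.frame(cx = cx, cy = cy, w = w, h = h,
             x_min = cx - w / 2, y_min = cy - h / 2,
             x_max = cx + w / 2, y_max = cy + h / 2)
}

## Inverse of decodeBox for a box whose center lies strictly inside `cell`.
encodeBox <- function(box, cell, anchor, stride) {
  box <- boxMatrix(box)
  cx <- (box[, 1] + box[, 3]) / 2 / stride
  cy <- (box[, 2] + box[, 4]) / 2 / stride
  fx <- cx - cell[1]; fy <- cy - cell[2]
  if (any(fx <= 0) || any(fx >= 1) || any(fy <= 0) || any(fy >= 1))
    stop("box center does not lie strictly inside the cell", call. = FALSE)
  c(log(fx / (1 - fx)), log(fy / (1 - fy)),
    log((box[, 3] - box[, 1]) / anchor[1]),
    log((box[, 4] - box[, 2]) / anchor[2]))
}

#' Complete-IoU (CIoU) location loss
#'
#' The bounding-box regression loss used for localization: plain IoU
#' augmented with a normalized center-distance penalty and an aspect-ratio
#' consistency penalty,
#' \deqn{L_{loc} = 1 - IoU + \rho^2(b, b^{gt}) / c^2 + \alpha\upsilon,}
#' where \eqn{\rho} is the distance between box centers, \eqn{c} the
#' diagonal of the smallest box enclosing both,
#' \eqn{\upsilon = \frac{4}{\pi^2}(\arctan\frac{w^{gt}}{h^{gt}} -
#' \arctan\frac{w}{h})^2} and \eqn{\alpha = \upsilon / (1 - IoU +
#' \upsilon)}. The loss is 0 exactly when the boxes coincide and is always
#' at least `1 - IoU`.
#'
#' @param pred,gt corner-form boxes (vectors or single-row data.frames).
#' @return list with `loss` and a `terms` list (`iou`, `rho2`, `c2`,
#'   `upsilon`, `alpha`) for inspection.
#' @examples
#' ciouLoss(c(0, 0, 1, 1), c(0, 0, 1, 1))$loss   # 0
#' @export
ciouLoss <- function(pred, gt) {
  p <- boxMatrix(pred); g <- boxMatrix(gt)
  if (nrow(p) != 1L || nrow(g) != 1L)
    stop("ciouLoss compares one pair of boxes", call. = FALSE)
  if (p[3] <= p[1] || p[4] <= p[2] || g[3] <= g[1] || g[4] <= g[2])
    stop("ciouLoss: zero-size box", call. = FALSE)
  iou <- boxIoU(p, g)
  pcx <- (p[1] + p[3]) / 2; pcy <- (p[2] + p[4]) / 2
  gcx <- (g[1] + g[3]) / 2; gcy <- (g[2] + g[4]) / 2
  rho2 <- (pcx - gcx)^2 + (pcy - gcy)^2
  ex <- max(p[3], g[3]) - min(p[1], g[1])
  ey <- max(p[4], g[4]) - min(p[2], g[2])
  c2 <- ex^2 + ey^2
  pw <- p[3] - p[1]; ph <- p[4] - p[2]
  gw <- g[3] - g[1]; gh <- g[4] - g[2]
  upsilon <- 4 / pi^2 * (atan(gw / gh) - atan(pw / ph))^2
  alpha <- if (upsilon == 0) 0 else upsilon / (1 - iou + upsilon)
  list(loss = 1 - iou + rho2 / c2 + alpha * upsilon,
       terms = list(iou = iou, rho2 = rho2, c2 = c2,
                    upsilon = upsilon, alpha = alpha))
}

## Clamped binary cross entropy; y in {0,1} targets, p predicted probability.
bce <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Objectness loss (weighted binary cross entropy)
#'
#' Confidence loss over every (cell, anchor) slot of every scale: the sum of
#' binary cross entropies at object-carrying slots plus `lambdaNoobj` times
#' the sum over object-free slots,
#' \deqn{L_{obj} = \sum_i^{S^2}\sum_j^{B} I^{obj}_{ij}\,
#'   CE(C_i, \hat C_i) + \lambda_{noobj} \sum_i^{S^2}\sum_j^{B}
#'   I^{noobj}_{ij}\, CE(C_i, \hat C_i),}
#' with target confidence C_i = 1 at assigned slots and 0 elsewhere. The
#' down-weighting counters the extreme slot-level class imbalance: almost
#' all of the S^2 B candidate boxes contain no object.
#'
#' @param confidence predicted confidences in \[0, 1\]: a numeric vector or a
#'   list of vectors/arrays, one per scale, matching the assignment layout.
#' @param assignment a [assignTargets()] result (or any list with an
#'   `objectness` element of 0/1 arrays matching `confidence`).
#' @param lambdaNoobj weight of the no-object term (default 0.5).
#' @param eps probability clamp for the logs.
#' @return scalar loss.
#' @examples
#' a <- list(objectness = list(c(1, 0, 0)))
#' objectnessLoss(list(c(0.5, 0.1, 0.1)), a, lambdaNoobj = 0)  # -log(0.5)
#' @export
objectnessLoss <- function(confidence, assignment, lambdaNoobj = 0.5,
                           eps = 1e-7) {
  if (!is.list(confidence)) confidence <- list(confidence)
  ind <- assignment$objectness
  if (length(confidence) != length(ind))
    stop("confidence and assignment disagree on the number of scales",
         call. = FALSE)
  total <- 0
  for (s in seq_along(ind)) {
    io <- as.numeric(ind[[s]]); ph <- as.numeric(confidence[[s]])
    if (length(io) != length(ph))
      stop("confidence and assignment disagree on slot count at scale ", s,
           call. = FALSE)
    e <- bce(io, ph, eps)
    total <- total + sum(e[io == 1]) + lambdaNoobj * sum(e[io == 0])
  }
  total
}

#' Class loss (binary cross entropy at object slots only)
#'
#' Sum over the object-carrying slots of the per-class binary cross entropy
#' between the one-hot target class vector and the predicted class
#' probabilities,
#' \deqn{L_{class} = \sum_i I^{obj}_i \sum_{c \in classes}
#'   CE(p_i(c), \hat p_i(c)).}
#' Slots without an object contribute nothing.
#'
#' @param classProb predicted class probabilities: a numeric matrix
#'   (slots x classes) or a list of such matrices, one per scale, rows
#'   aligned with the flattened assignment slots.
#' @param assignment a [assignTargets()] result.
#' @param eps probability clamp.
#' @return scalar loss.
#' @export
classLoss <- function(classProb, assignment, eps = 1e-7) {
  if (!is.list(classProb)) classProb <- list(classProb)
  ind <- assignment$objectness
  cls <- assignment$classTargets
  if (length(classProb) != length(ind))
    stop("classProb and assignment disagree on the number of scales",
         call. = FALSE)
  total <- 0
  for (s in seq_along(ind)) {
    io <- as.numeric(ind[[s]])
    p <- classProb[[s]]
    if (is.null(dim(p))) p <- matrix(p, nrow = length(io))
    tc <- cls[[s]]
    if (nrow(p) != length(io))
      stop("classProb rows must match assignment slots at scale ", s,
           call. = FALSE)
    obj <- which(io == 1)
    if (!length(obj)) next
    if (ncol(p) != ncol(tc))
      stop("class-count mismatch between predictions and targets",
           call. = FALSE)
    total <- total + sum(bce(tc[obj, , drop = FALSE],
                             p[obj, , drop = FALSE], eps))
  }
  total
}

#' Combined detector loss
#'
#' Weighted sum of the three detector losses: CIoU localization (averaged
#' over assigned slots), objectness and classification. `predictions`
#' mirrors the layout produced by the network head: per scale, decoded boxes
#' for the assigned slots, confidences for all slots, class probabilities
#' for all slots.
#'
#' @param predictions list with elements `boxes` (list per scale: corner-form
#'   matrix for the assigned slots, in assignment row order), `confidence`
#'   (list per scale of all-slot confidences) and `classProb` (list per
#'   scale of all-slot class probability matrices).
#' @param assignment a [assignTargets()] result.
#' @param weights numeric length-3 vector of (location, objectness, class)
#'   weights.
#' @param lambdaNoobj no-object down-weight passed to [objectnessLoss()].
#' @return list with `loc`, `obj`, `cls`, `total`, `weights`, `lambdaNoobj`.
#' @export
totalLoss <- function(predictions, assignment, weights = c(1, 1, 1),
                      lambdaNoobj = 0.5) {
  stopifnot(length(weights) == 3)
  nAssigned <- 0; locSum <- 0
  for (s in seq_along(assignment$slots)) {
    sl <- assignment$slots[[s]]
    if (!nrow(sl)) next
    pb <- boxMatrix(predictions$boxes[[s]])
    if (nrow(pb) != nrow(sl))
      stop("predicted box count must match assigned slots at scale ", s,
           call. = FALSE)
    for (r in seq_len(nrow(sl))) {
      locSum <- locSum + ciouLoss(pb[r, ],
                                  c(sl$x_min[r], sl$y_min[r],
                                    sl$x_max[r], sl$y_max[r]))$loss
      nAssigned <- nAssigned + 1
    }
  }
  loc <- if (nAssigned) locSum / nAssigned else 0
  obj <- objectnessLoss(predictions$confidence, assignment, lambdaNoobj)
  cls <- classLoss(predictions$classProb, assignment)
  list(loc = loc, obj = obj, cls = cls,
       total = weights[1] * loc + weights[2] * obj + weights[3] * cls,
       weights = weights, lambdaNoobj = lambdaNoobj)
}
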