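## Mini-batch SGD training of the detector on the combined CIoU +
## objectness + class loss.

## CIoU loss from a center-size box against a corner-form ground truth;
## no validation, hot path for the finite-difference location gradient.
ciouCS <- function(cx, cy, w, h, gt) {
  px1 <- cx - w / 2; py1 <- cy - h / 2; px2 <- cx + w / 2; py2 <- cy + h / 2
  iw <- max(0, min(px2, gt[3]) - max(px1, gt[1]))
  ih <- max(0, min(py2, gt[4]) - max(py1, gt[2]))
  inter <- iw * ih
  gw <- gt[3] - gt[1]; gh <- gt[4] - gt[2]
  iou <- inter / (w * h + gw * gh - inter)
  rho2 <- (cx - (gt[1] + gt[3]) / 2)^2 + (cy - (gt[2] + gt[4]) / 2)^2
  ex <- max(px2, gt[3]) - min(px1, gt[1])
  ey <- max(py2, gt[4]) - min(py1, gt[2])
  ups <- 4 / pi^2 * (atan(gw / gh) - atan(w / h))^2
  alpha <- if (ups == 0) 0 else ups / (1 - iou + ups)
  1 - iou + rho2 / (ex^2 + ey^2) + alpha * ups
}

## Per-image loss and gradient of the loss wrt each head tensor.
headLossGrads <- function(model, heads, assignment, lossWeights,
                          lambdaNoobj) {
  nC <- model@nClasses
  step <- 5L + nC
  nA <- sum(vapply(assignment$slots, nrow, 0L))
  grads <- list()
  locSum <- 0; objSum <- 0; clsSum <- 0
  for (s in seq_along(heads)) {
    head <- heads[[s]]
    S <- dim(head)[1]
    B <- nrow(model@anchors@anchors[[s]])
    stride <- model@anchors@strides[s]
    g <- array(0, dim(head))
    objT <- assignment$objectness[[s]]
    for (b in seq_len(B)) {
      off <- (b - 1L) * step
      p <- sigmoid(head[, , off + 5L])
      tt <- objT[, , b]
      e <- bce(tt, p)
      objSum <- objSum + sum(e[tt == 1]) + lambdaNoobj * sum(e[tt == 0])
      g[, , off + 5L] <- lossWeights[2] * (p - tt) *
        ifelse(tt == 1, 1, lambdaNoobj)
    }
    sl <- assignment$slots[[s]]
    for (r in seq_len(nrow(sl))) {
      y <- sl$cell_y[r] + 1L; x <- sl$cell_x[r] + 1L
      off <- (sl$anchor[r] - 1L) * step
      gt <- c(sl$x_min[r], sl$y_min[r], sl$x_max[r], sl$y_max[r])
      ## class term
      zp <- sigmoid(head[y, x, off + 5L + seq_len(nC)])
      yv <- as.numeric(seq_len(nC) == sl$class_id[r] + 1L)
      clsSum <- clsSum + sum(bce(yv, zp))
      g[y, x, off + 5L + seq_len(nC)] <-
        g[y, x, off + 5L + seq_len(nC)] + lossWeights[3] * (zp - yv)
      ## location term: finite differences on the decoded box, chained
      ## through the analytic decode Jacobian. The size offsets saturate
      ## at +-4 for the loss; at the boundary the chain keeps the
      ## boundary derivative (instead of the true zero) so a slot that
      ## overshoots can still be pulled back, and a weak pull of the raw
      ## offsets toward zero re-activates saturated sigmoids.
      t4 <- head[y, x, off + 1:4]
      sx <- sigmoid(t4[1]); sy <- sigmoid(t4[2])
      tw <- min(max(t4[3], -4), 4); th <- min(max(t4[4], -4), 4)
      anc <- model@anchors@anchors[[s]][sl$anchor[r], ]
      bx <- (sx + sl$cell_x[r]) * stride
      by <- (sy + sl$cell_y[r]) * stride
      bw <- anc[1] * exp(tw); bh <- anc[2] * exp(th)
      locSum <- locSum + ciouCS(bx, by, bw, bh, gt)
      eps <- 1e-3
      d4 <- c(
        (ciouCS(bx + eps, by, bw, bh, gt) - ciouCS(bx - eps, by, bw, bh, gt)),
        (ciouCS(bx, by + eps, bw, bh, gt) - ciouCS(bx, by - eps, bw, bh, gt)),
        (ciouCS(bx, by, bw + eps, bh, gt) - ciouCS(bx, by, bw - eps, bh, gt)),
        (ciouCS(bx, by, bw, bh + eps, gt) - ciouCS(bx, by, bw, bh - eps, gt))
      ) / (2 * eps)
      dt <- c(d4[1] * stride * sx * (1 - sx),
              d4[2] * stride * sy * (1 - sy),
              d4[3] * bw, d4[4] * bh) + 0.02 * t4
      scale <- lossWeights[1] / max(nA, 1L)
      g[y, x, off + 1:4] <- g[y, x, off + 1:4] + scale * dt
    }
    grads[[as.character(model@config$heads[s])]] <- arrayToHead(g)
  }
  loc <- if (nA) locSum / nA else 0
  list(grads = grads, loc = loc, obj = objSum, cls = clsSum,
       total = sum(lossWeights * c(loc, objSum, clsSum)))
}

#' Train the detector with mini-batch SGD
#'
#' Runs `epochs` passes of stochastic gradient descent with momentum over
#' the samples, minimizing the weighted sum of the CIoU location loss
#' (averaged over assigned slots), the objectness loss and the class loss.
#' Sample order is reshuffled each epoch from the seeded RNG, so a given
#' `(model, samples, config, seed)` always produces the same loss history
#' and weights. Images not at the network input size are resized (with
#' their boxes) on entry. Training aborts with a diagnostic if a batch
#' produces a non-finite loss.
#'
#' @param model a [ChromosomeDetector-class].
#' @param samples list of [MetaphaseSample-class], or a list with `images`
#'   and `boxes` elements ([readDataset()] output).
#' @param epochs training epochs (default 200).
#' @param batchSize mini-batch size (default 32).
#' @param lr SGD learning rate (default 0.01).
#' @param momentum SGD momentum (default 0.9).
#' @param lossWeights numeric length-3 (location, objectness, class)
#'   weights (default `c(1, 1, 1)`).
#' @param lambdaNoobj no-object down-weight in the objectness loss
#'   (default 0.5).
#' @param clipNorm global gradient-norm clip applied to each batch
#'   gradient before the momentum update (default 10); the objectness sum
#'   over thousands of slots can produce large early gradients.
#' @param lrSchedule `"constant"` (default) or `"cosine"` (half-cosine
#'   decay from `lr` to 0.05 `lr` across the epochs).
#' @param seed RNG seed for shuffling.
#' @param verbose print the per-epoch losses.
#' @return list with `model` (trained) and `history` (data.frame: `epoch`,
#'   `loc`, `obj`, `cls`, `total` — per-epoch means of the per-image
#'   losses).
#' @export
trainDetector <- function(model, samples, epochs = 200L, batchSize = 32L,
                          lr = 0.01, momentum = 0.9,
                          lossWeights = c(1, 1, 1), lambdaNoobj = 0.5,
                          clipNorm = 10, lrSchedule = c("constant", "cosine"),
                          seed = 1L, verbose = FALSE) {
  stopifnot(epochs >= 1, batchSize >= 1, lr > 0)
  lrSchedule <- match.arg(lrSchedule)
  if (!is.null(samples$images)) {
    images <- samples$images; boxes <- samples$boxes
  } else {
    images <- lapply(samples, sampleImage)
    boxes <- lapply(samples, sampleBoxes)
  }
  n <- length(images)
  if (!n) stop("empty training set", call. = FALSE)
  sz <- model@anchors@inputSize
  prep <- lapply(seq_len(n), function(i) {
    img <- images[[i]]; bx <- boxes[[i]]
    if (nrow(img) != sz || ncol(img) != sz) {
      r <- resizeWithBoxes(img, bx, target = sz)
      img <- r$image; bx <- r$boxes
    }
    list(input = imageToInput(img),
         assignment = assignTargets(bx, model@anchors, model@nClasses))
  })
  layers <- model@config$layers
  vel <- lapply(model@weights, function(w)
    list(W = w$W * 0, b = w$b * 0))
  history <- data.frame(epoch = integer(0), loc = numeric(0),
                        obj = numeric(0), cls = numeric(0),
                        total = numeric(0))
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    lrEp <- if (lrSchedule == "cosine")
      lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * (ep - 1) / max(1, epochs - 1))))
    else lr
    ord <- sample.int(n)
    epLoss <- c(loc = 0, obj = 0, cls = 0, total = 0)
    nBatches <- ceiling(n / batchSize)
    for (bi in seq_len(nBatches)) {
      idx <- ord[((bi - 1L) * batchSize + 1L):min(bi * batchSize, n)]
      acc <- NULL
      for (i in idx) {
        st <- net_forward(model@weights, layers, prep[[i]]$input, sz, sz,
                          TRUE)
        heads <- lapply(seq_along(model@config$heads), function(s) {
          j <- model@config$heads[s] + 1L
          headToArray(st$acts[[j]], st$H[j], st$W[j])
        })
        if (!all(vapply(heads, function(h) all(is.finite(h)), TRUE)))
          stop(sprintf("non-finite network output at epoch %d, batch %d, sample %d",
                       ep, bi, i), call. = FALSE)
        hl <- headLossGrads(model, heads, prep[[i]]$assignment,
                            lossWeights, lambdaNoobj)
        if (!is.finite(hl$total))
          stop(sprintf("non-finite loss at epoch %d, batch %d, sample %d",
                       ep, bi, i), call. = FALSE)
        epLoss <- epLoss + c(hl$loc, hl$obj, hl$cls, hl$total)
        bg <- net_backward(model@weights, layers, st$acts, st$H, st$W,
                           hl$grads)
        if (is.null(acc)) {
          acc <- bg
        } else {
          for (l in seq_along(acc)) {
            acc[[l]]$dW <- acc[[l]]$dW + bg[[l]]$dW
            acc[[l]]$db <- acc[[l]]$db + bg[[l]]$db
          }
        }
      }
      m <- length(idx)
      gnorm <- sqrt(sum(vapply(acc, function(g)
        sum((g$dW / m)^2) + sum((as.numeric(g$db) / m)^2), 0)))
      clip <- if (gnorm > clipNorm) clipNorm / gnorm else 1
      for (l in seq_along(model@weights)) {
        vel[[l]]$W <- momentum * vel[[l]]$W + clip * acc[[l]]$dW / m
        vel[[l]]$b <- momentum * vel[[l]]$b + clip * as.numeric(acc[[l]]$db) / m
        model@weights[[l]]$W <- model@weights[[l]]$W - lrEp * vel[[l]]$W
        model@weights[[l]]$b <- model@weights[[l]]$b - lrEp * vel[[l]]$b
      }
    }
    history <- rbind(history,
                     data.frame(epoch = ep, loc = epLoss[["loc"]] / n,
                                obj = epLoss[["obj"]] / n,
                                cls = epLoss[["cls"]] / n,
                                total = epLoss[["total"]] / n))
    if (verbose)
      message(sprintf("epoch %3d  loc %.4f  obj %.4f  cls %.4f  total %.4f",
                      ep, epLoss[["loc"]] / n, epLoss[["obj"]] / n,
                      epLoss[["cls"]] / n, epLoss[["total"]] / n))
  }
  rownames(history) <- NULL
  list(model = model, history = history)
}

#' Split samples into train/validation/test partitions
#'
#' Seed-deterministic random partition: disjoint, exhaustive, sized by
#' rounding the cumulative fractions.
#'
#' @param x a list of samples, or an integer count (then index vectors are
#'   returned).
#' @param fractions numeric vector summing to 1 (default
#'   `c(0.6, 0.2, 0.2)`).
#' @param seed RNG seed.
#' @return named list of partitions (`train`, `validation`, `test` for
#'   three fractions).
#' @export
splitDataset <- function(x, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x) else length(x)
  set.seed(seed)
  ord <- sample.int(n)
  bounds <- round(cumsum(fractions) * n)
  starts <- c(0L, head(bounds, -1L)) + 1L
  parts <- lapply(seq_along(fractions), function(i)
    if (starts[i] > bounds[i]) integer(0) else sort(ord[starts[i]:bounds[i]]))
  if (any(lengths(parts) == 0L)) warning("empty split produced")
  names(parts) <- if (length(fractions) == 3L)
    c("train", "validation", "test")
  else paste0("split", seq_along(fractions))
  if (is.numeric(x) && length(x) == 1L) parts
  else lapply(parts, function(ix) x[ix])
}

#' Desk-scale training preset
#'
#' The package's reference configuration for training the compact detector
#' on desk-preset scenes ([deskSceneSpec()]): 30 epochs of
#' single-sample SGD with a half-cosine learning-rate decay from 0.015,
#' loss weights (10, 1, 2), gradient-norm clip 20, copy-paste
#' augmentation of the dicentric class to three times its raw count, and
#' inference thresholds (score 0.15, NMS IoU 0.3). These values are the
#' preset used by the package's own training demonstrations.
#'
#' @return named list of training and inference settings.
#' @export
deskTrainPreset <- function() {
  list(epochs = 30L, batchSize = 1L, lr = 0.015, momentum = 0.9,
       lossWeights = c(10, 1, 2), lambdaNoobj = 0.5, clipNorm = 20,
       lrSchedule = "cosine", augmentFactor = 3,
       confThreshold = 0.15, nmsThreshold = 0.3)
}
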