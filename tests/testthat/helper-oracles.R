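# Independent reference implementations used as oracles. These are kept
# deliberately naive (loops, enumeration, rasterization) and separate from
# the package's vectorized code paths.

# Literal transcription of the box decode: b = sigmoid(t) + C (grid units,
# scaled by stride), size = anchor * exp(t).
oracleDecode <- function(t, cell, anchor, stride) {
  sig <- function(x) (1 + exp(-x))^-1
  bx <- (sig(t[1]) + cell[1]) * stride
  by <- (sig(t[2]) + cell[2]) * stride
  bw <- anchor[1] * exp(t[3])
  bh <- anchor[2] * exp(t[4])
  c(cx = bx, cy = by, w = bw, h = bh)
}

# IoU by counting subpixels on a fine raster; exact for boxes whose
# coordinates are multiples of 1/res.
oracleIoUraster <- function(a, b, res = 4) {
  x0 <- floor(min(a[1], b[1]) * res); x1 <- ceiling(max(a[3], b[3]) * res)
  y0 <- floor(min(a[2], b[2]) * res); y1 <- ceiling(max(a[4], b[4]) * res)
  xs <- (seq(x0, x1 - 1) + 0.5) / res
  ys <- (seq(y0, y1 - 1) + 0.5) / res
  inA <- outer(ys >= a[2] & ys < a[4], xs >= a[1] & xs < a[3], `&`)
  inB <- outer(ys >= b[2] & ys < b[4], xs >= b[1] & xs < b[3], `&`)
  sum(inA & inB) / sum(inA | inB)
}

# Literal transcription of the CIoU location loss.
oracleCIoU <- function(p, g) {
  interW <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  interH <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- interW * interH
  areaP <- (p[3] - p[1]) * (p[4] - p[2])
  areaG <- (g[3] - g[1]) * (g[4] - g[2])
  iou <- inter / (areaP + areaG - inter)
  rho2 <- ((p[1] + p[3]) / 2 - (g[1] + g[3]) / 2)^2 +
          ((p[2] + p[4]) / 2 - (g[2] + g[4]) / 2)^2
  c2 <- (max(p[3], g[3]) - min(p[1], g[1]))^2 +
        (max(p[4], g[4]) - min(p[2], g[2]))^2
  ups <- 4 / pi^2 *
    (atan((g[3] - g[1]) / (g[4] - g[2])) - atan((p[3] - p[1]) / (p[4] - p[2])))^2
  alpha <- if (ups == 0) 0 else ups / ((1 - iou) + ups)
  1 - iou + rho2 / c2 + alpha * ups
}

# Double-sum transcription of the objectness loss over (cell, anchor)
# slots: BCE at object slots + lambda * BCE at no-object slots.
oracleObjectnessLoss <- function(conf, ind, lambda, eps = 1e-7) {
  total <- 0
  for (s in seq_along(conf)) {
    cs <- as.numeric(conf[[s]]); is <- as.numeric(ind[[s]])
    for (i in seq_along(cs)) {
      p <- min(max(cs[i], eps), 1 - eps)
      ce <- -(is[i] * log(p) + (1 - is[i]) * log(1 - p))
      total <- total + if (is[i] == 1) ce else lambda * ce
    }
  }
  total
}

# Per-class BCE sum at object slots only.
oracleClassLoss <- function(probs, ind, targets, eps = 1e-7) {
  total <- 0
  for (s in seq_along(probs)) {
    is <- as.numeric(ind[[s]])
    for (i in which(is == 1)) {
      for (cc in seq_len(ncol(probs[[s]]))) {
        p <- min(max(probs[[s]][i, cc], eps), 1 - eps)
        y <- targets[[s]][i, cc]
        total <- total - (y * log(p) + (1 - y) * log(1 - p))
      }
    }
  }
  total
}

# O(n^2) reference NMS: repeatedly pick the best-scoring live box.
oracleNMS <- function(det, iouThr, confThr, perClass = TRUE) {
  det <- det[det$score >= confThr, , drop = FALSE]
  live <- rep(TRUE, nrow(det))
  kept <- integer(0)
  while (any(live)) {
    cand <- which(live)
    best <- cand[order(-det$score[cand], cand)[1]]
    kept <- c(kept, best)
    live[best] <- FALSE
    for (j in which(live)) {
      if (perClass && det$class_id[j] != det$class_id[best]) next
      if (boxIoU(det[best, ], det[j, ]) > iouThr) live[j] <- FALSE
    }
  }
  det[kept, , drop = FALSE]
}

# Exhaustive 256-level Otsu search straight from the definition.
oracleOtsu <- function(image) {
  g <- round(pmin(pmax(as.numeric(image), 0), 255))
  best <- -Inf; bestT <- NA
  for (t in 0:254) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best + 1e-9) { best <- v; bestT <- t }
  }
  bestT
}

# BFS flood-fill labeling.
oracleFloodFill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  nlab <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nlab <- nlab + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nlab
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; cc <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nlab
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# Naive greedy matcher: walk detections in confidence order, scan all
# ground truths each time.
oracleMatch <- function(det, gt, thr) {
  used <- rep(FALSE, nrow(gt))
  tp <- 0L
  for (cl in unique(det$class_id)) {
    idx <- which(det$class_id == cl)
    idx <- idx[order(-det$score[idx], idx)]
    for (i in idx) {
      bestIoU <- -1; bestJ <- 0
      for (j in which(!used & gt$class_id == cl)) {
        v <- boxIoU(det[i, ], gt[j, ])
        if (v > bestIoU) { bestIoU <- v; bestJ <- j }
      }
      if (bestJ > 0 && bestIoU >= thr) { used[bestJ] <- TRUE; tp <- tp + 1L }
    }
  }
  list(tp = tp, fp = nrow(det) - tp, fn = nrow(gt) - tp)
}

# Riemann-sum AP over the sorted PR points with a suffix-max envelope.
oracleAP <- function(scores, matched, nGT) {
  ord <- order(-scores)
  matched <- matched[ord]
  n <- length(matched)
  prec <- cumsum(matched) / seq_len(n)
  rec <- cumsum(matched) / nGT
  ap <- 0; prevR <- 0
  for (i in seq_len(n)) {
    env <- max(prec[i:n])
    ap <- ap + (rec[i] - prevR) * env
    prevR <- rec[i]
  }
  ap
}

# Random valid corner-form box.
randomBox <- function(lim = 100, minSize = 1) {
  x <- sort(runif(2, 0, lim)); y <- sort(runif(2, 0, lim))
  c(x[1], y[1], max(x[2], x[1] + minSize), max(y[2], y[1] + minSize))
}
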