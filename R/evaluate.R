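## Detection evaluation at a fixed IoU threshold: greedy matching,
## F1-confidence curve, all-point-interpolated average precision, mAP, and
## the chromosomes-per-metaphase summary.

#' Match detections to ground truth at an IoU threshold
#'
#' Per class, detections are sorted by descending confidence (ties by
#' input order) and greedily matched: each detection takes the unmatched
#' ground-truth box of the same class with the highest IoU, provided that
#' IoU reaches the threshold; otherwise it is a false positive. Ground
#' truths left unmatched are false negatives.
#'
#' @param detections detection data.frame (box columns, `class_id`,
#'   `score`).
#' @param gtBoxes ground-truth box data.frame.
#' @param iouThreshold matching threshold (default 0.5).
#' @return list with `detections` (the input rows plus `matched`, `gt_id`,
#'   `iou`), `nGT` (named per-class ground-truth counts) and counts `tp`,
#'   `fp`, `fn`.
#' @export
matchDetections <- function(detections, gtBoxes, iouThreshold = 0.5) {
  det <- detections
  det$matched <- logical(nrow(det))
  det$gt_id <- rep(NA_integer_, nrow(det))
  det$iou <- rep(NA_real_, nrow(det))
  classes <- sort(unique(c(det$class_id, gtBoxes$class_id)))
  for (cl in classes) {
    di <- which(det$class_id == cl)
    gi <- which(gtBoxes$class_id == cl)
    if (!length(di) || !length(gi)) next
    di <- di[order(-det$score[di], di)]
    iouM <- boxIoUMatrix(det[di, , drop = FALSE],
                         gtBoxes[gi, , drop = FALSE])
    taken <- logical(length(gi))
    for (r in seq_along(di)) {
      ious <- iouM[r, ]
      ious[taken] <- -1
      best <- which.max(ious)
      if (ious[best] >= iouThreshold) {
        taken[best] <- TRUE
        det$matched[di[r]] <- TRUE
        det$gt_id[di[r]] <- gi[best]
        det$iou[di[r]] <- ious[best]
      }
    }
  }
  nGT <- table(factor(gtBoxes$class_id, levels = classes))
  tp <- sum(det$matched)
  list(detections = det, nGT = nGT, tp = tp, fp = nrow(det) - tp,
       fn = nrow(gtBoxes) - tp)
}

#' Pool per-image match results into one dataset-level table
#'
#' Runs [matchDetections()] on every image and concatenates the flagged
#' detections (with an `image` column) while summing the per-class
#' ground-truth counts; dataset-level curves and AP are computed from this
#' pooled table.
#'
#' @param detections list of per-image detection data.frames.
#' @param gtBoxes list of per-image ground-truth box data.frames.
#' @param iouThreshold matching IoU threshold (default 0.5).
#' @return list with `detections` (pooled, flagged) and `nGT`.
#' @export
poolMatches <- function(detections, gtBoxes, iouThreshold = 0.5) {
  stopifnot(length(detections) == length(gtBoxes))
  rows <- list(); nGT <- integer(0)
  for (i in seq_along(detections)) {
    m <- matchDetections(detections[[i]], gtBoxes[[i]], iouThreshold)
    d <- m$detections
    if (nrow(d)) { d$image <- i; rows[[length(rows) + 1L]] <- d }
    cls <- names(m$nGT)
    for (k in seq_along(m$nGT)) {
      nGT[cls[k]] <- (if (cls[k] %in% names(nGT)) nGT[[cls[k]]] else 0L) +
        m$nGT[[k]]
    }
  }
  pooled <- if (length(rows)) do.call(rbind, rows) else
    cbind(emptyBoxes(), score = numeric(0), matched = logical(0),
          image = integer(0))
  list(detections = pooled, nGT = nGT)
}

#' F1 score as a function of the confidence cutoff
#'
#' Recomputes precision and recall over all classes at every confidence
#' cutoff of the grid (by default every distinct detection confidence plus
#' the endpoints 0 and 1) and reports F1 = 2PR/(P+R), with F1 = 0 where
#' P + R = 0. The maximizing cutoff summarizes the model's operating
#' point; ties go to the lowest cutoff.
#'
#' @param matches a [poolMatches()] result (or [matchDetections()] result
#'   for a single image).
#' @param grid optional numeric vector of cutoffs in \[0, 1\].
#' @return list with `curve` (data.frame: `confidence`, `precision`,
#'   `recall`, `f1`), `maxF1` and `bestConfidence`.
#' @export
f1ConfidenceCurve <- function(matches, grid = NULL) {
  det <- matches$detections
  totalGT <- sum(matches$nGT)
  if (is.null(grid))
    grid <- sort(unique(c(0, det$score, 1)))
  stopifnot(length(grid) >= 1, all(grid >= 0), all(grid <= 1))
  f <- function(cut) {
    sel <- det$score >= cut
    tp <- sum(det$matched[sel]); fp <- sum(sel) - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (totalGT > 0) tp / totalGT else 0
    c(p, r, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  vals <- t(vapply(grid, f, numeric(3)))
  curve <- data.frame(confidence = grid, precision = vals[, 1],
                      recall = vals[, 2], f1 = vals[, 3])
  best <- which.max(curve$f1)
  list(curve = curve, maxF1 = curve$f1[best],
       bestConfidence = curve$confidence[best])
}

#' Average precision of one class
#'
#' All-point interpolated area under the precision-recall curve:
#' detections of the class are sorted by descending confidence (ties by
#' descending IoU, then input order), cumulative precision/recall are
#' computed, the precision envelope is made monotone non-increasing in
#' recall, and the area is integrated over the recall increments.
#'
#' @param matches a [poolMatches()] / [matchDetections()] result.
#' @param classId class to evaluate.
#' @return AP in \[0, 1\], or NA (with a warning) when the class has no
#'   ground truth.
#' @export
averagePrecision <- function(matches, classId) {
  idx <- match(as.character(classId), names(matches$nGT))
  nGT <- if (is.na(idx)) 0L else matches$nGT[[idx]]
  if (nGT == 0) {
    warning("class ", classId, " absent from ground truth; AP undefined")
    return(NA_real_)
  }
  det <- matches$detections
  det <- det[det$class_id == classId, , drop = FALSE]
  if (!nrow(det)) return(0)
  iouKey <- ifelse(is.na(det$iou), -1, det$iou)
  ord <- order(-det$score, -iouKey, seq_len(nrow(det)))
  tp <- cumsum(det$matched[ord])
  fp <- cumsum(!det$matched[ord])
  precision <- tp / (tp + fp)
  recall <- tp / nGT
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Mean average precision
#'
#' Unweighted mean of the per-class APs; NA entries (classes without
#' ground truth) are dropped.
#'
#' @param aps numeric vector of per-class AP values.
#' @return mAP.
#' @export
mapScore <- function(aps) mean(aps[!is.na(aps)])

#' Mean number of chromosomes per metaphase
#'
#' Total box count across all classes divided by the number of images; the
#' sanity statistic for metaphase detection (a normal human metaphase has
#' 46 chromosomes).
#'
#' @param boxes a list of box/detection data.frames (one per image), or a
#'   single data.frame.
#' @param nImages number of images (defaults to the list length).
#' @return mean count per image.
#' @export
chromosomesPerMetaphase <- function(boxes, nImages = NULL) {
  if (is.data.frame(boxes)) boxes <- list(boxes)
  if (is.null(nImages)) nImages <- length(boxes)
  stopifnot(nImages >= 1)
  sum(vapply(boxes, nrow, 0L)) / nImages
}

#' Evaluate detections against ground truth over a dataset
#'
#' Pools greedy matches at the IoU threshold across all images, then
#' reports per-class precision/recall at the F1-optimal confidence cutoff,
#' per-class AP, mAP, the maximum F1 with its cutoff, and the mean
#' predicted chromosomes per metaphase.
#'
#' @param detections list of per-image detection data.frames.
#' @param gtBoxes list of per-image ground-truth box data.frames.
#' @param iouThreshold matching IoU threshold (default 0.5).
#' @param classes class ids to evaluate (default `c(0, 1)`).
#' @return list with `perClass` (data.frame: class, precision, recall,
#'   ap), `mAP`, `maxF1`, `bestConfidence`, `chromosomesPerMetaphase`,
#'   `iouThreshold` and the pooled `matches`.
#' @export
evaluateDetections <- function(detections, gtBoxes, iouThreshold = 0.5,
                               classes = c(0L, 1L)) {
  pooled <- poolMatches(detections, gtBoxes, iouThreshold)
  f1 <- f1ConfidenceCurve(pooled)
  det <- pooled$detections
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    sel <- det$class_id == cl & det$score >= f1$bestConfidence
    tp <- sum(det$matched[sel]); fp <- sum(sel) - tp
    i <- match(as.character(cl), names(pooled$nGT))
    nGT <- if (is.na(i)) 0L else pooled$nGT[[i]]
    data.frame(class = cl,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               recall = if (nGT > 0) tp / nGT else NA_real_,
               ap = suppressWarnings(averagePrecision(pooled, cl)))
  }))
  list(perClass = perClass, mAP = mapScore(perClass$ap),
       maxF1 = f1$maxF1, bestConfidence = f1$bestConfidence,
       chromosomesPerMetaphase = chromosomesPerMetaphase(detections),
       iouThreshold = iouThreshold, matches = pooled)
}
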