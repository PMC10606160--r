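mkDet <- function(b, score, class_id = 0L) {
  data.frame(x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
             class_id = class_id, score = score)
}

test_that("matchDetections applies the IoU threshold per class", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   class_id = 0L)
  hit <- mkDet(c(0, 0, 10, 9), 0.9)       # IoU 0.9
  m <- matchDetections(hit, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))
  miss <- mkDet(c(0, 6, 10, 16), 0.9)     # IoU 0.25
  m2 <- matchDetections(miss, gt)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 1L, 1L))
  # class mismatch is never a match
  wrongClass <- mkDet(c(0, 0, 10, 10), 0.9, 1L)
  m3 <- matchDetections(wrongClass, gt)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0L, 1L, 1L))
})

test_that("matchDetections agrees with the naive greedy oracle", {
  set.seed(29)
  for (rep in 1:60) {
    nG <- sample(0:10, 1); nD <- sample(0:10, 1)
    gt <- if (nG) do.call(rbind, lapply(1:nG, function(i) {
      b <- randomBox(50, 3)
      data.frame(x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
                 class_id = sample(0:1, 1))
    })) else emptyBoxes()
    det <- if (nD) do.call(rbind, lapply(1:nD, function(i) {
      base <- if (nG && runif(1) < 0.7) unlist(gt[sample(nG, 1), 1:4]) else
        randomBox(50, 3)
      jit <- rnorm(4, 0, 2)
      b <- c(base[1] + jit[1], base[2] + jit[2],
             max(base[3] + jit[3], base[1] + jit[1] + 1),
             max(base[4] + jit[4], base[2] + jit[2] + 1))
      data.frame(x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
                 class_id = sample(0:1, 1), score = runif(1))
    })) else cbind(emptyBoxes(), score = numeric(0))
    m <- matchDetections(det, gt, 0.5)
    o <- oracleMatch(det, gt, 0.5)
    expect_equal(c(m$tp, m$fp, m$fn), c(o$tp, o$fp, o$fn))
    # precision/recall identities from the flags
    expect_equal(sum(m$detections$matched), m$tp)
    expect_true(all(m$detections$iou[m$detections$matched] >= 0.5))
    # each GT matched at most once
    expect_false(any(duplicated(stats::na.omit(m$detections$gt_id))))
  }
})

test_that("f1ConfidenceCurve finds the harmonic-mean optimum", {
  # perfect detector: F1 = 1 at every cutoff below the scores
  gt <- data.frame(x_min = c(0, 20), y_min = c(0, 20),
                   x_max = c(10, 30), y_max = c(10, 30),
                   class_id = c(0L, 0L))
  det <- rbind(mkDet(c(0, 0, 10, 10), 0.9), mkDet(c(20, 20, 30, 30), 0.8))
  pm <- poolMatches(list(det), list(gt))
  f1 <- f1ConfidenceCurve(pm)
  expect_equal(f1$maxF1, 1)
  # known precision/recall pair: F1 is their harmonic mean
  p <- 0.946; r <- 0.915
  expect_equal(2 * p * r / (p + r), 0.930, tolerance = 5e-4)
  # no detections: F1 = 0 everywhere
  pm0 <- poolMatches(list(cbind(emptyBoxes(), score = numeric(0))),
                     list(gt))
  expect_equal(f1ConfidenceCurve(pm0)$maxF1, 0)
})

test_that("f1 curve values recompute from the pooled match flags", {
  set.seed(33)
  dets <- list(); gts <- list()
  for (i in 1:5) {
    s <- generateMetaphase(deskSceneSpec(nChromosomes = 5, nDicentric = 1,
                                         seed = 400 + i))
    gt <- sampleBoxes(s)
    det <- do.call(rbind, lapply(seq_len(nrow(gt)), function(k) {
      b <- unlist(gt[k, 1:4]) + rnorm(4, 0, 4)
      data.frame(x_min = b[1], y_min = b[2],
                 x_max = max(b[3], b[1] + 2), y_max = max(b[4], b[2] + 2),
                 class_id = gt$class_id[k], score = runif(1))
    }))
    dets[[i]] <- det; gts[[i]] <- gt
  }
  pm <- poolMatches(dets, gts)
  f1 <- f1ConfidenceCurve(pm)
  for (j in sample(nrow(f1$curve), 5)) {
    cut <- f1$curve$confidence[j]
    sel <- pm$detections$score >= cut
    tp <- sum(pm$detections$matched[sel])
    p <- if (sum(sel)) tp / sum(sel) else 0
    r <- tp / sum(pm$nGT)
    expect_equal(f1$curve$precision[j], p)
    expect_equal(f1$curve$recall[j], r)
  }
})

test_that("averagePrecision handles the edge cases and matches its oracle", {
  gt <- data.frame(x_min = 0, y_min = 0, x_max = 10, y_max = 10,
                   class_id = 0L)
  perfect <- poolMatches(list(mkDet(c(0, 0, 10, 10), 0.9)), list(gt))
  expect_equal(averagePrecision(perfect, 0L), 1)
  allFP <- poolMatches(list(mkDet(c(50, 50, 60, 60), 0.9)), list(gt))
  expect_equal(averagePrecision(allFP, 0L), 0)
  expect_warning(ap1 <- averagePrecision(perfect, 1L), "absent")
  expect_true(is.na(ap1))
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(1:40, 1); nGT <- sample(1:20, 1)
    matched <- runif(n) < 0.5
    if (sum(matched) > nGT) matched[which(matched)[-(1:nGT)]] <- FALSE
    scores <- runif(n)
    pm <- list(detections = data.frame(class_id = 0L, score = scores,
                                       matched = matched, iou = NA_real_),
               nGT = c(`0` = nGT))
    expect_equal(averagePrecision(pm, 0L), oracleAP(scores, matched, nGT),
                 tolerance = 1e-12)
  }
})

test_that("mapScore is the mean of defined per-class APs", {
  expect_equal(mapScore(c(0.8, 0.6)), 0.7)
  expect_equal(mapScore(c(0.9, NA)), 0.9)
  expect_equal(mapScore(c(0.5, 0.5, 0.5)), 0.5)  # mean identity
})

test_that("chromosomesPerMetaphase is total boxes over images", {
  boxes <- replicate(10, data.frame(x_min = seq(0, 450, 10),
                                    y_min = 0, x_max = seq(5, 455, 10),
                                    y_max = 5, class_id = 0L),
                     simplify = FALSE)
  expect_equal(chromosomesPerMetaphase(boxes), 46)
  expect_equal(chromosomesPerMetaphase(list(emptyBoxes())), 0)
})

test_that("a perfect detector scores 1 on every dataset-level metric", {
  samples <- lapply(1:4, function(i)
    generateMetaphase(deskSceneSpec(nChromosomes = 6, nDicentric = 2,
                                    seed = 500 + i)))
  gts <- lapply(samples, sampleBoxes)
  dets <- lapply(gts, function(g) cbind(g, score = 0.9))
  rep <- evaluateDetections(dets, gts)
  expect_equal(rep$perClass$precision, c(1, 1))
  expect_equal(rep$perClass$recall, c(1, 1))
  expect_equal(rep$perClass$ap, c(1, 1))
  expect_equal(rep$mAP, 1)
  expect_equal(rep$maxF1, 1)
  expect_equal(rep$chromosomesPerMetaphase, 6)
})
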