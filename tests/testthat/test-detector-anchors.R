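test_that("kmeansAnchors collapses identical boxes to one centroid value", {
  wh <- matrix(rep(c(20, 30), each = 8), ncol = 2) +
    matrix(rnorm(16, 0, 1e-9), ncol = 2)    # distinct up to rounding noise
  km <- kmeansAnchors(wh, k = 2, seed = 1)
  expect_equal(unname(km$centroids[, 1]), c(20, 20), tolerance = 1e-6)
  expect_equal(unname(km$centroids[, 2]), c(30, 30), tolerance = 1e-6)
})

test_that("kmeansAnchors recovers two well-separated size clusters", {
  set.seed(5)
  small <- cbind(runif(20, 8, 12), runif(20, 8, 12))
  large <- cbind(runif(20, 48, 52), runif(20, 48, 52))
  km <- kmeansAnchors(rbind(small, large), k = 2, seed = 3)
  expect_equal(unname(km$centroids[1, ]), colMeans(small), tolerance = 0.05)
  expect_equal(unname(km$centroids[2, ]), colMeans(large), tolerance = 0.05)
  # objective (mean 1 - IoU) never increases across iterations
  expect_true(all(diff(km$objective) <= 1e-12))
})

test_that("kmeansAnchors objective descends on random data and is seeded", {
  set.seed(6)
  wh <- cbind(runif(60, 5, 80), runif(60, 5, 80))
  a <- kmeansAnchors(wh, k = 5, seed = 9)
  b <- kmeansAnchors(wh, k = 5, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(a$objective) <= 1e-12))
  expect_error(kmeansAnchors(wh[1:3, ], k = 4), "at least k")
})

test_that("assignTargets puts each ground truth at its center cell and best anchor", {
  anch <- anchorSet(list(rbind(c(10, 10), c(30, 10), c(10, 30))), 8L, 80L)
  # box centered at (36, 20) -> cell (4, 2); tall 10x28 -> anchor 3
  boxes <- data.frame(x_min = 31, y_min = 6, x_max = 41, y_max = 34,
                      class_id = 1L)
  asg <- assignTargets(boxes, anch)
  sl <- asg$slots[[1]]
  expect_equal(nrow(sl), 1L)
  expect_equal(c(sl$cell_x, sl$cell_y, sl$anchor), c(4, 2, 3))
  expect_equal(sum(asg$objectness[[1]]), 1)
  expect_equal(asg$classTargets[[1]][sl$slot, ], c(0, 1))
  # no ground truth: all-no-object
  asg0 <- assignTargets(emptyBoxes(), anch)
  expect_equal(sum(asg0$objectness[[1]]), 0)
  expect_error(assignTargets(data.frame(x_min = -30, y_min = 0, x_max = -10,
                                        y_max = 10, class_id = 0L), anch),
               "bounds|outside")
})

test_that("assignTargets matches brute-force cell/anchor enumeration", {
  anch <- anchorSet(list(rbind(c(12, 12), c(24, 12), c(12, 24)),
                         rbind(c(30, 30), c(50, 24), c(24, 50))),
                    c(8L, 16L), 96L)
  set.seed(81)
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    boxes <- do.call(rbind, lapply(seq_len(n), function(i) {
      w <- runif(1, 6, 40); h <- runif(1, 6, 40)
      cx <- runif(1, w / 2 + 1, 95 - w / 2); cy <- runif(1, h / 2 + 1, 95 - h / 2)
      data.frame(x_min = cx - w / 2, y_min = cy - h / 2,
                 x_max = cx + w / 2, y_max = cy + h / 2,
                 class_id = sample(0:1, 1))
    }))
    asg <- assignTargets(boxes, anch)
    for (s in 1:2) {
      stride <- anch@strides[s]
      taken <- matrix(FALSE, 0, 3)
      for (g in seq_len(nrow(boxes))) {
        cx <- (boxes$x_min[g] + boxes$x_max[g]) / 2
        cy <- (boxes$y_min[g] + boxes$y_max[g]) / 2
        w <- boxes$x_max[g] - boxes$x_min[g]
        h <- boxes$y_max[g] - boxes$y_min[g]
        gx <- floor(cx / stride); gy <- floor(cy / stride)
        # enumerate anchors by concentric IoU
        ious <- vapply(seq_len(3), function(b) {
          aw <- anch@anchors[[s]][b, 1]; ah <- anch@anchors[[s]][b, 2]
          inter <- min(w, aw) * min(h, ah)
          inter / (w * h + aw * ah - inter)
        }, 0)
        slot <- asg$slots[[s]][asg$slots[[s]]$gt_id == g, ]
        if (nrow(slot)) {
          expect_equal(c(slot$cell_x, slot$cell_y), c(gx, gy))
          # the chosen anchor is the best not already taken at this cell
          prior <- asg$slots[[s]]
          earlier <- prior[prior$gt_id < g & prior$cell_x == gx &
                             prior$cell_y == gy, "anchor"]
          free <- setdiff(order(ious, decreasing = TRUE), earlier)
          expect_equal(slot$anchor, free[1])
        }
      }
    }
  }
})

test_that("nms keeps the expected survivors in simple cases", {
  two <- data.frame(x_min = c(0, 1), y_min = c(0, 0),
                    x_max = c(10, 11), y_max = c(10, 10),
                    class_id = c(0L, 0L), score = c(0.9, 0.8))
  kept <- nms(two, iouThreshold = 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 0.9)
  disjoint <- data.frame(x_min = c(0, 50), y_min = c(0, 50),
                         x_max = c(10, 60), y_max = c(10, 60),
                         class_id = c(0L, 0L), score = c(0.9, 0.8))
  expect_equal(nrow(nms(disjoint, 0.5)), 2L)
  # different classes are not suppressed under per-class NMS
  two$class_id <- c(0L, 1L)
  expect_equal(nrow(nms(two, 0.5)), 2L)
})

test_that("nms matches the O(n^2) reference on random scenes", {
  set.seed(91)
  for (rep in 1:100) {
    n <- sample(1:50, 1)
    det <- do.call(rbind, lapply(seq_len(n), function(i) {
      b <- randomBox(60, 2)
      data.frame(x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
                 class_id = sample(0:1, 1),
                 score = round(runif(1), 2))   # rounded scores force ties
    }))
    thr <- runif(1, 0.2, 0.7); confThr <- runif(1, 0, 0.3)
    got <- nms(det, thr, confThr)
    want <- oracleNMS(det, thr, confThr)
    expect_equal(got[order(as.numeric(rownames(got))), , drop = FALSE],
                 want[order(as.numeric(rownames(want))), , drop = FALSE])
  }
})

test_that("nms output is independent of input order away from score ties", {
  set.seed(101)
  det <- do.call(rbind, lapply(1:30, function(i) {
    b <- randomBox(50, 2)
    data.frame(x_min = b[1], y_min = b[2], x_max = b[3], y_max = b[4],
               class_id = sample(0:1, 1), score = runif(1))
  }))
  a <- nms(det, 0.5)
  perm <- sample(nrow(det))
  b <- nms(det[perm, ], 0.5)
  key <- function(d) d[order(d$x_min, d$y_min, d$score), , drop = FALSE]
  ka <- key(a); kb <- key(b)
  rownames(ka) <- rownames(kb) <- NULL
  expect_equal(ka, kb)
})
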