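test_that("boxIoU handles identity, disjointness and a known overlap", {
  expect_equal(boxIoU(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(boxIoU(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  # overlap 1x1, union 4+4-1 = 7; cross-checked by subpixel rasterization
  expect_equal(boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(oracleIoUraster(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_error(boxIoU(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("boxIoU agrees with the rasterized pixel-counting oracle", {
  set.seed(11)
  for (i in 1:50) {
    # quarter-integer coordinates make the res = 4 raster exact
    a <- round(randomBox(40) * 4) / 4
    b <- round(randomBox(40) * 4) / 4
    if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2]) next
    expect_equal(boxIoU(a, b), oracleIoUraster(a, b), tolerance = 1e-12)
  }
})

test_that("decodeBox reproduces the sigmoid/exp transform", {
  d <- decodeBox(c(0, 0, 0, 0), cell = c(3, 4), anchor = c(10, 20),
                 stride = 1)
  expect_equal(c(d$cx, d$cy), c(3.5, 4.5))   # sigmoid(0) = 0.5
  expect_equal(c(d$w, d$h), c(10, 20))       # exp(0) = 1
  expect_equal(decodeBox(c(0, 0, log(2), 0), c(0, 0), c(10, 20), 8)$w, 20)
})

test_that("decodeBox matches the formula oracle on random encodings", {
  set.seed(21)
  for (i in 1:1000) {
    t <- rnorm(4, 0, 2)
    cell <- sample(0:19, 2)
    anchor <- runif(2, 2, 60)
    stride <- sample(c(4, 8, 16, 32), 1)
    got <- decodeBox(t, cell, anchor, stride)
    want <- oracleDecode(t, cell, anchor, stride)
    expect_equal(c(got$cx, got$cy, got$w, got$h), unname(want),
                 tolerance = 1e-12)
  }
})

test_that("encode/decode round trip reproduces boxes inside their cell", {
  set.seed(31)
  for (i in 1:100) {
    stride <- 8; cell <- c(sample(0:9, 1), sample(0:9, 1))
    cx <- (cell[1] + runif(1, 0.05, 0.95)) * stride
    cy <- (cell[2] + runif(1, 0.05, 0.95)) * stride
    w <- runif(1, 2, 50); h <- runif(1, 2, 50)
    box <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
    anchor <- runif(2, 2, 60)
    t <- encodeBox(box, cell, anchor, stride)
    d <- decodeBox(t, cell, anchor, stride)
    expect_equal(c(d$x_min, d$y_min, d$x_max, d$y_max), box,
                 tolerance = 1e-6)
  }
})

test_that("ciouLoss is zero iff boxes coincide and matches its oracle", {
  expect_equal(ciouLoss(c(1, 2, 5, 9), c(1, 2, 5, 9))$loss, 0)
  set.seed(41)
  for (i in 1:1000) {
    p <- randomBox(); g <- randomBox()
    got <- ciouLoss(p, g)
    expect_equal(got$loss, oracleCIoU(p, g), tolerance = 1e-9)
    expect_gte(got$loss, 1 - got$terms$iou)    # penalties are non-negative
    if (!isTRUE(all.equal(p, g))) expect_gt(got$loss, 0)
  }
})

test_that("ciouLoss on a concentric half-size same-aspect box is 1 - IoU", {
  r <- ciouLoss(c(25, 25, 75, 75), c(0, 0, 100, 100))
  expect_equal(r$terms$iou, 0.25)
  expect_equal(r$terms$rho2, 0)
  expect_equal(r$terms$upsilon, 0)
  expect_equal(r$loss, 0.75)
})

test_that("objectness loss matches the double-sum BCE transcription", {
  # single object slot at p = 0.5 gives -log(0.5)
  a1 <- list(objectness = list(c(1, 0, 0)))
  expect_equal(objectnessLoss(list(c(0.5, 0.1, 0.1)), a1, lambdaNoobj = 0),
               -log(0.5), tolerance = 1e-9)
  # lambda = 0 makes the loss invariant to no-object predictions
  expect_equal(objectnessLoss(list(c(0.5, 0.9, 0.9)), a1, lambdaNoobj = 0),
               objectnessLoss(list(c(0.5, 0.0, 0.3)), a1, lambdaNoobj = 0))
  set.seed(51)
  for (i in 1:1000) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    ind <- list(rbinom(n1, 1, 0.2), rbinom(n2, 1, 0.2))
    conf <- list(runif(n1), runif(n2))
    lam <- runif(1)
    a <- list(objectness = ind)
    expect_equal(objectnessLoss(conf, a, lam),
                 oracleObjectnessLoss(conf, ind, lam), tolerance = 1e-9)
  }
})

test_that("perfect confidence predictions give (near) zero objectness loss", {
  ind <- list(c(1, 0, 1, 0, 0))
  a <- list(objectness = ind)
  expect_lt(objectnessLoss(ind, a), 1e-5)
})

test_that("class loss matches its oracle and vanishes without objects", {
  a0 <- list(objectness = list(rep(0, 4)),
             classTargets = list(matrix(0, 4, 2)))
  expect_equal(classLoss(list(matrix(runif(8), 4, 2)), a0), 0)
  # one object slot, two classes, uniform prediction: -2 log(0.5)
  tg <- matrix(0, 3, 2); tg[2, 1] <- 1
  a1 <- list(objectness = list(c(0, 1, 0)), classTargets = list(tg))
  expect_equal(classLoss(list(matrix(0.5, 3, 2)), a1), -2 * log(0.5),
               tolerance = 1e-9)
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    ind <- rbinom(n, 1, 0.4)
    tg <- matrix(0, n, 2)
    tg[cbind(seq_len(n), sample(1:2, n, TRUE))] <- 1
    probs <- matrix(runif(2 * n), n, 2)
    a <- list(objectness = list(ind), classTargets = list(tg))
    expect_equal(classLoss(list(probs), a),
                 oracleClassLoss(list(probs), list(ind), list(tg)),
                 tolerance = 1e-9)
  }
})

test_that("exact one-hot class predictions give (near) zero class loss", {
  tg <- matrix(c(1, 0, 0, 1), 2, 2)
  a <- list(objectness = list(c(1, 1)), classTargets = list(tg))
  expect_lt(classLoss(list(tg), a), 1e-5)
})

test_that("totalLoss is the weighted sum of its reported components", {
  set.seed(71)
  anch <- anchorSet(list(rbind(c(10, 20), c(20, 10))), 8L, 64L)
  boxes <- data.frame(x_min = c(5, 30), y_min = c(8, 40),
                      x_max = c(20, 50), y_max = c(30, 55),
                      class_id = c(0L, 1L))
  asg <- assignTargets(boxes, anch)
  S <- asg$gridSizes[1]; B <- 2
  for (rep in 1:20) {
    pred <- list(
      boxes = list(t(vapply(seq_len(nrow(asg$slots[[1]])), function(r)
        randomBox(60, 2), numeric(4)))),
      confidence = list(runif(S * S * B)),
      classProb = list(matrix(runif(S * S * B * 2), ncol = 2)))
    w <- runif(3, 0.2, 2); lam <- runif(1)
    tl <- totalLoss(pred, asg, weights = w, lambdaNoobj = lam)
    expect_equal(tl$total,
                 w[1] * tl$loc + w[2] * tl$obj + w[3] * tl$cls,
                 tolerance = 1e-12)
    # components recompute from the standalone loss functions
    expect_equal(tl$obj, objectnessLoss(pred$confidence, asg, lam))
    expect_equal(tl$cls, classLoss(pred$classProb, asg))
  }
  # perfect predictions: zero everywhere (up to probability clamping)
  perfect <- list(
    boxes = list(as.matrix(asg$slots[[1]][, c("x_min", "y_min",
                                              "x_max", "y_max")])),
    confidence = list(as.numeric(asg$objectness[[1]])),
    classProb = list(asg$classTargets[[1]]))
  tl <- totalLoss(perfect, asg)
  expect_equal(tl$loc, 0, tolerance = 1e-9)
  expect_lt(tl$total, 1e-4)
})
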