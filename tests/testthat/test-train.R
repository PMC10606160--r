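# Training tests run on small 160-px scenes so the whole file stays fast.

tinyScene <- function(seed, n = 6, nDic = 2) {
  deskSceneSpec(imageSize = 160, nChromosomes = n, nDicentric = nDic,
                lengthRange = c(22, 34), widthRange = c(8, 11),
                seed = seed)
}

tinyModel <- function(samples, seed = 3) {
  anch <- anchorSet(list(rbind(c(24, 12), c(12, 24), c(20, 20)),
                         rbind(c(32, 18), c(18, 32), c(28, 28))),
                    c(8L, 16L), 160L)
  chromosomeDetector(anch, seed = seed)
}

test_that("network analytic gradients match finite differences", {
  s <- generateMetaphase(tinyScene(11, n = 5))
  model <- tinyModel(list(s))
  input <- dicentricAssay:::imageToInput(sampleImage(s))
  asg <- assignTargets(sampleBoxes(s), model@anchors)
  lossOf <- function(m) {
    st <- dicentricAssay:::net_forward(m@weights, m@config$layers, input,
                                       160L, 160L, TRUE)
    heads <- lapply(seq_along(m@config$heads), function(sc) {
      j <- m@config$heads[sc] + 1L
      dicentricAssay:::headToArray(st$acts[[j]], st$H[j], st$W[j])
    })
    dicentricAssay:::headLossGrads(m, heads, asg, c(1, 1, 1), 0.5)
  }
  base <- lossOf(model)
  st <- dicentricAssay:::net_forward(model@weights, model@config$layers,
                                     input, 160L, 160L, TRUE)
  bg <- dicentricAssay:::net_backward(model@weights, model@config$layers,
                                      st$acts, st$H, st$W, base$grads)
  set.seed(42)
  for (l in c(1, 3, 5, 7, 10)) {
    for (rep in 1:3) {
      i <- sample(length(model@weights[[l]]$W), 1)
      eps <- 1e-5
      mp <- model; mp@weights[[l]]$W[i] <- mp@weights[[l]]$W[i] + eps
      mm <- model; mm@weights[[l]]$W[i] <- mm@weights[[l]]$W[i] - eps
      num <- (lossOf(mp)$total - lossOf(mm)$total) / (2 * eps)
      ana <- bg[[l]]$dW[i]
      expect_lt(abs(num - ana) / max(1e-4, abs(num), abs(ana)), 0.02)
    }
  }
})

test_that("training reduces the loss on a small learnable problem", {
  samples <- lapply(1:10, function(i) generateMetaphase(tinyScene(600 + i)))
  model <- tinyModel(samples)
  fit <- trainDetector(model, samples, epochs = 8, batchSize = 4,
                       lr = 0.02, clipNorm = 20, lossWeights = c(10, 1, 2),
                       seed = 5)
  h <- fit$history
  expect_equal(nrow(h), 8L)
  expect_true(all(is.finite(h$total)))
  expect_lt(h$total[8], h$total[1])
  expect_equal(h$total, 10 * h$loc + h$obj + 2 * h$cls, tolerance = 1e-12)
})

test_that("training is bit-deterministic under its seed", {
  samples <- lapply(1:4, function(i) generateMetaphase(tinyScene(700 + i)))
  model <- tinyModel(samples)
  a <- trainDetector(model, samples, epochs = 3, batchSize = 2, lr = 0.01,
                     seed = 9)
  b <- trainDetector(model, samples, epochs = 3, batchSize = 2, lr = 0.01,
                     seed = 9)
  expect_identical(a$history, b$history)
  expect_identical(a$model@weights, b$model@weights)
  # inference determinism too
  img <- sampleImage(samples[[1]])
  expect_identical(predictDetections(a$model, img, 0.1),
                   predictDetections(b$model, img, 0.1))
})

test_that("an untrained model with conf threshold 1 yields nothing", {
  s <- generateMetaphase(tinyScene(12))
  model <- tinyModel(list(s))
  det <- predictDetections(model, sampleImage(s), confThreshold = 1)
  expect_equal(nrow(det), 0L)
})

test_that("checkpoint save/load round trips the model", {
  s <- generateMetaphase(tinyScene(13))
  model <- tinyModel(list(s))
  f <- tempfile(fileext = ".rds")
  saveDetector(model, f)
  back <- loadDetector(f)
  expect_identical(back@weights, model@weights)
  expect_identical(back@anchors@anchors, model@anchors@anchors)
  img <- sampleImage(s)
  expect_identical(predictDetections(back, img, 0.05),
                   predictDetections(model, img, 0.05))
  # init from a checkpoint reproduces those weights in a fresh model
  warm <- chromosomeDetector(model@anchors, seed = 99, init = f)
  expect_identical(warm@weights, model@weights)
})

test_that("splitDataset partitions exhaustively and deterministically", {
  sp <- splitDataset(100, c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(lengths(sp), c(train = 60L, validation = 20L, test = 20L))
  expect_equal(sort(unlist(sp, use.names = FALSE)), 1:100)
  expect_identical(sp, splitDataset(100, c(0.6, 0.2, 0.2), seed = 4))
  # list input returns list partitions
  lst <- splitDataset(as.list(1:10), c(0.5, 0.3, 0.2), seed = 1)
  expect_equal(sum(lengths(lst)), 10L)
  expect_warning(splitDataset(3, c(0.9, 0.05, 0.05), seed = 1), "empty")
  # the paper-scale split sizes are representable
  ref <- splitDataset(1456, c(887, 380, 189) / 1456, seed = 1)
  expect_equal(unname(lengths(ref)), c(887L, 380L, 189L))
})
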