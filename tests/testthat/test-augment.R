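test_that("extractPatch recovers the generator's mask inside the box", {
  spec <- deskSceneSpec(nChromosomes = 6, nDicentric = 1, seed = 61)
  s <- generateMetaphase(spec)
  b <- sampleBoxes(s)
  masks <- sampleMasks(s)
  for (k in seq_len(nrow(b))) {
    p <- extractPatch(sampleImage(s), b[k, , drop = FALSE])
    expect_s4_class(p, "ChromosomePatch")
    expect_equal(dim(p@mask), dim(masks[[k]]))
    # segmentation within the crop reproduces the rendered mask almost
    # exactly (noise can flip isolated border pixels)
    agree <- mean(p@mask == masks[[k]])
    expect_gte(agree, 0.98)
    expect_equal(p@classId, b$class_id[k])
  }
  expect_error(extractPatch(matrix(150, 50, 50), c(5, 5, 20, 20)),
               "constant")
  # two blobs in a crop: only the larger is kept
  img <- matrix(220, 40, 40)
  img[5:20, 5:12] <- 50     # large blob
  img[30:33, 30:32] <- 50   # small blob
  p <- extractPatch(img, c(0, 0, 40, 40), classId = 0L)
  expect_equal(sum(p@mask), 16L * 8L)
})

test_that("pastePatch composites only mask pixels and appends one box", {
  spec <- deskSceneSpec(nChromosomes = 0, nDicentric = 0, seed = 71,
                        noiseSd = 0)
  empty <- generateMetaphase(spec)
  src <- generateMetaphase(deskSceneSpec(nChromosomes = 1, nDicentric = 1,
                                         seed = 72))
  patch <- extractPatch(sampleImage(src), sampleBoxes(src)[1, , drop = FALSE])
  set.seed(5)
  out <- pastePatch(empty, patch, transform = FALSE)
  expect_equal(nrow(sampleBoxes(out)), 1L)
  expect_equal(sampleBoxes(out)$class_id, 1L)
  # pixels outside the pasted mask are untouched
  changed <- sampleImage(out) != sampleImage(empty)
  expect_equal(sum(changed & !(sampleLabels(out) == 1L)), 0L)
  # the appended box is tight around the pasted mask
  m <- sampleMasks(out)[[1]]
  expect_true(any(m[1, ]) && any(m[nrow(m), ]) && any(m[, 1]) &&
              any(m[, ncol(m)]))
})

test_that("pastePatch fails cleanly when no free position exists", {
  # a canvas whose foreground occupies every pixel leaves no room
  full <- new("MetaphaseSample",
              image = matrix(60, 64, 64),
              boxes = data.frame(x_min = 0, y_min = 0, x_max = 64,
                                 y_max = 64, class_id = 0L),
              labels = matrix(1L, 64, 64),
              spec = sceneSpec(imageSize = 64, nChromosomes = 1,
                               seed = 1))
  src <- generateMetaphase(deskSceneSpec(nChromosomes = 1, nDicentric = 0,
                                         seed = 73))
  patch <- extractPatch(sampleImage(src),
                        sampleBoxes(src)[1, , drop = FALSE])
  set.seed(9)
  expect_error(pastePatch(full, patch, margin = 2, maxAttempts = 50,
                          transform = FALSE),
               "50 attempts")
})

test_that("repeated pastes never overlap existing foreground", {
  spec <- deskSceneSpec(nChromosomes = 4, nDicentric = 1, seed = 81)
  s <- generateMetaphase(spec)
  pool <- buildPatchPool(list(s), 0L)
  set.seed(11)
  before <- 4L
  for (i in 1:30) {
    res <- tryCatch(pastePatch(s, pool[[sample.int(length(pool), 1)]]),
                    error = function(e) NULL)
    if (is.null(res)) next
    s <- res
  }
  n <- nrow(sampleBoxes(s))
  expect_gt(n, before)
  # instance labels partition the foreground: per-instance areas sum to
  # the occupied area, and Otsu re-segmentation finds n separate objects
  lab <- sampleLabels(s)
  expect_equal(sum(lab > 0), sum(tabulate(lab[lab > 0], n)))
  cc <- connectedComponents(sampleImage(s) <= otsuThreshold(sampleImage(s)))
  kept <- cc$regions[cc$regions$area >= 20, ]
  expect_equal(nrow(kept), n)
})

test_that("balanceDataset reaches the target dicentric count exactly", {
  specs <- lapply(1:8, function(i)
    deskSceneSpec(nChromosomes = 5, nDicentric = as.integer(i <= 2),
                  seed = 200 + i))
  samples <- lapply(specs, generateMetaphase)
  dic <- buildPatchPool(samples, 1L)
  nor <- buildPatchPool(samples, 0L)
  expect_equal(length(dic), 2L)
  bal <- balanceDataset(samples, dic, nor, targetDicentric = 10,
                        normalPerDicentric = 1L, seed = 5)
  total <- sum(vapply(bal$samples, function(s)
    sum(sampleBoxes(s)$class_id == 1L), 0L))
  expect_equal(total, 10L)
  expect_equal(bal$dicentricCount, 10L)
  # no-op when the target equals the current count
  same <- balanceDataset(samples, dic, nor, targetDicentric = 2, seed = 5)
  expect_identical(lapply(same$samples, sampleBoxes),
                   lapply(samples, sampleBoxes))
  expect_error(balanceDataset(samples, dic, nor, targetDicentric = 1),
               "below the current count")
  expect_error(balanceDataset(samples, list(), nor, targetDicentric = 5),
               "nonempty")
})

test_that("balanceDataset is deterministic under its seed", {
  samples <- lapply(1:4, function(i)
    generateMetaphase(deskSceneSpec(nChromosomes = 4,
                                    nDicentric = as.integer(i == 1),
                                    seed = 300 + i)))
  dic <- buildPatchPool(samples, 1L)
  nor <- buildPatchPool(samples, 0L)
  a <- balanceDataset(samples, dic, nor, targetDicentric = 6, seed = 9)
  b <- balanceDataset(samples, dic, nor, targetDicentric = 6, seed = 9)
  expect_identical(lapply(a$samples, sampleImage),
                   lapply(b$samples, sampleImage))
  expect_identical(lapply(a$samples, sampleBoxes),
                   lapply(b$samples, sampleBoxes))
})
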