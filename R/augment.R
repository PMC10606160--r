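## Copy-paste augmentation for the rare dicentric class: segment chromosome
## patches with a transparent background and composite them into images
## without ever touching existing foreground.

#' Extract a background-transparent chromosome patch
#'
#' Crops `box` from `image`, segments the crop with [otsuThreshold()]
#' (foreground = darker side), keeps the largest connected component as the
#' transparency mask and tight-crops to it. Only mask pixels are composited
#' when the patch is later pasted, so the background becomes transparent.
#'
#' @param image numeric gray-level matrix.
#' @param box single-row box data.frame or corner vector; must lie within
#'   the image.
#' @param classId class recorded on the patch (defaults to the box's
#'   `class_id` if present, else 0).
#' @param source provenance string stored on the patch.
#' @return A [ChromosomePatch-class].
#' @export
extractPatch <- function(image, box, classId = NULL, source = "") {
  b <- boxMatrix(box)
  if (nrow(b) != 1L) stop("extractPatch takes a single box", call. = FALSE)
  if (b[1] < 0 || b[2] < 0 || b[3] > ncol(image) || b[4] > nrow(image))
    stop("box outside image", call. = FALSE)
  if (is.null(classId))
    classId <- if (is.data.frame(box) && "class_id" %in% names(box))
      box$class_id[1] else 0L
  crop <- image[(b[2] + 1):b[4], (b[1] + 1):b[3], drop = FALSE]
  thr <- tryCatch(otsuThreshold(crop), error = function(e)
    stop("extraction failed: constant crop", call. = FALSE))
  fg <- crop <= thr
  cc <- connectedComponents(fg)
  if (!nrow(cc$regions))
    stop("extraction failed: empty foreground", call. = FALSE)
  big <- cc$regions$id[which.max(cc$regions$area)]
  mask <- cc$labels == big
  rr <- range(which(rowSums(mask) > 0)); rc <- range(which(colSums(mask) > 0))
  new("ChromosomePatch",
      image = crop[rr[1]:rr[2], rc[1]:rc[2], drop = FALSE],
      mask = mask[rr[1]:rr[2], rc[1]:rc[2], drop = FALSE],
      classId = as.integer(classId), source = as.character(source))
}

## One of the 8 axis-aligned orientations (4 rotations x optional flip).
orientPatch <- function(patch, orientation) {
  img <- patch@image; msk <- patch@mask
  if (orientation >= 4L) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  for (r in seq_len(orientation %% 4L)) {
    img <- t(img[rev(seq_len(nrow(img))), , drop = FALSE])
    msk <- t(msk[rev(seq_len(nrow(msk))), , drop = FALSE])
  }
  new("ChromosomePatch", image = img, mask = msk, classId = patch@classId,
      source = patch@source)
}

#' Paste a patch into a metaphase sample without superposition
#'
#' Samples positions uniformly until the patch mask (dilated by `margin`
#' pixels) overlaps zero pixels of the existing foreground, then composites
#' the patch's mask pixels into the image, extends the instance label
#' matrix and appends the patch's bounding box. Pixels outside the mask are
#' untouched. Fails with a placement error after `maxAttempts` rejected
#' positions.
#'
#' @param sample a [MetaphaseSample-class].
#' @param patch a [ChromosomePatch-class] smaller than the image.
#' @param margin clearance in pixels between the pasted mask and existing
#'   foreground (default 2).
#' @param maxAttempts position draws before giving up (default 100).
#' @param transform randomly flip/rotate the patch by 90 degrees before
#'   pasting (default TRUE).
#' @return the updated [MetaphaseSample-class].
#' @export
pastePatch <- function(sample, patch, margin = 2L, maxAttempts = 100L,
                       transform = TRUE) {
  if (transform) patch <- orientPatch(patch, sample.int(8L, 1L) - 1L)
  img <- sample@image; lab <- sample@labels
  sz <- dim(img)
  if (nrow(patch@mask) >= sz[1] || ncol(patch@mask) >= sz[2])
    stop("patch does not fit the image", call. = FALSE)
  halo <- dilateMask(patch@mask, margin)
  ph <- nrow(halo); pw <- ncol(halo)
  for (att in seq_len(maxAttempts)) {
    ry <- sample.int(sz[1] - ph + 1L, 1L)
    rx <- sample.int(sz[2] - pw + 1L, 1L)
    occ <- lab[ry:(ry + ph - 1L), rx:(rx + pw - 1L)] > 0L
    if (any(occ & halo)) next
    rows <- (ry + margin):(ry + margin + nrow(patch@mask) - 1L)
    cols <- (rx + margin):(rx + margin + ncol(patch@mask) - 1L)
    id <- nrow(sample@boxes) + 1L
    subI <- img[rows, cols]; subI[patch@mask] <- patch@image[patch@mask]
    img[rows, cols] <- subI
    subL <- lab[rows, cols]; subL[patch@mask] <- id
    lab[rows, cols] <- subL
    boxes <- rbind(sample@boxes, data.frame(
      x_min = cols[1] - 1L, y_min = rows[1] - 1L,
      x_max = cols[length(cols)], y_max = rows[length(rows)],
      class_id = patch@classId))
    return(new("MetaphaseSample", image = img, boxes = boxes, labels = lab,
               spec = sample@spec))
  }
  stop(sprintf("no superposition-free position found in %d attempts",
               maxAttempts), call. = FALSE)
}

#' Build a patch pool from labeled samples
#'
#' Extracts a [ChromosomePatch-class] from every box of class `classId`
#' across a list of samples (or image/box pairs). Boxes whose extraction
#' fails are skipped.
#'
#' @param samples list of [MetaphaseSample-class], or a list with `images`
#'   and `boxes` elements as returned by [readDataset()].
#' @param classId class to harvest (1 = dicentric).
#' @return list of [ChromosomePatch-class].
#' @export
buildPatchPool <- function(samples, classId) {
  if (!is.null(samples$images)) {
    images <- samples$images; boxes <- samples$boxes
  } else {
    images <- lapply(samples, sampleImage)
    boxes <- lapply(samples, sampleBoxes)
  }
  pool <- list()
  for (i in seq_along(images)) {
    b <- boxes[[i]]
    for (k in which(b$class_id == classId)) {
      p <- tryCatch(extractPatch(images[[i]], b[k, , drop = FALSE],
                                 classId = classId,
                                 source = sprintf("image %d box %d", i, k)),
                    error = function(e) NULL)
      if (!is.null(p)) pool[[length(pool) + 1L]] <- p
    }
  }
  pool
}

#' Rebalance the dicentric class by copy-paste augmentation
#'
#' Pastes dicentric patches (sampled with replacement from
#' `dicentricPool`) into randomly chosen images until the dataset's total
#' dicentric box count reaches `targetDicentric`. After each successful
#' dicentric paste, `normalPerDicentric` normal patches are pasted
#' alongside so the detector cannot learn to recognize dicentrics by their
#' composited edges alone. Deterministic under `seed`.
#'
#' @param samples list of [MetaphaseSample-class].
#' @param dicentricPool,normalPool nonempty lists of
#'   [ChromosomePatch-class] of class 1 and 0 respectively.
#' @param targetDicentric desired total number of class-1 boxes (>= the
#'   current count).
#' @param normalPerDicentric normal patches pasted per dicentric paste
#'   (default 1).
#' @param margin,maxAttempts passed to [pastePatch()].
#' @param transform random patch flips/rotations (default TRUE).
#' @param seed RNG seed.
#' @return list with `samples` (augmented), `added` (dicentric pastes) and
#'   `dicentricCount`.
#' @export
balanceDataset <- function(samples, dicentricPool, normalPool,
                           targetDicentric, normalPerDicentric = 1L,
                           margin = 2L, maxAttempts = 100L,
                           transform = TRUE, seed = 1L) {
  if (!length(dicentricPool) || !length(normalPool))
    stop("patch pools must be nonempty", call. = FALSE)
  count <- sum(vapply(samples, function(s) sum(s@boxes$class_id == 1L), 0L))
  if (targetDicentric < count)
    stop("targetDicentric below the current count (", count, ")",
         call. = FALSE)
  set.seed(seed)
  added <- 0L
  failures <- 0L
  maxFailures <- 20L * max(1L, targetDicentric - count)
  while (count < targetDicentric) {
    i <- sample.int(length(samples), 1L)
    p <- dicentricPool[[sample.int(length(dicentricPool), 1L)]]
    res <- tryCatch(pastePatch(samples[[i]], p, margin, maxAttempts,
                               transform),
                    error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      if (failures > maxFailures)
        stop(sprintf("augmentation stalled: reached %d of %d dicentric boxes",
                     count, targetDicentric), call. = FALSE)
      next
    }
    samples[[i]] <- res
    count <- count + 1L
    added <- added + 1L
    for (j in seq_len(normalPerDicentric)) {
      np <- normalPool[[sample.int(length(normalPool), 1L)]]
      res <- tryCatch(pastePatch(samples[[i]], np, margin, maxAttempts,
                                 transform),
                      error = function(e) NULL)
      if (!is.null(res)) samples[[i]] <- res
    }
  }
  list(samples = samples, added = added, dicentricCount = count)
}
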