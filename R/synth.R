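## Synthetic Giemsa-like metaphase generator. Chromosomes are rendered as
## bands of varying radius around a quadratic Bezier medial axis; a
## centromere is a cosine-shaped notch in the radius profile. A normal
## chromosome has one centromeric constriction, a dicentric has two.

quadBezier <- function(t, p0, p1, p2) {
  u <- 1 - t
  cbind(u^2 * p0[1] + 2 * u * t * p1[1] + t^2 * p2[1],
        u^2 * p0[2] + 2 * u * t * p1[2] + t^2 * p2[2])
}

## Radius profile along the axis: half-width minus cosine notches at the
## centromere positions. Notch half-width 0.12 in axis parameter units
## keeps constrictions interior and well separated.
radiusProfile <- function(t, width, nCentromeres, constrictionDepth,
                          notchHalfWidth = 0.12) {
  centers <- if (nCentromeres == 1L) 0.5 else c(0.32, 0.68)
  notch <- rep(0, length(t))
  for (tc in centers) {
    inside <- abs(t - tc) < notchHalfWidth
    notch[inside] <- pmax(notch[inside],
      0.5 * (1 + cos(pi * (t[inside] - tc) / notchHalfWidth)))
  }
  (width / 2) * (1 - constrictionDepth * notch)
}

#' Render a single synthetic chromosome patch
#'
#' Draws an elongated, optionally bent band: the medial axis is a quadratic
#' Bezier of the requested length and bend, and the band radius follows a
#' cosine-notch profile with `nCentromeres` interior constrictions, the
#' visual cue that separates a normal (one centromere) from a dicentric
#' (two centromeres) chromosome. The patch is tight-cropped to the mask.
#'
#' @param length chromosome length in pixels (must exceed `width`).
#' @param width chromosome width in pixels.
#' @param curvature bend of the medial axis in radians (0 = straight).
#' @param nCentromeres 1 (normal) or 2 (dicentric).
#' @param constrictionDepth fraction of the width removed at each
#'   centromere (default 0.55).
#' @param angle rotation of the axis in radians (default 0, axis along x).
#' @param intensityForeground,intensityBackground gray levels used for the
#'   returned `image`.
#' @return list with `mask` (logical matrix, tight), `image` (numeric
#'   matrix, foreground/background gray levels), `radius` (the radius
#'   profile along the axis) and `axisT` (its parameter grid).
#' @examples
#' p <- renderChromosome(40, 10, curvature = 0.5, nCentromeres = 2)
#' dim(p$mask)
#' @export
renderChromosome <- function(length, width, curvature, nCentromeres,
                             constrictionDepth = 0.55, angle = 0,
                             intensityForeground = 60,
                             intensityBackground = 220) {
  if (length <= 0 || width <= 0 || length <= width)
    stop("need length > width > 0", call. = FALSE)
  if (!nCentromeres %in% c(1L, 2L))
    stop("nCentromeres must be 1 or 2", call. = FALSE)
  ## medial axis: chord of `length` bent by `curvature` radians
  p0 <- c(0, 0); p2 <- c(length, 0)
  p1 <- c(length / 2, length * tan(curvature / 2) / 2)
  M <- max(16L, ceiling(length * 1.5))
  tgrid <- seq(0, 1, length.out = M)
  axis <- quadBezier(tgrid, p0, p1, p2)
  if (angle != 0) {
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2)
    axis <- axis %*% t(R)
  }
  r <- radiusProfile(tgrid, width, as.integer(nCentromeres),
                     constrictionDepth)
  ## rasterize on a grid just covering axis +- max radius
  pad <- width / 2 + 1
  x0 <- floor(min(axis[, 1]) - pad); x1 <- ceiling(max(axis[, 1]) + pad)
  y0 <- floor(min(axis[, 2]) - pad); y1 <- ceiling(max(axis[, 2]) + pad)
  xs <- seq(x0, x1) + 0.5; ys <- seq(y0, y1) + 0.5
  px <- rep(xs, each = base::length(ys))
  py <- rep(ys, times = base::length(xs))
  inside <- rep(FALSE, base::length(px))
  for (m in seq_len(M)) {
    inside <- inside |
      ((px - axis[m, 1])^2 + (py - axis[m, 2])^2 <= r[m]^2)
  }
  mask <- matrix(inside, nrow = base::length(ys))   # rows = y, cols = x
  keepR <- which(rowSums(mask) > 0); keepC <- which(colSums(mask) > 0)
  mask <- mask[keepR[1]:keepR[base::length(keepR)],
               keepC[1]:keepC[base::length(keepC)], drop = FALSE]
  image <- matrix(intensityBackground, nrow(mask), ncol(mask))
  image[mask] <- intensityForeground
  list(mask = mask, image = image, radius = r, axisT = tgrid)
}

## Chebyshev dilation of a logical mask by r pixels, with r rings of
## padding so dilation can grow past the original crop.
dilateMask <- function(mask, r) {
  if (r <= 0) return(mask)
  nr <- nrow(mask) + 2L * r; nc <- ncol(mask) + 2L * r
  out <- matrix(FALSE, nr, nc)
  for (dy in -r:r) for (dx in -r:r) {
    out[(1 + r + dy):(nr - r + dy), (1 + r + dx):(nc - r + dx)] <-
      out[(1 + r + dy):(nr - r + dy), (1 + r + dx):(nc - r + dx)] | mask
  }
  out
}

#' Generate one synthetic metaphase spread
#'
#' Places `nChromosomes` rendered chromosomes (exactly `nDicentric` of them
#' with two centromeric constrictions) on a light background without any
#' pixel overlap and with at least `minGap` pixels of clearance (Chebyshev
#' metric) between foreground masks, by rejection-sampling positions.
#' Additive Gaussian noise is applied last and clipped to \[0, 255\]. The
#' RNG is seeded from `spec@seed`, so the same spec always yields the same
#' sample, bit for bit.
#'
#' @param spec a [SceneSpec-class].
#' @param maxAttempts placement attempts per chromosome before giving up
#'   (default 200).
#' @return A [MetaphaseSample-class] with exact ground truth.
#' @examples
#' s <- generateMetaphase(deskSceneSpec(nChromosomes = 4, nDicentric = 1,
#'                                      seed = 3))
#' sampleBoxes(s)
#' @export
generateMetaphase <- function(spec, maxAttempts = 200L) {
  validObject(spec)
  set.seed(spec@seed)
  n <- spec@nChromosomes
  sz <- spec@imageSize
  image <- matrix(spec@intensityBackground, sz, sz)
  labels <- matrix(0L, sz, sz)
  classes <- integer(0)
  if (n > 0) {
    classes <- sample(c(rep(1L, spec@nDicentric),
                        rep(0L, n - spec@nDicentric)))
  }
  boxes <- emptyBoxes()
  for (k in seq_len(n)) {
    len <- runif(1, spec@lengthRange[1], spec@lengthRange[2])
    wid <- runif(1, spec@widthRange[1], spec@widthRange[2])
    curv <- runif(1, spec@curvatureRange[1], spec@curvatureRange[2]) *
      sample(c(-1, 1), 1)
    ang <- runif(1, 0, pi)
    patch <- renderChromosome(len, wid, curv,
                              nCentromeres = classes[k] + 1L,
                              constrictionDepth = spec@constrictionDepth,
                              angle = ang,
                              intensityForeground = spec@intensityForeground,
                              intensityBackground = spec@intensityBackground)
    halo <- dilateMask(patch$mask, spec@minGap)
    ph <- nrow(halo); pw <- ncol(halo)
    if (ph >= sz || pw >= sz)
      stop("chromosome ", k, " does not fit the image", call. = FALSE)
    placed <- FALSE
    for (att in seq_len(maxAttempts)) {
      ry <- sample.int(sz - ph + 1L, 1L)      # top row of the halo crop
      rx <- sample.int(sz - pw + 1L, 1L)
      occ <- labels[ry:(ry + ph - 1L), rx:(rx + pw - 1L)] > 0L
      if (!any(occ & halo)) {
        my <- ry + spec@minGap; mx <- rx + spec@minGap
        rows <- my:(my + nrow(patch$mask) - 1L)
        cols <- mx:(mx + ncol(patch$mask) - 1L)
        sub <- labels[rows, cols]
        sub[patch$mask] <- k
        labels[rows, cols] <- sub
        img <- image[rows, cols]
        img[patch$mask] <- spec@intensityForeground
        image[rows, cols] <- img
        boxes <- rbind(boxes, data.frame(
          x_min = cols[1] - 1L, y_min = rows[1] - 1L,
          x_max = cols[length(cols)], y_max = rows[length(rows)],
          class_id = classes[k]))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("placement failed for chromosome %d after %d attempts (image too crowded)",
                   k, maxAttempts), call. = FALSE)
  }
  if (spec@noiseSd > 0)
    image <- image + rnorm(length(image), 0, spec@noiseSd)
  image <- pmin(pmax(image, 0), 255)
  if (spec@invert) image <- 255 - image
  new("MetaphaseSample", image = image, boxes = boxes, labels = labels,
      spec = spec)
}

#' Generate a list of synthetic metaphase samples in memory
#'
#' Convenience wrapper producing `nImages` samples from a template spec.
#' Image `i` uses seed `seed + i - 1`. When a `doseModel` and `dose` are
#' supplied, the per-image dicentric count is drawn from a Poisson
#' distribution with mean `F(dose)` from the linear-quadratic model
#' (capped at `nChromosomes`), emulating the dose dependence of the
#' dicentric yield; otherwise the template's `nDicentric` is used.
#'
#' @param nImages number of samples (>= 1).
#' @param spec template [SceneSpec-class].
#' @param seed base RNG seed.
#' @param doseModel optional [DoseResponseModel-class].
#' @param dose absorbed dose in Gy used with `doseModel`.
#' @param maxAttempts per-chromosome placement cap.
#' @return list of [MetaphaseSample-class].
#' @export
generateSamples <- function(nImages, spec, seed = spec@seed,
                            doseModel = NULL, dose = NULL,
                            maxAttempts = 200L) {
  stopifnot(nImages >= 1)
  nDic <- rep(spec@nDicentric, nImages)
  if (!is.null(doseModel)) {
    if (is.null(dose)) stop("dose required with doseModel", call. = FALSE)
    set.seed(seed)
    nDic <- pmin(rpois(nImages, doseResponse(doseModel, dose)),
                 spec@nChromosomes)
  }
  lapply(seq_len(nImages), function(i) {
    si <- spec
    si@seed <- as.integer(seed + i - 1L)
    si@nDicentric <- as.integer(nDic[i])
    generateMetaphase(si, maxAttempts)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `nImages` synthetic metaphases as 8-bit grayscale PNGs with YOLO
#' txt labels (one `class cx cy w h` line per box, normalized to \[0, 1\])
#' and a YAML manifest recording the spec, seeds and per-image dicentric
#' counts. With a `doseModel` and `dose`, per-image dicentric counts are
#' Poisson with mean F(dose), as in [generateSamples()].
#'
#' @param nImages number of images (>= 1).
#' @param spec template [SceneSpec-class].
#' @param outDir output directory; `images/` and `labels/` are created
#'   inside it.
#' @param seed base RNG seed.
#' @param doseModel,dose optional dose policy for dicentric counts.
#' @param maxAttempts per-chromosome placement cap.
#' @return invisibly, the manifest list.
#' @export
generateDataset <- function(nImages, spec, outDir, seed = spec@seed,
                            doseModel = NULL, dose = NULL,
                            maxAttempts = 200L) {
  stopifnot(nImages >= 1)
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create ", outDir, call. = FALSE)
  samples <- generateSamples(nImages, spec, seed, doseModel, dose,
                             maxAttempts)
  entries <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    stem <- sprintf("img_%05d", i)
    writeGrayPNG(sampleImage(samples[[i]]),
                 file.path(outDir, "images", paste0(stem, ".png")))
    writeLabels(sampleBoxes(samples[[i]]), spec@imageSize,
                file.path(outDir, "labels", paste0(stem, ".txt")))
    entries[[i]] <- list(stem = stem, seed = samples[[i]]@spec@seed,
                         n_dicentric = sum(sampleBoxes(samples[[i]])$class_id == 1L))
  }
  manifest <- list(
    n_images = nImages, seed = seed,
    dose = if (is.null(dose)) NULL else dose,
    spec = specAsList(spec),
    images = entries)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}

specAsList <- function(spec) {
  list(image_size = spec@imageSize, n_chromosomes = spec@nChromosomes,
       n_dicentric = spec@nDicentric,
       length_range = spec@lengthRange, width_range = spec@widthRange,
       constriction_depth = spec@constrictionDepth,
       curvature_range = spec@curvatureRange,
       intensity_foreground = spec@intensityForeground,
       intensity_background = spec@intensityBackground,
       noise_sd = spec@noiseSd, min_gap = spec@minGap,
       invert = spec@invert, seed = spec@seed)
}

specFromList <- function(x) {
  sceneSpec(imageSize = x$image_size, nChromosomes = x$n_chromosomes,
            nDicentric = x$n_dicentric, lengthRange = unlist(x$length_range),
            widthRange = unlist(x$width_range),
            constrictionDepth = x$constriction_depth,
            curvatureRange = unlist(x$curvature_range),
            intensityForeground = x$intensity_foreground,
            intensityBackground = x$intensity_background,
            noiseSd = x$noise_sd, minGap = x$min_gap,
            invert = x$invert, seed = x$seed)
}
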