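## Automatic chromosome labeling: global Otsu threshold, connected
## components, tight bounding boxes. Touching chromosomes merge into one
## region; the procedure assumes separable objects.

#' Otsu's threshold
#'
#' Returns the gray level maximizing the between-class variance of the
#' image histogram over the 256 8-bit levels (gray levels are rounded into
#' bins first). Pixels at or below the returned level form the dark class.
#' Ties are broken toward the lowest maximizing level.
#'
#' @param image numeric gray-level matrix in \[0, 255\] (or a histogram of
#'   256 counts).
#' @return integer threshold in 0..254.
#' @examples
#' img <- matrix(c(rep(10, 50), rep(200, 50)), 10)
#' otsuThreshold(img)
#' @export
otsuThreshold <- function(image) {
  if (length(image) == 256 && is.null(dim(image))) {
    counts <- as.numeric(image)
  } else {
    g <- round(pmin(pmax(as.numeric(image), 0), 255))
    counts <- as.numeric(tabulate(g + 1L, nbins = 256L))
  }
  if (sum(counts > 0) < 2)
    stop("degenerate input: image has fewer than 2 distinct gray levels",
         call. = FALSE)
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)                     # class 0 = levels <= t
  sum0 <- cumsum(counts * levels)
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, sum0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum0[256] - sum0) / w1, 0)
  sigmaB <- w0 * w1 * (mu0 - mu1)^2
  sigmaB[256] <- -Inf                      # t = 255 puts everything in one class
  as.integer(levels[which.max(sigmaB)])    # which.max takes the lowest tie
}

#' Connected components of a binary mask
#'
#' Labels maximal connected foreground components (8-connectivity by
#' default) and summarizes each as a region with its area and tight
#' bounding box. Regions are ordered deterministically by
#' `(y_min, x_min)` and the label matrix is renumbered to match.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8 (default 8).
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `regions` (data.frame: `id`, `area`, `x_min`, `y_min`, `x_max`,
#'   `y_max`, 0-based half-open pixel corners).
#' @export
connectedComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  lab <- label_components(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L)
    return(list(labels = lab,
                regions = data.frame(id = integer(0), area = integer(0),
                                     x_min = integer(0), y_min = integer(0),
                                     x_max = integer(0), y_max = integer(0))))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(ids, n)
  ymin <- tapply(rows, ids, min) - 1L
  ymax <- tapply(rows, ids, max)
  xmin <- tapply(cols, ids, min) - 1L
  xmax <- tapply(cols, ids, max)
  ord <- order(ymin, xmin)
  remap <- integer(n); remap[ord] <- seq_len(n)
  lab[idx] <- remap[ids]
  list(labels = lab,
       regions = data.frame(id = seq_len(n), area = as.integer(area[ord]),
                            x_min = as.integer(xmin[ord]),
                            y_min = as.integer(ymin[ord]),
                            x_max = as.integer(xmax[ord]),
                            y_max = as.integer(ymax[ord])))
}

#' Automatic bounding-box labeling of chromosomes
#'
#' The automated labeling procedure for normal chromosomes: binarize the
#' image with [otsuThreshold()] (foreground = the darker side, matching
#' Giemsa-stained chromatin), extract connected components, drop specks
#' smaller than `minArea` pixels, and return the tight bounding box of each
#' remaining region labeled `classId`. Touching chromosomes merge into a
#' single box — an accepted limitation of threshold-based labeling.
#'
#' @param image numeric gray-level matrix.
#' @param minArea minimum component area in pixels (default 20).
#' @param classId class assigned to every box (default 0, normal).
#' @param connectivity 4 or 8 (default 8).
#' @param invert take the brighter side as foreground.
#' @return box data.frame (see [emptyBoxes()]).
#' @export
autoLabel <- function(image, minArea = 20L, classId = 0L,
                      connectivity = 8L, invert = FALSE) {
  thr <- otsuThreshold(image)
  fg <- if (invert) image > thr else image <= thr
  cc <- connectedComponents(fg, connectivity)
  keep <- cc$regions[cc$regions$area >= minArea, , drop = FALSE]
  if (!nrow(keep)) return(emptyBoxes())
  data.frame(x_min = keep$x_min, y_min = keep$y_min,
             x_max = keep$x_max, y_max = keep$y_max,
             class_id = as.integer(rep(classId, nrow(keep))))
}

#' Label every image in a directory
#'
#' Applies [autoLabel()] to each PNG under `imagesDir` and writes a YOLO
#' label file per image into `outDir`.
#'
#' @param imagesDir directory of PNG images.
#' @param outDir output label directory (created if missing).
#' @param ... passed to [autoLabel()].
#' @return invisibly, a data.frame of per-image box counts.
#' @export
labelDirectory <- function(imagesDir, outDir, ...) {
  files <- sort(list.files(imagesDir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG images in ", imagesDir, call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- integer(length(files))
  for (i in seq_along(files)) {
    img <- readGrayPNG(files[i])
    boxes <- autoLabel(img, ...)
    counts[i] <- nrow(boxes)
    writeLabels(boxes, c(ncol(img), nrow(img)),
                file.path(outDir, sub("\\.png$", ".txt", basename(files[i]))))
  }
  invisible(data.frame(image = basename(files), boxes = counts))
}
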