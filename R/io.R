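## Format boundary: YOLO txt labels, 8-bit grayscale PNG images, YAML
## manifests. Internally boxes are 0-based half-open pixel corners; the
## normalized center-size convention exists only in the label files.

#' Read and write YOLO-format label files
#'
#' A YOLO label file holds one line per box: `class cx cy w h`, where the
#' center and size are normalized to \[0, 1\] by the image size. These
#' functions convert losslessly (to the stated 6-decimal precision) between
#' that convention and the package's 0-based half-open pixel corners.
#'
#' @param path label file path.
#' @param imageSize image size in pixels: a single number for square
#'   images or `c(width, height)`.
#' @return `readLabels()` returns a box data.frame (see [emptyBoxes()]);
#'   `writeLabels()` returns the path invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLabels(data.frame(x_min = 0, y_min = 0, x_max = 320, y_max = 320,
#'                        class_id = 0L), 640, f)
#' readLabels(f, 640)
#' @export
readLabels <- function(path, imageSize) {
  w <- imageSize[1]; h <- if (length(imageSize) > 1) imageSize[2] else imageSize[1]
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(emptyBoxes())
  parsed <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 5 || anyNA(vals))
      stop(sprintf("%s: malformed label line %d: '%s'", path, i, lines[i]),
           call. = FALSE)
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
      stop(sprintf("%s: line %d: normalized coordinate outside [0, 1]",
                   path, i), call. = FALSE)
    vals
  })
  m <- do.call(rbind, parsed)
  data.frame(x_min = (m[, 2] - m[, 4] / 2) * w,
             y_min = (m[, 3] - m[, 5] / 2) * h,
             x_max = (m[, 2] + m[, 4] / 2) * w,
             y_max = (m[, 3] + m[, 5] / 2) * h,
             class_id = as.integer(m[, 1]))
}

#' @rdname readLabels
#' @param boxes box data.frame to write.
#' @export
writeLabels <- function(boxes, imageSize, path) {
  validateBoxes(boxes, rep(imageSize[1], 2)[1:2], "boxes")
  w <- imageSize[1]; h <- if (length(imageSize) > 1) imageSize[2] else imageSize[1]
  lines <- character(nrow(boxes))
  if (nrow(boxes)) {
    cx <- (boxes$x_min + boxes$x_max) / 2 / w
    cy <- (boxes$y_min + boxes$y_max) / 2 / h
    bw <- (boxes$x_max - boxes$x_min) / w
    bh <- (boxes$y_max - boxes$y_min) / h
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, cx, cy, bw, bh)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write 8-bit grayscale PNG images
#'
#' The package represents images as numeric matrices of gray levels in
#' \[0, 255\], rows = y, columns = x. PNGs are written as 8-bit grayscale;
#' gray levels are rounded to integers on write.
#'
#' @param image numeric matrix in \[0, 255\].
#' @param path PNG file path.
#' @return `readGrayPNG()` the image matrix; `writeGrayPNG()` the path,
#'   invisibly.
#' @export
writeGrayPNG <- function(image, path) {
  png::writePNG(round(pmin(pmax(image, 0), 255)) / 255, path)
  invisible(path)
}

#' @rdname writeGrayPNG
#' @export
readGrayPNG <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 255
}

#' Resize an image together with its boxes
#'
#' Anisotropic bilinear resize to a square target (the network input
#' convention); boxes are scaled by the same per-axis factors. Boxes whose
#' width or height falls below one pixel after scaling are dropped with a
#' warning.
#'
#' @param image numeric gray-level matrix.
#' @param boxes box data.frame in the source pixel frame (may be empty).
#' @param target target side length in pixels (default 640).
#' @return list with `image` (target x target matrix), `boxes` (scaled) and
#'   `scale` (`c(sx, sy)`).
#' @export
resizeWithBoxes <- function(image, boxes = emptyBoxes(), target = 640) {
  stopifnot(length(image) > 0)
  h <- nrow(image); w <- ncol(image)
  out <- EBImage::resize(EBImage::Image(t(image) / 255), w = target,
                         h = target)
  resized <- t(EBImage::imageData(out)) * 255
  resized <- pmin(pmax(resized, 0), 255)
  sx <- target / w; sy <- target / h
  if (nrow(boxes)) {
    scaled <- boxes
    scaled$x_min <- boxes$x_min * sx; scaled$x_max <- boxes$x_max * sx
    scaled$y_min <- boxes$y_min * sy; scaled$y_max <- boxes$y_max * sy
    tiny <- (scaled$x_max - scaled$x_min < 1) |
      (scaled$y_max - scaled$y_min < 1)
    if (any(tiny)) {
      warning(sum(tiny), " box(es) collapsed below 1 px after resize; dropped")
      scaled <- scaled[!tiny, , drop = FALSE]
    }
    boxes <- scaled
  }
  list(image = resized, boxes = boxes, scale = c(sx, sy))
}

#' Read a YOLO-layout dataset directory
#'
#' Expects `images/*.png` with matching `labels/<stem>.txt` files (a
#' missing label file means an image without annotated boxes).
#'
#' @param dir dataset directory.
#' @return list with `stems`, `images` (list of matrices) and `boxes`
#'   (list of box tables).
#' @export
readDataset <- function(dir) {
  files <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no PNG images under ", dir, call. = FALSE)
  stems <- sub("\\.png$", "", basename(files))
  images <- lapply(files, readGrayPNG)
  boxes <- lapply(seq_along(files), function(i) {
    lp <- file.path(dir, "labels", paste0(stems[i], ".txt"))
    if (file.exists(lp))
      readLabels(lp, c(ncol(images[[i]]), nrow(images[[i]])))
    else emptyBoxes()
  })
  list(stems = stems, images = images, boxes = boxes)
}

#' Read a grayscale image (PNG or TIFF)
#'
#' Dispatches on the file extension; multi-channel images are reduced to
#' their first channel. Returns the package's gray-level matrix
#' convention (values in 0-255).
#'
#' @param path image path (`.png`, `.tif` or `.tiff`).
#' @return numeric matrix of gray levels.
#' @export
readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(readGrayPNG(path))
  if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    return(a * 255)
  }
  stop("unsupported image format: .", ext, call. = FALSE)
}

#' Export labels as COCO-style JSON
#'
#' Writes a minimal COCO object-detection annotation file (`images`,
#' `annotations` with `[x, y, width, height]` boxes, `categories` for the
#' normal/dicentric classes) for interoperability with external tooling.
#'
#' @param boxes list of box data.frames, one per image.
#' @param imageSizes integer vector/list of square image sizes, or an
#'   n x 2 matrix of (width, height).
#' @param stems character vector of image file stems.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeCocoJson <- function(boxes, imageSizes, stems, path) {
  stopifnot(length(boxes) == length(stems))
  sz <- if (is.matrix(imageSizes)) imageSizes else
    cbind(unlist(imageSizes), unlist(imageSizes))
  if (nrow(sz) == 1L) sz <- sz[rep(1L, length(boxes)), , drop = FALSE]
  images <- lapply(seq_along(boxes), function(i)
    list(id = i, file_name = paste0(stems[i], ".png"),
         width = sz[i, 1], height = sz[i, 2]))
  anns <- list(); aid <- 0L
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    for (k in seq_len(nrow(b))) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = i, category_id = b$class_id[k] + 1L,
        bbox = c(b$x_min[k], b$y_min[k],
                 b$x_max[k] - b$x_min[k], b$y_max[k] - b$y_min[k]),
        area = (b$x_max[k] - b$x_min[k]) * (b$y_max[k] - b$y_min[k]),
        iscrowd = 0L)
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = anns,
         categories = list(list(id = 1L, name = "normal_chromosome"),
                           list(id = 2L, name = "dicentric_chromosome"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
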