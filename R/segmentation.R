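#' Segment tissue-slice outlines from a mosaic image
#'
#' Extracts one closed contour per tissue slice from a low-magnification
#' mosaic. Foreground is found by automatic global thresholding (inter-class
#' variance criterion) with polarity auto-detection (slices may be darker or
#' brighter than the background; the minority intensity class is taken as
#' foreground). Objects are cleaned by morphological closing and hole filling,
#' labelled, and traced at the 0.5 iso-level so the polygon area matches the
#' object's pixel count to well under 1%.
#'
#' @param img a [MosaicImage-class].
#' @param minArea minimum object area in square micrometres (default 0.5 mm^2,
#'   the scale of organoid slices).
#' @param borderPolicy what to do with objects touching the image border:
#'   \code{"keep"}, \code{"drop"}, or \code{"flag"} (keep, mark
#'   \code{borderTouching}).
#' @param brushRadius structuring-element radius in pixels for the closing.
#' @return list of [SliceContour-class], ordered by decreasing area. An image
#'   with no foreground (e.g. uniform intensity) yields an empty list.
#' @export
segmentSlices <- function(img, minArea = 5e5,
                          borderPolicy = c("keep", "drop", "flag"),
                          brushRadius = 3L) {
  stopifnot(is(img, "MosaicImage"))
  borderPolicy <- match.arg(borderPolicy)
  if (minArea < 0) stop("minArea must be >= 0")
  x <- img@pixels
  if (diff(range(x)) == 0) return(list())

  th <- EBImage::otsu(x, range = range(x))
  fg <- x > th
  if (mean(fg) > 0.5) fg <- !fg  # slices occupy the minority of the mosaic

  brush <- EBImage::makeBrush(2L * as.integer(brushRadius) + 1L, shape = "disc")
  fg <- EBImage::closing(fg, brush)
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  nObj <- max(lab)
  if (nObj == 0) return(list())

  contours <- list()
  for (i in seq_len(nObj)) {
    mask <- lab == i
    npx <- sum(mask)
    areaUm2 <- npx * img@pixelSize^2
    if (areaUm2 < minArea) next
    touches <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
               any(mask[, 1]) || any(mask[, ncol(mask)])
    if (touches && borderPolicy == "drop") next
    poly <- .traceMask(mask)
    if (is.null(poly) || nrow(poly) < 8L) next
    ctr <- polygonCentroid(poly)
    contours[[length(contours) + 1L]] <- new("SliceContour",
      sliceId = "", source = .sourceOf(img@modality), polygon = poly,
      pixelSize = img@pixelSize,
      area = abs(polygonArea(poly)) * img@pixelSize^2,
      centroid = ctr, descriptor = shapeDescriptor(poly),
      borderTouching = touches && borderPolicy == "flag")
  }
  ord <- order(vapply(contours, sliceArea, numeric(1)), decreasing = TRUE)
  contours <- contours[ord]
  for (k in seq_along(contours))
    contours[[k]]@sliceId <- sprintf("%s_slice_%02d", img@frameId, k)
  contours
}

.sourceOf <- function(modality)
  if (modality == "live-brightfield") "live" else "fixed"

## Subpixel boundary of a binary mask: 0.5 iso-contour. Matrix rows index y,
## columns x; contourLines treats the first coordinate as its "x", so the
## traced (row, col) pairs are swapped into (x, y) pixel coordinates.
## Returns the longest ring, vertices canonicalized to positive signed area.
.traceMask <- function(mask) {
  z <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  best <- cl[[which.max(vapply(cl, function(s) length(s$x), numeric(1)))]]
  poly <- cbind(x = best$y, y = best$x)
  # drop duplicated closing vertex if present
  n <- nrow(poly)
  if (n > 1 && all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  if (polygonArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}
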