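#' Estimate the live-to-fixed similarity transform for a matched slice pair
#'
#' Coarse initialization (centroid alignment plus principal-axis angle, with
#' the 180-degree ambiguity and both chirality hypotheses enumerated) followed
#' by iterative-closest-point (ICP) refinement on arc-length-resampled contour
#' vertices. Scale is nominally fixed by pixel-size calibration; a bounded
#' residual scale absorbs calibration error. The chirality hypothesis with the
#' lower final residual wins.
#'
#' @param liveContour,fixedContour a matched pair of [SliceContour-class].
#' @param mirroredHint optional logical; restricts the chirality hypotheses
#'   (as produced by [pairingCost()]). \code{NA} tries both.
#' @param scaleBounds allowed scale window (after pixel-size normalization).
#' @param nResample contour vertices used for ICP.
#' @param maxIter iteration cap; non-convergence raises an error of class
#'   \code{bRGmapConvergenceError} carrying the best transform so far.
#' @param tol convergence threshold on the residual change (pixels).
#' @return a [Transform2D-class] with \code{residualRMS} filled in.
#' @export
estimateTransform <- function(liveContour, fixedContour, mirroredHint = NA,
                              scaleBounds = c(0.95, 1.05), nResample = 256L,
                              maxIter = 100L, tol = 1e-4) {
  stopifnot(is(liveContour, "SliceContour"), is(fixedContour, "SliceContour"))
  src <- resamplePolygon(liveContour@polygon, nResample)
  dst <- resamplePolygon(fixedContour@polygon, nResample)
  nCoarse <- min(64L, nResample)
  srcC <- resamplePolygon(liveContour@polygon, nCoarse)
  dstC <- resamplePolygon(fixedContour@polygon, nCoarse)
  hyps <- if (is.na(mirroredHint)) c(FALSE, TRUE) else as.logical(mirroredHint)

  s0 <- sqrt(fixedContour@area / liveContour@area) *
        liveContour@pixelSize / fixedContour@pixelSize
  s0 <- min(max(s0, scaleBounds[1]), scaleBounds[2])

  # coarse search: low-resolution ICP from a ring of start angles around the
  # principal-axis estimate (which is ambiguous for near-symmetric slices),
  # then full-resolution refinement of the best start per hypothesis.
  best <- NULL
  angDst <- .principalAngle(dst)
  for (mir in hyps) {
    srcM <- src
    srcMC <- srcC
    if (mir) { srcM[, 1] <- -srcM[, 1]; srcMC[, 1] <- -srcMC[, 1] }
    dAng0 <- angDst - .principalAngle(srcMC)
    coarseBest <- NULL
    for (dAng in dAng0 + seq(0, 330, by = 30)) {
      t0 <- .initTransform(srcMC, dstC, dAng, s0)
      fit <- .icp(srcMC, dstC, t0, scaleBounds, maxIter = 10L, tol = 1e-3)
      if (is.null(coarseBest) || fit$rms < coarseBest$rms) coarseBest <- fit
    }
    t0 <- list(rotation = coarseBest$rotation, scale = coarseBest$scale,
               tx = coarseBest$tx, ty = coarseBest$ty)
    fit <- .icp(srcM, dst, t0, scaleBounds, maxIter, tol)
    if (is.null(best) || fit$rms < best$rms) best <- c(fit, mirror = mir)
  }
  res <- transform2D(rotation = .wrapAngle(best$rotation), scale = best$scale,
                     tx = best$tx, ty = best$ty, mirror = best$mirror,
                     residualRMS = best$rms)
  if (!best$converged) {
    cond <- structure(
      class = c("bRGmapConvergenceError", "error", "condition"),
      list(message = sprintf(
             "ICP did not converge within %d iterations (best residual %.4g px)",
             maxIter, best$rms),
           call = sys.call(-1), transform = res))
    stop(cond)
  }
  res
}

## rotation/scale given; translation aligns the centroids.
.initTransform <- function(srcM, dst, rotation, scale) {
  A <- scale * .rotMat(rotation)
  t <- colMeans(dst) - drop(A %*% colMeans(srcM))
  list(rotation = rotation, scale = scale, tx = t[1], ty = t[2])
}

## ICP on pre-mirrored source points: nearest-vertex correspondence, then a
## least-squares similarity fit (Umeyama) with the scale clamped to bounds.
.icp <- function(srcM, dst, t0, scaleBounds, maxIter, tol) {
  cur <- t0
  lastRms <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    A <- cur$scale * .rotMat(cur$rotation)
    mapped <- srcM %*% t(A)
    mapped[, 1] <- mapped[, 1] + cur$tx
    mapped[, 2] <- mapped[, 2] + cur$ty
    d2 <- outer(mapped[, 1], dst[, 1], "-")^2 +
          outer(mapped[, 2], dst[, 2], "-")^2
    nn <- max.col(-d2, ties.method = "first")
    rms <- sqrt(mean(d2[cbind(seq_len(nrow(d2)), nn)]))
    if (abs(lastRms - rms) < tol) { converged <- TRUE; lastRms <- rms; break }
    lastRms <- rms
    cur <- .fitSimilarity(srcM, dst[nn, , drop = FALSE], scaleBounds)
  }
  c(cur, rms = lastRms, converged = converged)
}

## Least-squares similarity (no reflection) between matched point sets.
.fitSimilarity <- function(X, Y, scaleBounds) {
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varX <- mean(rowSums(Xc^2))
  scale <- sum(sv$d * c(1, d)) / varX
  scale <- min(max(scale, scaleBounds[1]), scaleBounds[2])
  rot <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  t <- my - scale * drop(R %*% mx)
  list(rotation = rot, scale = scale, tx = t[1], ty = t[2])
}

#' Map live-imaging fields of view onto fixed-image coordinates
#'
#' Each field of view (FOV) is a rectangle in live-mosaic coordinates,
#' attached to a slice. Its four corners and its center are mapped through the
#' alignment transform of that slice, yielding a quadrilateral region of
#' interest on the immunostained image. FOVs whose slice is unmatched are
#' reported separately.
#'
#' @param pairing a [SlicePairing-class].
#' @param transforms named list of [Transform2D-class], one per paired live
#'   slice id.
#' @param fovs data.frame with columns \code{video_id}, \code{slice_id},
#'   \code{center_x}, \code{center_y}, \code{width}, \code{height} (pixels,
#'   live frame) and optionally \code{magnification_tag}.
#' @return list with \code{roi}: data.frame of mapped quadrilaterals
#'   (corner coordinates \code{x1..y4}, mapped center, slice residual) and
#'   \code{unmapped}: FOVs on unmatched slices.
#' @export
annotateFovs <- function(pairing, transforms, fovs) {
  stopifnot(is(pairing, "SlicePairing"), is.data.frame(fovs))
  need <- c("video_id", "slice_id", "center_x", "center_y", "width", "height")
  if (!all(need %in% names(fovs)))
    stop("fovs must have columns ", paste(need, collapse = ", "))
  pairedIds <- pairing@pairs$live_id
  rows <- list(); unmapped <- list()
  for (k in seq_len(nrow(fovs))) {
    f <- fovs[k, ]
    if (!f$slice_id %in% pairedIds) { unmapped[[length(unmapped) + 1L]] <- f; next }
    tr <- transforms[[f$slice_id]]
    if (is.null(tr))
      stop("no transform supplied for paired slice '", f$slice_id, "'")
    hw <- f$width / 2; hh <- f$height / 2
    corners <- cbind(f$center_x + c(-hw, hw, hw, -hw),
                     f$center_y + c(-hh, -hh, hh, hh))
    mc <- mapPoints(tr, corners)
    ct <- mapPoints(tr, c(f$center_x, f$center_y))
    rows[[length(rows) + 1L]] <- data.frame(
      video_id = f$video_id, slice_id = f$slice_id,
      fixed_id = pairing@pairs$fixed_id[match(f$slice_id, pairedIds)],
      x1 = mc[1, 1], y1 = mc[1, 2], x2 = mc[2, 1], y2 = mc[2, 2],
      x3 = mc[3, 1], y3 = mc[3, 2], x4 = mc[4, 1], y4 = mc[4, 2],
      center_x = ct[1], center_y = ct[2],
      residual_rms = tr@residualRMS, stringsAsFactors = FALSE)
  }
  list(roi = if (length(rows)) do.call(rbind, rows) else
         data.frame(video_id = character()),
       unmapped = if (length(unmapped)) do.call(rbind, unmapped) else
         fovs[0, , drop = FALSE])
}

#' Attach field-of-view records to segmented live slices
#'
#' Assigns each FOV (recorded in live-mosaic coordinates) the id of the
#' nearest segmented live slice contour (by centroid distance).
#'
#' @param fovs data.frame with \code{center_x}, \code{center_y}.
#' @param liveContours list of live [SliceContour-class].
#' @return the FOV table with \code{slice_id} filled in.
#' @export
assignFovSlices <- function(fovs, liveContours) {
  stopifnot(length(liveContours) > 0)
  ctrs <- t(vapply(liveContours, function(ct) ct@centroid, numeric(2)))
  ids <- vapply(liveContours, sliceId, character(1))
  nearest <- vapply(seq_len(nrow(fovs)), function(k) {
    d2 <- (ctrs[, 1] - fovs$center_x[k])^2 + (ctrs[, 2] - fovs$center_y[k])^2
    which.min(d2)
  }, integer(1))
  fovs$slice_id <- ids[nearest]
  fovs
}
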