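## Synthetic live/fixed slice-set generator. Slices are random smooth
## star-convex blobs (low-order harmonic radius perturbation) placed on
## disjoint grid cells; every fixed slice is its live counterpart under a
## known similarity transform (random rotation, translation, horizontal flip
## with the configured probability), plus area jitter and boundary
## deformation noise. All randomness is seeded once per call and the global
## RNG state is restored afterwards.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.LIVE_BG <- 204 / 255; .LIVE_FG <- 51 / 255   # brightfield: dark slices
.FIXED_BG <- 51 / 255; .FIXED_FG <- 204 / 255 # fluorescence: bright slices

## Star-convex radius function r(theta) = R (1 + sum a_k cos(k theta + phi_k)).
.starRadius <- function(theta, R, amps, phases, ks) {
  r <- rep(1, length(theta))
  for (h in seq_along(ks)) r <- r + amps[h] * cos(ks[h] * theta + phases[h])
  R * r
}

.rasterizeStar <- function(size, center, R, amps, phases, ks,
                           extraAmp = numeric(0), extraPhase = numeric(0),
                           extraKs = integer(0), scaleR = 1) {
  mask <- matrix(0L, size, size)
  rmax <- R * scaleR * (1 + sum(abs(amps))) + sum(abs(extraAmp)) + 1
  xs <- max(1L, floor(center[1] - rmax)):min(size, ceiling(center[1] + rmax))
  ys <- max(1L, floor(center[2] - rmax)):min(size, ceiling(center[2] + rmax))
  dx <- outer(rep(1, length(ys)), xs - center[1])
  dy <- outer(ys - center[2], rep(1, length(xs)))
  rad <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  rb <- .starRadius(th, R * scaleR, amps, phases, ks)
  if (length(extraAmp))
    for (h in seq_along(extraKs))
      rb <- rb + extraAmp[h] * cos(extraKs[h] * th + extraPhase[h])
  mask[ys, xs] <- as.integer(rad <= rb)
  mask
}

## Mirror-asymmetry of a star-convex radius function, in pixels: the minimum
## over candidate reflection axes of the RMS difference between the radius
## profile and its reflection. Shapes are rejection-sampled to keep this
## above a floor, so that the ground-truth flip of every generated slice is
## identifiable in principle (a near-achiral slice has no detectable flip).
.mirrorAsymmetry <- function(R, amps, phases, ks) {
  th0 <- seq(0, pi, length.out = 91L)
  dl <- seq(0, pi, length.out = 61L)
  worst <- Inf
  for (t0 in th0) {
    d <- .starRadius(t0 + dl, R, amps, phases, ks) -
         .starRadius(t0 - dl, R, amps, phases, ks)
    worst <- min(worst, sqrt(mean(d^2)))
  }
  worst
}

## Nearest-neighbour inverse warp of a binary live-frame mask into the fixed
## frame under a recorded live-to-fixed transform.
.warpMask <- function(mask, tr, size) {
  out <- matrix(0L, size, size)
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0) return(out)
  corners <- cbind(range(idx[, 2]), range(idx[, 1]))  # (x, y)
  box <- mapPoints(tr, cbind(corners[c(1, 2, 2, 1), 1], corners[c(1, 1, 2, 2), 2]))
  xs <- max(1L, floor(min(box[, 1]) - 2)):min(size, ceiling(max(box[, 1]) + 2))
  ys <- max(1L, floor(min(box[, 2]) - 2)):min(size, ceiling(max(box[, 2]) + 2))
  inv <- invertTransform(tr)
  A <- .linearPart(inv)
  px <- outer(rep(1, length(ys)), xs)
  py <- outer(ys, rep(1, length(xs)))
  qx <- A[1, 1] * px + A[1, 2] * py + inv@tx
  qy <- A[2, 1] * px + A[2, 2] * py + inv@ty
  ix <- floor(qx + 0.5); iy <- floor(qy + 0.5)
  ok <- ix >= 1 & ix <= ncol(mask) & iy >= 1 & iy <= nrow(mask)
  val <- matrix(0L, length(ys), length(xs))
  val[ok] <- mask[cbind(iy[ok], ix[ok])]
  out[ys, xs] <- val
  out
}

#' Generate a synthetic live/fixed slice-image pair with known ground truth
#'
#' Emulates the inputs of the correlative pipeline: a live brightfield mosaic
#' (dark slices on bright background) and a fixed tile-scan mosaic (bright
#' slices on dark background) containing the same \code{nSlices} tissue
#' slices, each fixed slice being its live counterpart under a random
#' rotation, translation and (with probability \code{flipProb}) a horizontal
#' flip, with small area jitter and boundary deformation.
#'
#' @param nSlices number of slices (>= 0).
#' @param imageSize side length in pixels of both square mosaics.
#' @param noiseParams list with \code{areaJitter} (fractional area jitter) and
#'   \code{boundaryAmp} (boundary deformation amplitude, pixels).
#' @param flipProb probability a slice is mirrored during fixation.
#' @param pixelSize micrometres per pixel (both frames).
#' @param seed integer seed; identical calls reproduce identical output.
#' @param fovsPerSlice live-imaging fields of view recorded per slice.
#' @return list with \code{live} and \code{fixed} ([MosaicImage-class]) and
#'   \code{truth} ([SliceSetTruth-class]).
#' @export
generateSliceSet <- function(nSlices, imageSize = 512L,
                             noiseParams = list(areaJitter = 0.02,
                                                boundaryAmp = 1),
                             flipProb = 0.5, pixelSize = 10, seed = 1L,
                             fovsPerSlice = 1L) {
  stopifnot(nSlices >= 0)
  imageSize <- as.integer(imageSize)
  aj <- noiseParams$areaJitter %||% 0
  ba <- noiseParams$boundaryAmp %||% 0
  .withSeed(seed, {
    live <- matrix(.LIVE_BG, imageSize, imageSize)
    fixed <- matrix(.FIXED_BG, imageSize, imageSize)
    emptyFovs <- data.frame(video_id = character(), slice_index = integer(),
                            slice_id = character(), center_x = numeric(),
                            center_y = numeric(), width = numeric(),
                            height = numeric(), stringsAsFactors = FALSE)
    if (nSlices == 0) {
      truth <- new("SliceSetTruth", masksLive = list(), transforms = list(),
                   pairing = integer(), noiseParams = list(areaJitter = aj,
                   boundaryAmp = ba), seed = as.integer(seed),
                   imageSize = imageSize, fovs = emptyFovs)
      return(list(
        live = mosaicImage(live, pixelSize, "live-brightfield", "live"),
        fixed = mosaicImage(fixed, pixelSize, "fixed-fluorescence-tile-scan",
                            "fixed"),
        truth = truth))
    }
    k <- ceiling(sqrt(nSlices))
    cell <- imageSize / k
    if (cell / 2 - 4 < 10)
      stop("cannot place ", nSlices, " non-overlapping slices in a ",
           imageSize, "px image: grid cells too small")
    cellCenter <- function(slot) {
      r <- (slot - 1) %/% k; c <- (slot - 1) %% k
      c(c * cell + cell / 2, r * cell + cell / 2)
    }
    liveSlots <- sample(k * k)[seq_len(nSlices)]
    fixedSlots <- sample(k * k)[seq_len(nSlices)]
    perm <- sample(nSlices)

    masksLive <- vector("list", nSlices)
    transforms <- vector("list", nSlices)
    fovRows <- list()
    fixedSum <- matrix(0L, imageSize, imageSize)
    ks <- 2:5
    for (i in seq_len(nSlices)) {
      R <- cell / 2 * runif(1, 0.45, 0.6)
      for (try in seq_len(50L)) {
        amps <- runif(4, 0.03, 0.12)
        phases <- runif(4, 0, 2 * pi)
        if (.mirrorAsymmetry(R, amps, phases, ks) >= 3) break
      }
      cL <- cellCenter(liveSlots[i]) + runif(2, -0.03, 0.03) * cell
      masksLive[[i]] <- .rasterizeStar(imageSize, cL, R, amps, phases, ks)

      rot <- runif(1, 0, 360)
      mir <- runif(1) < flipProb
      cF <- cellCenter(fixedSlots[perm[i]]) + runif(2, -0.03, 0.03) * cell
      tr <- transform2D(rotation = .wrapAngle(rot), scale = 1, mirror = mir)
      tt <- cF - mapPoints(tr, cL)
      tr@tx <- tt[1]; tr@ty <- tt[2]
      transforms[[i]] <- tr

      if (aj > 0 || ba > 0) {
        scaleR <- sqrt(1 + runif(1, -aj, aj))
        nb <- 2L
        extraAmp <- runif(nb, 0, ba / 2)
        extraPhase <- runif(nb, 0, 2 * pi)
        extraKs <- 6:7
        noised <- .rasterizeStar(imageSize, cL, R, amps, phases, ks,
                                 extraAmp, extraPhase, extraKs, scaleR)
      } else noised <- masksLive[[i]]
      fixedSum <- fixedSum + .warpMask(noised, tr, imageSize)

      for (v in seq_len(fovsPerSlice)) {
        off <- runif(2, -0.2, 0.2) * R
        fovRows[[length(fovRows) + 1L]] <- data.frame(
          video_id = sprintf("video_%02d_%d", i, v), slice_index = i,
          slice_id = NA_character_,
          center_x = cL[1] + off[1], center_y = cL[2] + off[2],
          width = 40, height = 40, stringsAsFactors = FALSE)
      }
    }
    if (any(fixedSum > 1L))
      stop("slice placement produced overlapping fixed slices; ",
           "increase imageSize or reduce nSlices")
    liveMask <- Reduce(`+`, masksLive)
    live[liveMask == 1L] <- .LIVE_FG
    fixed[fixedSum == 1L] <- .FIXED_FG
    truth <- new("SliceSetTruth", masksLive = masksLive,
                 transforms = transforms, pairing = perm,
                 noiseParams = list(areaJitter = aj, boundaryAmp = ba),
                 seed = as.integer(seed), imageSize = imageSize,
                 fovs = if (length(fovRows)) do.call(rbind, fovRows) else emptyFovs)
    list(live = mosaicImage(live, pixelSize, "live-brightfield", "live"),
         fixed = mosaicImage(fixed, pixelSize, "fixed-fluorescence-tile-scan",
                             "fixed"),
         truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
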