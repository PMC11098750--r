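## Independent oracles and small builders shared across tests.

# Brute-force minimum-cost assignment by enumerating all permutations
# (independent of the package's Hungarian solver).
bruteForceAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; bestA <- NULL
  for (p in perms(seq_len(m))) {
    a <- p[seq_len(n)]
    tc <- sum(cost[cbind(seq_len(n), a)])
    if (tc < best) { best <- tc; bestA <- a }
  }
  list(cost = best, assignment = bestA)
}

# Hand-rolled affine application of a recorded transform (mirror about the
# vertical axis, then scale, rotation, translation) - independent of
# mapPoints().
applyRecordedTransform <- function(tr, pts) {
  pts <- if (is.null(dim(pts))) matrix(pts, 1, 2) else as.matrix(pts)
  x <- pts[, 1]; y <- pts[, 2]
  if (tr@mirror) x <- -x
  x <- x * tr@scale; y <- y * tr@scale
  th <- tr@rotation * pi / 180
  cbind(cos(th) * x - sin(th) * y + tr@tx,
        sin(th) * x + cos(th) * y + tr@ty)
}

# Hand-rolled nearest-neighbour warp of a binary mask under a recorded
# transform (inverse mapping by direct algebra, not invertTransform()).
nnWarpMask <- function(mask, tr, size) {
  out <- matrix(0L, size, size)
  th <- tr@rotation * pi / 180
  for (yy in seq_len(size)) {
    px <- seq_len(size); py <- yy
    # undo translation, rotation, scale, mirror in reverse order
    ux <- px - tr@tx; uy <- py - tr@ty
    rx <- cos(th) * ux + sin(th) * uy
    ry <- -sin(th) * ux + cos(th) * uy
    rx <- rx / tr@scale; ry <- ry / tr@scale
    if (tr@mirror) rx <- -rx
    ix <- floor(rx + 0.5); iy <- floor(ry + 0.5)
    ok <- ix >= 1 & ix <= size & iy >= 1 & iy <= size
    out[yy, ok] <- mask[cbind(iy[ok], ix[ok])]
  }
  out
}

# A clearly chiral star-shaped test polygon.
chiralPolygon <- function(cx = 100, cy = 120, R = 50, n = 240) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  r <- R * (1 + 0.15 * cos(2 * th + 0.7) + 0.08 * cos(3 * th + 1.9) +
              0.05 * cos(5 * th))
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# SliceContour from a polygon, computing derived slots.
makeContour <- function(poly, id = "c1", source = "live", pixelSize = 1) {
  new("SliceContour", sliceId = id, source = source, polygon = poly,
      pixelSize = pixelSize, area = abs(polygonArea(poly)) * pixelSize^2,
      centroid = polygonCentroid(poly), descriptor = shapeDescriptor(poly))
}

# Generation-index bookkeeping for a synthetic slice set: which generated
# slice each segmented contour corresponds to, via centroids.
genIndexMaps <- function(res, lv, fx) {
  n <- length(res$truth@masksLive)
  liveCtr <- t(vapply(res$truth@masksLive, function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]))
  }, numeric(2)))
  fixedCtr <- t(vapply(seq_len(n), function(i)
    mapPoints(res$truth@transforms[[i]], liveCtr[i, ]), numeric(2)))
  list(
    liveCtr = liveCtr,
    genOfLive = vapply(lv, function(ct)
      which.min(colSums((t(liveCtr) - ct@centroid)^2)), integer(1)),
    genOfFixed = vapply(fx, function(ct)
      which.min(colSums((t(fixedCtr) - ct@centroid)^2)), integer(1)))
}

# Random valid fate-probability vector (uniform on the simplex).
randomFateProbs <- function() {
  v <- -log(runif(5))
  v <- v / sum(v)
  fateProbabilities(v[1], v[2], v[3], v[4], v[5])
}

rotationError <- function(est, truth)
  abs(((est - truth + 180) %% 360) - 180)
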