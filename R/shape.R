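## Exact polygon geometry: signed area, centroid, raw/central moments by
## Green's theorem (triangulation against the origin), Hu moment invariants
## and the 7-component log-scaled shape descriptor.

#' Signed polygon area (shoelace), in squared vertex units
#'
#' @param poly numeric matrix (n x 2), closed implicitly (last edge joins the
#'   last vertex back to the first).
#' @return signed area; positive for counterclockwise order in the package's
#'   y-down pixel convention.
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname polygonArea
#' @export
polygonCentroid <- function(poly) {
  m <- polygonMoments(poly, 1L)
  unname(c(m["1,0"], m["0,1"]) / m["0,0"])
}

#' Exact geometric moments of a polygon
#'
#' Computes raw moments \eqn{M_{pq} = \int x^p y^q \, dA} over the polygon
#' interior exactly (signed, triangulating every edge against the origin).
#'
#' @param poly numeric matrix (n x 2) of vertices.
#' @param maxOrder maximum total order p + q.
#' @return named numeric vector with names \code{"p,q"}.
#' @export
polygonMoments <- function(poly, maxOrder = 3L) {
  a <- poly
  b <- poly[c(seq_len(nrow(poly))[-1], 1L), , drop = FALSE]
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  out <- c()
  for (p in 0:maxOrder) for (q in 0:(maxOrder - p)) {
    s <- 0
    for (k in 0:p) for (l in 0:q) {
      coef <- choose(p, k) * choose(q, l) *
        factorial(k + l) * factorial(p + q - k - l) / factorial(p + q + 2)
      s <- s + coef * sum(cross *
        a[, 1]^k * b[, 1]^(p - k) * a[, 2]^l * b[, 2]^(q - l))
    }
    out[sprintf("%d,%d", p, q)] <- s
  }
  out
}

## Central moments mu_pq up to order 3, orientation-canonicalized
## (vertex order reversed if the signed area is negative, so mu00 > 0).
.centralMoments <- function(poly) {
  if (polygonArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  ctr <- polygonCentroid(poly)
  polygonMoments(sweep(poly, 2, ctr), 3L)
}

#' Hu moment invariants of a polygon
#'
#' The seven Hu invariants computed from exact (analytic) central polygon
#' moments, normalized for scale. Invariants 1-6 are unchanged under
#' translation, rotation and uniform scaling; the 7th changes sign under
#' mirror reflection.
#'
#' @param poly numeric matrix (n x 2) of vertices.
#' @return numeric length 7.
#' @export
huMoments <- function(poly) {
  mu <- .centralMoments(poly)
  m00 <- mu["0,0"]
  if (!is.finite(m00) || m00 <= 0)
    stop("degenerate polygon: zero or undefined area")
  eta <- function(p, q) mu[sprintf("%d,%d", p, q)] / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- numeric(7)
  h[1] <- n20 + n02
  h[2] <- (n20 - n02)^2 + 4 * n11^2
  h[3] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h[4] <- (n30 + n12)^2 + (n21 + n03)^2
  h[5] <- (n30 - 3 * n12) * (n30 + n12) *
            ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
          (3 * n21 - n03) * (n21 + n03) *
            (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h[6] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
          4 * n11 * (n30 + n12) * (n21 + n03)
  h[7] <- (3 * n21 - n03) * (n30 + n12) *
            ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
          (n30 - 3 * n12) * (n21 + n03) *
            (3 * (n30 + n12)^2 - (n21 + n03)^2)
  unname(h)
}

## Signed log compression keeps invariants of very different magnitudes
## comparable while preserving the sign (and hence chirality of component 7).
## The 1e-6 scale acts as a noise floor: invariants below it - where boundary
## noise can flip the sign - are compressed towards zero instead of being
## amplified by the log.
.signedLog <- function(h) sign(h) * log10(1 + abs(h) / 1e-6)

#' Shape descriptor of a slice contour
#'
#' A fixed-length (7) descriptor: signed-log-scaled Hu moment invariants of
#' the contour polygon. Components 1-6 are invariant to translation, rotation
#' and uniform scaling; component 7 has equal magnitude and opposite sign for
#' mirror-image shapes.
#'
#' @param x a [SliceContour-class] or an n x 2 vertex matrix.
#' @return numeric length 7.
#' @export
shapeDescriptor <- function(x) {
  poly <- if (is(x, "SliceContour")) x@polygon else as.matrix(x)
  if (abs(polygonArea(poly)) <= .Machine$double.eps)
    stop("degenerate polygon: zero area")
  .signedLog(huMoments(poly))
}

#' Resample a closed polygon to equally spaced vertices
#'
#' Arc-length resampling used by the iterative-closest-point refinement.
#'
#' @param poly numeric matrix (n x 2).
#' @param n number of output vertices.
#' @return n x 2 matrix.
#' @export
resamplePolygon <- function(poly, n = 256L) {
  p <- rbind(poly, poly[1, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polygon: zero perimeter")
  at <- seq(0, total, length.out = n + 1L)[seq_len(n)]
  cbind(approx(s, p[, 1], xout = at)$y, approx(s, p[, 2], xout = at)$y)
}

## Orientation of the principal axis (degrees) from central second moments.
.principalAngle <- function(poly) {
  mu <- .centralMoments(poly)
  0.5 * atan2(2 * mu[["1,1"]], mu[["2,0"]] - mu[["0,2"]]) * 180 / pi
}
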