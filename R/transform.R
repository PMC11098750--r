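## Similarity transforms with optional horizontal mirror.
## Composition order is fixed package-wide: mirror -> scale -> rotate -> translate,
##   p' = s * R(theta) * M * p + t,   M = diag(-1, 1) when mirror is TRUE.

.rotMat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

.linearPart <- function(t) {
  A <- t@scale * .rotMat(t@rotation)
  if (t@mirror) A[, 1] <- -A[, 1]
  A
}

#' Apply a transform to points
#'
#' Applies, in order, mirror (reflection of x about the vertical axis), scale,
#' rotation and translation.
#'
#' @param t a [Transform2D-class].
#' @param points numeric matrix (n x 2) or length-2 vector, columns x and y.
#' @return transformed points, same shape as input.
#' @examples
#' mapPoints(transform2D(tx = 10, ty = 5), c(0, 0))
#' @export
mapPoints <- function(t, points) {
  stopifnot(is(t, "Transform2D"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(points, 1, 2) else as.matrix(points)
  stopifnot(ncol(pts) == 2L)
  out <- pts %*% t(.linearPart(t))
  out[, 1] <- out[, 1] + t@tx
  out[, 2] <- out[, 2] + t@ty
  if (vec) drop(out) else out
}

#' Invert a transform
#'
#' @param t a [Transform2D-class].
#' @return the inverse [Transform2D-class]; mapping then inverse-mapping
#'   returns the input within numerical precision.
#' @export
invertTransform <- function(t) {
  stopifnot(is(t, "Transform2D"))
  # p = (1/s) M R(-theta) (p' - t); M R(-a) = R(a) M, so the inverse keeps
  # the mirror flag and has rotation +theta (mirrored) or -theta (plain).
  rot <- if (t@mirror) t@rotation else -t@rotation
  inv <- transform2D(rotation = rot, scale = 1 / t@scale, mirror = t@mirror,
                     residualRMS = t@residualRMS)
  tt <- mapPoints(inv, c(t@tx, t@ty))
  inv@tx <- -tt[1]
  inv@ty <- -tt[2]
  inv
}

#' Compose two transforms
#'
#' @param t2,t1 [Transform2D-class] objects; the result applies \code{t1}
#'   first, then \code{t2}.
#' @return a single [Transform2D-class] equal to \code{t2 o t1}.
#' @export
composeTransforms <- function(t2, t1) {
  stopifnot(is(t1, "Transform2D"), is(t2, "Transform2D"))
  # M2 R(a) = R(-a) M2: pulling t1's rotation through t2's mirror negates it.
  rot1 <- if (t2@mirror) -t1@rotation else t1@rotation
  tt <- mapPoints(t2, c(t1@tx, t1@ty))
  transform2D(rotation = .wrapAngle(t2@rotation + rot1),
              scale = t1@scale * t2@scale,
              tx = tt[1], ty = tt[2],
              mirror = xor(t1@mirror, t2@mirror))
}

.wrapAngle <- function(deg) {
  a <- (deg + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}
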