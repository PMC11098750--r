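#' Pairing cost between a live and a fixed slice contour
#'
#' Slices are matched on area and shape:
#' \deqn{cost = w_{area} |\log(A_a/A_b)| + w_{shape} d(descr_a, descr_b)}
#' where \eqn{d} is the Euclidean distance between 7-component shape
#' descriptors. Because fixation can mirror a slice, the distance is evaluated
#' under both chirality hypotheses (sign of the 7th, chirality-carrying,
#' component flipped or not) and the lower one is kept.
#'
#' @param a,b [SliceContour-class] objects.
#' @param weights named numeric, \code{c(area = , shape = )}.
#' @return list with \code{cost} (non-negative) and \code{mirrored} (logical,
#'   which chirality hypothesis won; ties favour no mirror).
#' @export
pairingCost <- function(a, b, weights = c(area = 1, shape = 1)) {
  stopifnot(is(a, "SliceContour"), is(b, "SliceContour"))
  if (a@area <= 0 || b@area <= 0) stop("contour areas must be positive")
  da <- a@descriptor; db <- b@descriptor
  areaTerm <- weights[["area"]] * abs(log(a@area / b@area))
  shapeDist <- function(mirror) {
    db2 <- db
    if (mirror) db2[7] <- -db2[7]
    sqrt(sum((da - db2)^2))
  }
  cPlain <- areaTerm + weights[["shape"]] * shapeDist(FALSE)
  cMirr  <- areaTerm + weights[["shape"]] * shapeDist(TRUE)
  if (cPlain <= cMirr) list(cost = cPlain, mirrored = FALSE)
  else list(cost = cMirr, mirrored = TRUE)
}

#' Pair live and fixed slice contours by optimal assignment
#'
#' Builds the full live x fixed cost matrix with [pairingCost()] and solves
#' the one-to-one assignment minimizing total cost (Hungarian algorithm).
#' Lists may differ in length; surplus slices, and pairs whose cost exceeds
#' \code{maxCost}, end up in the unmatched lists.
#'
#' @param live,fixed lists of [SliceContour-class].
#' @param weights passed to [pairingCost()].
#' @param maxCost pairs costlier than this are dissolved. The default comes
#'   from the synthetic noise study: matched pairs cost well under 0.2 (their
#'   mean plus 3 sd is about 0.11) while mismatched pairs cost upwards of
#'   0.9, so 0.5 separates the two populations with margin on both sides.
#' @return a [SlicePairing-class].
#' @export
pairSlices <- function(live, fixed, weights = c(area = 1, shape = 1),
                       maxCost = 0.5) {
  nl <- length(live); nf <- length(fixed)
  liveIds <- vapply(live, sliceId, character(1))
  fixedIds <- vapply(fixed, sliceId, character(1))
  emptyPairs <- data.frame(live_id = character(), fixed_id = character(),
                           cost = numeric(), mirrored = logical(),
                           stringsAsFactors = FALSE)
  if (nl == 0 || nf == 0)
    return(new("SlicePairing", pairs = emptyPairs, unmatchedLive = liveIds,
               unmatchedFixed = fixedIds))

  cost <- matrix(0, nl, nf)
  mirr <- matrix(FALSE, nl, nf)
  for (i in seq_len(nl)) for (j in seq_len(nf)) {
    pc <- pairingCost(live[[i]], fixed[[j]], weights)
    cost[i, j] <- pc$cost
    mirr[i, j] <- pc$mirrored
  }
  asg <- .hungarian(cost)  # length nl; NA for unassigned rows

  keep <- which(!is.na(asg))
  keep <- keep[cost[cbind(keep, asg[keep])] <= maxCost]
  pairs <- data.frame(
    live_id = liveIds[keep], fixed_id = fixedIds[asg[keep]],
    cost = cost[cbind(keep, asg[keep])], mirrored = mirr[cbind(keep, asg[keep])],
    stringsAsFactors = FALSE)
  new("SlicePairing", pairs = pairs,
      unmatchedLive = setdiff(liveIds, pairs$live_id),
      unmatchedFixed = setdiff(fixedIds, pairs$fixed_id))
}

## Hungarian algorithm (shortest augmenting paths, O(n^2 m)), rectangular
## via virtual rows/columns. Returns, per row, the assigned column (NA when
## rows exceed columns and the row is left out). No installed package
## provides linear-sum assignment, hence the in-package solver; tests check
## it against brute-force enumeration for small n.
.hungarian <- function(cost) {
  n0 <- nrow(cost); m0 <- ncol(cost)
  transposed <- n0 > m0
  if (transposed) cost <- t(cost)
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j+1]: row assigned to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(Inf, m + 1); used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  asg <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) asg[p[j + 1L]] <- j
  if (!transposed) return(asg)
  out <- rep(NA_integer_, m)  # original rows
  for (i in seq_len(n)) if (!is.na(asg[i])) out[asg[i]] <- i
  out
}
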