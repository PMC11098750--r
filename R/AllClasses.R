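#' @import methods
NULL

## Canonical division-outcome codes for a bRG (type A) division:
## AA = two bRG daughters, AB = bRG + IP, AC = bRG + neuron,
## BB = two IPs, CC = two neurons. BC (IP + neuron) is never observed
## and is excluded from the default model.
.MODES <- c("AA", "AB", "AC", "BB", "CC")

.DIVISION_MODES <- c(
  "symmetric_proliferative",
  "asym_selfrenew_indirect",
  "asym_selfrenew_direct",
  "symmetric_selfconsuming_indirect",
  "symmetric_selfconsuming_direct",
  "mixed_IP_neuron",
  "unclassifiable"
)

.MODE_TO_DIVISION <- c(
  AA = "symmetric_proliferative",
  AB = "asym_selfrenew_indirect",
  AC = "asym_selfrenew_direct",
  BB = "symmetric_selfconsuming_indirect",
  CC = "symmetric_selfconsuming_direct"
)

.FATES <- c("bRG", "IP", "neuron", "unclassified")

#' Division-outcome probabilities of a bRG cell
#'
#' Probabilities of the five admissible division outcomes of a basal radial
#' glial (type A) cell: \code{pAA} (two bRG), \code{pAB} (bRG + intermediate
#' progenitor), \code{pAC} (bRG + neuron), \code{pBB} (two IPs) and
#' \code{pCC} (two neurons). The mixed IP + neuron outcome is never observed
#' and carries no probability. Probabilities must sum to one.
#'
#' @slot pAA,pAB,pAC,pBB,pCC numeric scalars in [0, 1] summing to 1.
#' @seealso [fateProbabilities()], [marginals()], [perturbFateProbabilities()]
#' @export
setClass("FateProbabilities",
  representation(pAA = "numeric", pAB = "numeric", pAC = "numeric",
                 pBB = "numeric", pCC = "numeric"),
  validity = function(object) {
    p <- c(object@pAA, object@pAB, object@pAC, object@pBB, object@pCC)
    if (length(p) != 5L || any(!is.finite(p)))
      return("all five probabilities must be finite scalars")
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
      return("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      return(sprintf("probabilities must sum to 1 (got %.12f)", sum(p)))
    TRUE
  }
)

#' Construct a FateProbabilities object
#'
#' @param pAA,pAB,pAC,pBB,pCC outcome probabilities (must sum to 1).
#' @return A validated [FateProbabilities-class] object.
#' @examples
#' fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
#' @export
fateProbabilities <- function(pAA, pAB = 0, pAC = 0, pBB = 0, pCC = 0) {
  if (length(pAA) == 5L && missing(pAB)) {
    v <- as.numeric(pAA)
    return(new("FateProbabilities", pAA = v[1], pAB = v[2], pAC = v[3],
               pBB = v[4], pCC = v[5]))
  }
  new("FateProbabilities", pAA = as.numeric(pAA), pAB = as.numeric(pAB),
      pAC = as.numeric(pAC), pBB = as.numeric(pBB), pCC = as.numeric(pCC))
}

#' @export
#' @describeIn fateProbabilities probabilities as a named numeric vector in
#'   canonical outcome order (AA, AB, AC, BB, CC).
probVector <- function(p) {
  stopifnot(is(p, "FateProbabilities"))
  c(AA = p@pAA, AB = p@pAB, AC = p@pAC, BB = p@pBB, CC = p@pCC)
}

setMethod("show", "FateProbabilities", function(object) {
  v <- probVector(object)
  cat("FateProbabilities (bRG division outcomes)\n")
  cat(sprintf("  p%s = %.4f\n", names(v), v), sep = "")
})

#' Expected per-division production rates
#'
#' Marginal production rates of each cell type per bRG division:
#' \code{pbarA = 2 pAA + pAB + pAC}, \code{pbarB = pAB + 2 pBB},
#' \code{pbarC = pAC + 2 pCC}. For a valid probability vector they sum to 2
#' (every division yields two daughters).
#'
#' @slot pbarA,pbarB,pbarC numeric scalars.
#' @export
setClass("Marginals",
  representation(pbarA = "numeric", pbarB = "numeric", pbarC = "numeric"),
  validity = function(object) {
    m <- c(object@pbarA, object@pbarB, object@pbarC)
    if (any(!is.finite(m))) return("marginals must be finite")
    if (object@pbarA < -1e-12 || object@pbarA > 2 + 1e-12)
      return("pbarA must lie in [0, 2]")
    TRUE
  }
)

#' @rdname Marginals-class
#' @param pbarA,pbarB,pbarC per-division production rates.
#' @export
newMarginals <- function(pbarA, pbarB, pbarC) {
  new("Marginals", pbarA = as.numeric(pbarA), pbarB = as.numeric(pbarB),
      pbarC = as.numeric(pbarC))
}

setMethod("show", "Marginals", function(object) {
  cat(sprintf("Marginals: pbarA = %.6g, pbarB = %.6g, pbarC = %.6g (sum %.6g)\n",
              object@pbarA, object@pbarB, object@pbarC,
              object@pbarA + object@pbarB + object@pbarC))
})

#' Similarity transform between live and fixed frames
#'
#' A 2-D similarity transform with optional horizontal mirror, mapping live
#' mosaic coordinates to fixed mosaic coordinates. Components are applied in
#' the fixed order mirror (reflection of x about the vertical axis), then
#' scale, rotation and translation:
#' \deqn{p' = s R(\theta) M p + t.}
#'
#' @slot rotation rotation angle in degrees.
#' @slot scale positive scale factor.
#' @slot tx,ty translation in pixels.
#' @slot mirror logical; horizontal flip before scale/rotation.
#' @slot residualRMS root-mean-square alignment residual in pixels (NA when
#'   the transform was not estimated from data).
#' @seealso [mapPoints()], [invertTransform()], [estimateTransform()]
#' @export
setClass("Transform2D",
  representation(rotation = "numeric", scale = "numeric", tx = "numeric",
                 ty = "numeric", mirror = "logical", residualRMS = "numeric"),
  prototype(rotation = 0, scale = 1, tx = 0, ty = 0, mirror = FALSE,
            residualRMS = NA_real_),
  validity = function(object) {
    if (!is.finite(object@scale) || object@scale <= 0)
      return("scale must be a positive finite number")
    if (!is.finite(object@rotation)) return("rotation must be finite")
    if (!is.finite(object@tx) || !is.finite(object@ty))
      return("translation must be finite")
    TRUE
  }
)

#' @rdname Transform2D-class
#' @param rotation,scale,tx,ty,mirror,residualRMS transform components.
#' @export
transform2D <- function(rotation = 0, scale = 1, tx = 0, ty = 0,
                        mirror = FALSE, residualRMS = NA_real_) {
  new("Transform2D", rotation = as.numeric(rotation), scale = as.numeric(scale),
      tx = as.numeric(tx), ty = as.numeric(ty), mirror = as.logical(mirror),
      residualRMS = as.numeric(residualRMS))
}

setMethod("show", "Transform2D", function(object) {
  cat(sprintf(
    "Transform2D: rotation %.3f deg, scale %.4f, translation (%.2f, %.2f), mirror %s",
    object@rotation, object@scale, object@tx, object@ty, object@mirror))
  if (is.finite(object@residualRMS))
    cat(sprintf(", residual RMS %.3f px", object@residualRMS))
  cat("\n")
})

#' A segmented tissue-slice outline
#'
#' Closed polygonal outline of one tissue slice in mosaic pixel coordinates
#' (origin top-left, x rightward, y downward; vertices canonicalized to
#' positive signed area in this convention), with physical area, centroid and
#' a 7-component moment-invariant shape descriptor. Components 1-6 of the
#' descriptor are invariant to translation, rotation and uniform scaling;
#' component 7 changes sign under mirror reflection (chirality).
#'
#' @slot sliceId character identifier.
#' @slot source \code{"live"} or \code{"fixed"}.
#' @slot polygon numeric matrix (n x 2) of vertices, columns x, y (pixels).
#' @slot pixelSize micrometres per pixel.
#' @slot area polygon area in square micrometres.
#' @slot centroid numeric length 2, pixel coordinates.
#' @slot descriptor numeric length 7 (see [shapeDescriptor()]).
#' @slot borderTouching logical; object touched the mosaic border.
#' @export
setClass("SliceContour",
  representation(sliceId = "character", source = "character",
                 polygon = "matrix", pixelSize = "numeric", area = "numeric",
                 centroid = "numeric", descriptor = "numeric",
                 borderTouching = "logical"),
  prototype(borderTouching = FALSE),
  validity = function(object) {
    if (!object@source %in% c("live", "fixed"))
      return("source must be 'live' or 'fixed'")
    poly <- object@polygon
    if (ncol(poly) != 2L || nrow(poly) < 8L)
      return("polygon must be an n x 2 matrix with >= 8 vertices")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    a <- abs(polygonArea(poly)) * object@pixelSize^2
    if (object@area <= 0) return("area must be positive")
    if (abs(object@area - a) / a > 0.01)
      return("area slot disagrees with polygon area by more than 1%")
    if (length(object@descriptor) != 7L)
      return("descriptor must have length 7")
    TRUE
  }
)

setMethod("show", "SliceContour", function(object) {
  cat(sprintf(
    "SliceContour '%s' (%s): %d vertices, area %.3g um^2, centroid (%.1f, %.1f)\n",
    object@sliceId, object@source, nrow(object@polygon), object@area,
    object@centroid[1], object@centroid[2]))
})

#' @rdname SliceContour-class
#' @param x a \code{SliceContour}.
#' @export
sliceArea <- function(x) x@area

#' @rdname SliceContour-class
#' @export
sliceId <- function(x) x@sliceId

#' @rdname SliceContour-class
#' @export
sliceDescriptor <- function(x) x@descriptor

#' @rdname SliceContour-class
#' @export
slicePolygon <- function(x) x@polygon

#' A single-plane grayscale mosaic image
#'
#' @slot pixels numeric matrix, rows indexing y (downward) and columns x;
#'   intensities in [0, 1].
#' @slot pixelSize micrometres per pixel (> 0).
#' @slot modality \code{"live-brightfield"} or \code{"fixed-fluorescence-tile-scan"}.
#' @slot frameId character identifier.
#' @export
setClass("MosaicImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 modality = "character", frameId = "character"),
  validity = function(object) {
    if (length(dim(object@pixels)) != 2L)
      return("pixels must be a 2-D matrix")
    if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
      return("image must be non-empty")
    if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
      return("pixelSize must be positive")
    if (!object@modality %in% c("live-brightfield", "fixed-fluorescence-tile-scan"))
      return("unknown modality")
    TRUE
  }
)

#' @rdname MosaicImage-class
#' @param pixels,pixelSize,modality,frameId slots; see class description.
#' @export
mosaicImage <- function(pixels, pixelSize = 1,
                        modality = c("live-brightfield",
                                     "fixed-fluorescence-tile-scan"),
                        frameId = "mosaic") {
  modality <- match.arg(modality)
  new("MosaicImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      modality = modality, frameId = frameId)
}

setMethod("show", "MosaicImage", function(object) {
  cat(sprintf("MosaicImage '%s' (%s): %d x %d px, %.3g um/px\n",
              object@frameId, object@modality, ncol(object@pixels),
              nrow(object@pixels), object@pixelSize))
})

#' One-to-one pairing between live and fixed slice contours
#'
#' @slot pairs data.frame with columns \code{live_id}, \code{fixed_id},
#'   \code{cost}, \code{mirrored}.
#' @slot unmatchedLive,unmatchedFixed character vectors of ids left unpaired.
#' @export
setClass("SlicePairing",
  representation(pairs = "data.frame", unmatchedLive = "character",
                 unmatchedFixed = "character"),
  validity = function(object) {
    need <- c("live_id", "fixed_id", "cost", "mirrored")
    if (!all(need %in% names(object@pairs)))
      return("pairs must have columns live_id, fixed_id, cost, mirrored")
    if (anyDuplicated(object@pairs$live_id) ||
        anyDuplicated(object@pairs$fixed_id))
      return("pairing must be one-to-one")
    if (any(!is.finite(object@pairs$cost)) || any(object@pairs$cost < 0))
      return("costs must be finite and non-negative")
    if (any(object@pairs$live_id %in% object@unmatchedLive) ||
        any(object@pairs$fixed_id %in% object@unmatchedFixed))
      return("an id cannot be both paired and unmatched")
    TRUE
  }
)

setMethod("show", "SlicePairing", function(object) {
  cat(sprintf("SlicePairing: %d pairs (%d mirrored), %d unmatched live, %d unmatched fixed\n",
              nrow(object@pairs), sum(object@pairs$mirrored),
              length(object@unmatchedLive), length(object@unmatchedFixed)))
})

#' @rdname SlicePairing-class
#' @param x a \code{SlicePairing}.
#' @export
pairingTable <- function(x) x@pairs

#' Ground truth for a generated live/fixed slice set
#'
#' @slot masksLive list of binary (0/1) matrices, one live slice each.
#' @slot transforms list of [Transform2D-class], live-to-fixed, per slice.
#' @slot pairing integer permutation: live slice i is fixed slice
#'   \code{pairing[i]} (by descending-area rank in each frame, NA if absent
#'   from the fixed frame).
#' @slot noiseParams list with \code{areaJitter} (fraction) and
#'   \code{boundaryAmp} (pixels).
#' @slot seed integer seed used.
#' @slot imageSize image side length in pixels.
#' @slot fovs data.frame of ground-truth fields of view in live coordinates.
#' @export
setClass("SliceSetTruth",
  representation(masksLive = "list", transforms = "list", pairing = "integer",
                 noiseParams = "list", seed = "integer", imageSize = "integer",
                 fovs = "data.frame"),
  validity = function(object) {
    n <- length(object@masksLive)
    if (length(object@transforms) != n || length(object@pairing) != n)
      return("masksLive, transforms and pairing must have equal length")
    pp <- object@pairing[!is.na(object@pairing)]
    if (anyDuplicated(pp)) return("pairing must be a bijection over matched indices")
    TRUE
  }
)

setMethod("show", "SliceSetTruth", function(object) {
  cat(sprintf("SliceSetTruth: %d slices, %d x %d px, seed %d, %d mirrored\n",
              length(object@masksLive), object@imageSize, object@imageSize,
              object@seed,
              sum(vapply(object@transforms, function(t) t@mirror, logical(1)))))
})

#' Statistical profile of a synthetic division cohort
#'
#' Parameterizes [generateDivisionDataset()]: division-outcome probabilities,
#' per-outcome mean depth from the apical surface, depth spread, the
#' probability that a differentiating daughter retains the mother marker
#' (SOX2), the probability that the process-inheriting daughter is the
#' self-renewing one, and the probability that HES1 is detectable in a
#' self-renewing daughter.
#'
#' @slot stageLabel character, e.g. \code{"week8"} or \code{"GW17"}.
#' @slot modeProbs a [FateProbabilities-class].
#' @slot depthMeans named numeric (AA, AB, AC, BB, CC), micrometres.
#' @slot depthSd positive numeric, micrometres.
#' @slot markerRetentionProb,inheritanceSelfrenewalProb,hes1DetectionProb
#'   probabilities in [0, 1].
#' @export
setClass("CohortProfile",
  representation(stageLabel = "character", modeProbs = "FateProbabilities",
                 depthMeans = "numeric", depthSd = "numeric",
                 markerRetentionProb = "numeric",
                 inheritanceSelfrenewalProb = "numeric",
                 hes1DetectionProb = "numeric"),
  validity = function(object) {
    if (!all(.MODES %in% names(object@depthMeans)))
      return("depthMeans must be named with AA, AB, AC, BB, CC")
    if (!is.finite(object@depthSd) || object@depthSd <= 0)
      return("depthSd must be > 0")
    pr <- c(object@markerRetentionProb, object@inheritanceSelfrenewalProb,
            object@hes1DetectionProb)
    if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
      return("profile probabilities must lie in [0, 1]")
    TRUE
  }
)

#' @rdname CohortProfile-class
#' @param stageLabel,modeProbs,depthMeans,depthSd,markerRetentionProb,inheritanceSelfrenewalProb,hes1DetectionProb
#'   slots; see class description.
#' @export
cohortProfile <- function(stageLabel, modeProbs,
                          depthMeans = c(AA = 1000, AB = 800, AC = 1306,
                                         BB = 800, CC = 1306),
                          depthSd = 150, markerRetentionProb = 0.5,
                          inheritanceSelfrenewalProb = 0.5,
                          hes1DetectionProb = 0.3) {
  new("CohortProfile", stageLabel = stageLabel, modeProbs = modeProbs,
      depthMeans = depthMeans[.MODES], depthSd = as.numeric(depthSd),
      markerRetentionProb = as.numeric(markerRetentionProb),
      inheritanceSelfrenewalProb = as.numeric(inheritanceSelfrenewalProb),
      hes1DetectionProb = as.numeric(hes1DetectionProb))
}

setMethod("show", "CohortProfile", function(object) {
  cat(sprintf("CohortProfile '%s'\n", object@stageLabel))
  v <- probVector(object@modeProbs)
  cat(sprintf("  mode probs: %s\n",
              paste(sprintf("%s=%.3f", names(v), v), collapse = " ")))
  cat(sprintf("  depth means (um): %s; sd %.0f\n",
              paste(sprintf("%s=%.0f", names(object@depthMeans),
                            object@depthMeans), collapse = " "),
              object@depthSd))
})
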