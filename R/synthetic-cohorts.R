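## Synthetic division-record cohorts with known statistical structure.
## One row per division; daughter marker calls follow the fate -> marker map
## (bRG: SOX2+/EOMES-/NEUN-; IP: EOMES+; neuron: NEUN+), differentiating
## daughters retain the mother marker SOX2 with the profile's retention
## probability, depths are normal (per-outcome mean, common sd) truncated at
## zero, and inheritance / HES1 flags follow the profile probabilities.

.FATE_OF_MODE <- list(AA = c("bRG", "bRG"), AB = c("bRG", "IP"),
                      AC = c("bRG", "neuron"), BB = c("IP", "IP"),
                      CC = c("neuron", "neuron"))

## Marker calls for one daughter of a given fate.
.markersForFate <- function(fate, retainSox2) {
  switch(fate,
    bRG = c(sox2 = "pos", eomes = "neg", neun = "neg"),
    IP = c(sox2 = if (retainSox2) "pos" else "neg", eomes = "pos",
           neun = "neg"),
    neuron = c(sox2 = if (retainSox2) "pos" else "neg", eomes = "neg",
               neun = "pos"))
}

#' Generate a synthetic division-record cohort
#'
#' Draws \code{n} bRG division records from a [CohortProfile-class]. The
#' generating outcome of every record is stored in \code{true_mode} so
#' classification recovery can be tested. Mitotic somal translocation calls
#' are drawn as 25\% stationary with the remainder split evenly between
#' apical and basal.
#'
#' @param profile a [CohortProfile-class].
#' @param n number of divisions (>= 0); with \code{perMode = TRUE}, number of
#'   divisions per outcome (5 n rows total).
#' @param seed integer seed.
#' @param perMode generate a depth-stratified cohort with exactly \code{n}
#'   divisions of each of the five outcomes instead of sampling outcomes from
#'   the profile probabilities.
#' @return data.frame, one row per division: \code{division_id}, \code{stage},
#'   \code{depth_um}, daughter marker columns \code{d1_sox2} ...
#'   \code{d2_neun} (values \code{pos}/\code{neg}/\code{na}), per-daughter
#'   logical flags \code{d*_process_inherited}, \code{d*_hes1_detected},
#'   \code{mst} and \code{true_mode}.
#' @export
generateDivisionDataset <- function(profile, n, seed = 1L, perMode = FALSE) {
  stopifnot(is(profile, "CohortProfile"))
  validObject(profile)
  validObject(profile@modeProbs)
  stopifnot(n >= 0)
  cols <- c("division_id", "stage", "depth_um",
            "d1_sox2", "d1_eomes", "d1_neun", "d1_process_inherited",
            "d1_hes1_detected", "d2_sox2", "d2_eomes", "d2_neun",
            "d2_process_inherited", "d2_hes1_detected", "mst", "true_mode")
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$depth_um <- numeric(0)
    return(out)
  }
  .withSeed(seed, {
    modes <- if (perMode) rep(.MODES, each = n)
             else sample(.MODES, n, replace = TRUE,
                         prob = probVector(profile@modeProbs))
    N <- length(modes)
    # depth: truncated normal (redraw the sub-zero tail)
    depth <- rnorm(N, profile@depthMeans[modes], profile@depthSd)
    while (any(bad <- depth < 0))
      depth[bad] <- rnorm(sum(bad), profile@depthMeans[modes[bad]],
                          profile@depthSd)
    # daughter fates in random order
    fatePairs <- do.call(rbind, .FATE_OF_MODE)[modes, , drop = FALSE]
    swap <- runif(N) < 0.5
    f1 <- ifelse(swap, fatePairs[, 2], fatePairs[, 1])
    f2 <- ifelse(swap, fatePairs[, 1], fatePairs[, 2])
    markers <- function(f) {
      retain <- runif(N) < profile@markerRetentionProb
      list(sox2 = ifelse(f == "bRG", "pos",
                  ifelse(retain, "pos", "neg")),
           eomes = ifelse(f == "IP", "pos", "neg"),
           neun = ifelse(f == "neuron", "pos", "neg"))
    }
    m1 <- markers(f1); m2 <- markers(f2)
    # process inheritance: exactly one daughter inherits; in asymmetric
    # divisions it is the self-renewing daughter with the profile's
    # probability, otherwise a coin flip between the two daughters.
    isAsym <- modes %in% c("AB", "AC")
    inhSelf <- runif(N) < profile@inheritanceSelfrenewalProb
    coin <- runif(N) < 0.5
    inh1 <- ifelse(isAsym, (f1 == "bRG") == inhSelf, coin)
    # HES1 is only ever detectable in non-differentiating (bRG) daughters
    hes1_1 <- f1 == "bRG" & runif(N) < profile@hes1DetectionProb
    hes1_2 <- f2 == "bRG" & runif(N) < profile@hes1DetectionProb
    mst <- sample(c("stationary", "apical", "basal"), N, replace = TRUE,
                  prob = c(0.25, 0.375, 0.375))
    data.frame(
      division_id = sprintf("%s_div_%06d", profile@stageLabel, seq_len(N)),
      stage = profile@stageLabel, depth_um = depth,
      d1_sox2 = m1$sox2, d1_eomes = m1$eomes, d1_neun = m1$neun,
      d1_process_inherited = inh1, d1_hes1_detected = hes1_1,
      d2_sox2 = m2$sox2, d2_eomes = m2$eomes, d2_neun = m2$neun,
      d2_process_inherited = !inh1, d2_hes1_detected = hes1_2,
      mst = mst, true_mode = unname(.MODE_TO_DIVISION[modes]),
      stringsAsFactors = FALSE)
  })
}

#' Built-in cohort profiles
#'
#' \code{profileWeek8()} is an illustrative young-organoid profile using the
#' package's worked division-outcome vector (0.6, 0.2, 0.1, 0.05, 0.05).
#' \code{profileGW17()} encodes a gestational-week-17 fetal cohort: majority
#' proliferative divisions, about a third of neurogenic divisions
#' self-consuming and close to half direct, with indirect neurogenic
#' divisions centred 800 um and direct ones 1306 um from the apical surface
#' (sd 150 um).
#'
#' @return a [CohortProfile-class].
#' @export
profileWeek8 <- function() {
  cohortProfile("week8", fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05),
                depthMeans = c(AA = 1000, AB = 800, AC = 1306, BB = 800,
                               CC = 1306))
}

#' @rdname profileWeek8
#' @export
profileGW17 <- function() {
  cohortProfile("GW17",
                fateProbabilities(0.6, 0.1496, 0.1224, 0.0704, 0.0576),
                depthMeans = c(AA = 1000, AB = 800, AC = 1306, BB = 800,
                               CC = 1306),
                depthSd = 150)
}
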