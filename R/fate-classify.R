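#' Classify a daughter-cell fate from marker calls
#'
#' Maps ternary SOX2/EOMES/NEUN calls (\code{"pos"}, \code{"neg"},
#' \code{"na"} = not assessed) to a fate. Precedence is NEUN > EOMES > SOX2:
#' NEUN marks terminal neuronal fate; ranking EOMES above SOX2 implements the
#' observed retention of the mother marker SOX2 in differentiating daughters,
#' so a SOX2+/EOMES+ cell is an IP. \code{"na"} is treated as negative and
#' recorded in the \code{"naAsNegative"} attribute.
#'
#' @param sox2,eomes,neun character vectors with values pos/neg/na.
#' @return factor with levels bRG, IP, neuron, unclassified; attribute
#'   \code{naAsNegative} flags elements where a not-assessed marker was
#'   treated as negative.
#' @examples
#' classifyFate("pos", "pos", "neg")  # SOX2 retention: still an IP
#' @export
classifyFate <- function(sox2, eomes, neun) {
  tok <- c("pos", "neg", "na")
  for (v in list(sox2, eomes, neun))
    if (!all(v %in% tok))
      stop("marker calls must be one of ", paste(tok, collapse = "|"))
  n <- max(length(sox2), length(eomes), length(neun))
  sox2 <- rep_len(sox2, n); eomes <- rep_len(eomes, n); neun <- rep_len(neun, n)
  fate <- ifelse(neun == "pos", "neuron",
          ifelse(eomes == "pos", "IP",
          ifelse(sox2 == "pos", "bRG", "unclassified")))
  out <- factor(fate, levels = .FATES)
  attr(out, "naAsNegative") <- sox2 == "na" | eomes == "na" | neun == "na"
  out
}

#' Classify division modes from daughter fates
#'
#' Maps the unordered pair of daughter fates of each division record to the
#' division-mode taxonomy: two bRG daughters are symmetric proliferative; one
#' bRG plus one differentiating daughter is asymmetric self-renewing (indirect
#' when the other daughter is an IP, direct when it is a neuron); two
#' differentiating daughters are symmetric self-consuming (indirect/direct
#' likewise). An IP + neuron pair - never observed in the published cohorts -
#' is labelled \code{mixed_IP_neuron} with a warning. Any unclassified
#' daughter makes the division unclassifiable.
#'
#' @param records data.frame of division records (see
#'   [generateDivisionDataset()] for the schema).
#' @return the records with added columns \code{d1_fate}, \code{d2_fate} and
#'   \code{mode} (factor over the seven taxonomy levels).
#' @export
classifyDivision <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records$d1_fate <- factor(character(), levels = .FATES)
    records$d2_fate <- factor(character(), levels = .FATES)
    records$mode <- factor(character(), levels = .DIVISION_MODES)
    return(records)
  }
  f1 <- classifyFate(records$d1_sox2, records$d1_eomes, records$d1_neun)
  f2 <- classifyFate(records$d2_sox2, records$d2_eomes, records$d2_neun)
  pairKey <- paste(pmin(as.integer(f1), as.integer(f2)),
                   pmax(as.integer(f1), as.integer(f2)))
  lut <- c("1 1" = "symmetric_proliferative",
           "1 2" = "asym_selfrenew_indirect",
           "1 3" = "asym_selfrenew_direct",
           "2 2" = "symmetric_selfconsuming_indirect",
           "3 3" = "symmetric_selfconsuming_direct",
           "2 3" = "mixed_IP_neuron")
  mode <- unname(lut[pairKey])
  mode[is.na(mode)] <- "unclassifiable"
  nMixed <- sum(mode == "mixed_IP_neuron")
  if (nMixed > 0)
    warning(nMixed, " division(s) pair an IP with a neuron, a mode never ",
            "observed in bRG cells")
  records$d1_fate <- f1
  records$d2_fate <- f2
  records$mode <- factor(mode, levels = .DIVISION_MODES)
  records
}

.ensureClassified <- function(records) {
  if (!"mode" %in% names(records)) classifyDivision(records) else records
}

.NEUROGENIC <- c("asym_selfrenew_indirect", "asym_selfrenew_direct",
                 "symmetric_selfconsuming_indirect",
                 "symmetric_selfconsuming_direct", "mixed_IP_neuron")
.ASYM <- c("asym_selfrenew_indirect", "asym_selfrenew_direct")
.DIRECT <- c("asym_selfrenew_direct", "symmetric_selfconsuming_direct")

#' Summarize division-mode proportions per stage
#'
#' Reports, per group, raw mode counts and three nested breakdowns:
#' proliferative vs neurogenic over all classifiable divisions; asymmetric
#' (self-renewing) vs symmetric (self-consuming) among neurogenic divisions;
#' and direct (daughter set contains a neuron and no IP) vs indirect
#' (contains an IP) among neurogenic divisions. Each breakdown's proportions
#' sum to one.
#'
#' @param records division records; classified on the fly if needed.
#' @param groupBy grouping column, default \code{"stage"}.
#' @return list with \code{modeCounts} (group x mode table) and
#'   \code{breakdowns}: data.frame with columns group, breakdown, level,
#'   count, proportion.
#' @export
summarizeModes <- function(records, groupBy = "stage") {
  records <- .ensureClassified(records)
  groups <- unique(records[[groupBy]])
  rows <- list()
  for (g in groups) {
    r <- records[records[[groupBy]] == g, ]
    cls <- r$mode[r$mode != "unclassifiable"]
    if (length(cls) == 0) {
      warning("group '", g, "' has no classifiable divisions; omitted")
      next
    }
    neuro <- cls[as.character(cls) %in% .NEUROGENIC]
    brk <- function(breakdown, level, count, denom) data.frame(
      group = g, breakdown = breakdown, level = level, count = count,
      proportion = if (denom > 0) count / denom else NA_real_,
      stringsAsFactors = FALSE)
    nP <- sum(cls == "symmetric_proliferative"); nN <- length(neuro)
    rows[[length(rows) + 1L]] <- brk("proliferative_vs_neurogenic",
                                     "proliferative", nP, nP + nN)
    rows[[length(rows) + 1L]] <- brk("proliferative_vs_neurogenic",
                                     "neurogenic", nN, nP + nN)
    if (nN > 0) {
      nA <- sum(as.character(neuro) %in% .ASYM)
      rows[[length(rows) + 1L]] <- brk("asymmetric_vs_symmetric",
                                       "asymmetric", nA, nN)
      rows[[length(rows) + 1L]] <- brk("asymmetric_vs_symmetric",
                                       "symmetric", nN - nA, nN)
      nD <- sum(as.character(neuro) %in% .DIRECT)
      rows[[length(rows) + 1L]] <- brk("direct_vs_indirect", "direct", nD, nN)
      rows[[length(rows) + 1L]] <- brk("direct_vs_indirect", "indirect",
                                       nN - nD, nN)
    }
  }
  list(modeCounts = table(records[[groupBy]], records$mode),
       breakdowns = if (length(rows)) do.call(rbind, rows) else
         data.frame(group = character()))
}

#' Daughter fate by basal-process inheritance among asymmetric divisions
#'
#' Restricted to asymmetric self-renewing divisions, cross-tabulates, per
#' daughter, whether it inherited the basal process against whether it is the
#' self-renewing (bRG) or the differentiating daughter, and reports the
#' percentage of process-inheriting daughters that remained bRG.
#'
#' @param records division records (classified on the fly if needed).
#' @return list with \code{table} (2 x 2: inherited yes/no x self-renewing /
#'   differentiating), \code{pctSelfRenewingInheriting} and \code{nDivisions}.
#' @export
inheritanceCrosstab <- function(records) {
  records <- .ensureClassified(records)
  r <- records[as.character(records$mode) %in% .ASYM, ]
  tab <- matrix(0L, 2, 2, dimnames = list(
    inherited = c("yes", "no"), fate = c("self_renewing", "differentiating")))
  if (nrow(r) == 0) {
    warning("no asymmetric divisions with inheritance flags")
    return(list(table = tab, pctSelfRenewingInheriting = NA_real_,
                nDivisions = 0L))
  }
  for (d in 1:2) {
    selfRenewing <- r[[sprintf("d%d_fate", d)]] == "bRG"
    inherited <- r[[sprintf("d%d_process_inherited", d)]]
    tab["yes", "self_renewing"] <- tab["yes", "self_renewing"] +
      sum(inherited & selfRenewing)
    tab["yes", "differentiating"] <- tab["yes", "differentiating"] +
      sum(inherited & !selfRenewing)
    tab["no", "self_renewing"] <- tab["no", "self_renewing"] +
      sum(!inherited & selfRenewing)
    tab["no", "differentiating"] <- tab["no", "differentiating"] +
      sum(!inherited & !selfRenewing)
  }
  pct <- 100 * tab["yes", "self_renewing"] / sum(tab["yes", ])
  list(table = tab, pctSelfRenewingInheriting = pct, nDivisions = nrow(r))
}

#' HES1 assignment among asymmetric divisions
#'
#' Among asymmetric divisions with a HES1-detectable daughter, counts how
#' often that daughter is the self-renewing (EOMES-/NEUN-) one, and
#' cross-tabulates HES1 detection against basal-process inheritance of the
#' HES1-positive daughter.
#'
#' @param records division records (classified on the fly if needed).
#' @return list with \code{nDetected}, \code{nInSelfRenewing},
#'   \code{inheritance} (named counts: \code{inherited}, \code{not_inherited}
#'   of the HES1-positive daughter).
#' @export
hes1Assignment <- function(records) {
  records <- .ensureClassified(records)
  r <- records[as.character(records$mode) %in% .ASYM, ]
  nDetected <- 0L; nSelf <- 0L
  inh <- c(inherited = 0L, not_inherited = 0L)
  for (k in seq_len(nrow(r))) {
    for (d in 1:2) {
      if (!isTRUE(r[[sprintf("d%d_hes1_detected", d)]][k])) next
      nDetected <- nDetected + 1L
      if (r[[sprintf("d%d_fate", d)]][k] == "bRG") nSelf <- nSelf + 1L
      if (isTRUE(r[[sprintf("d%d_process_inherited", d)]][k]))
        inh["inherited"] <- inh["inherited"] + 1L
      else inh["not_inherited"] <- inh["not_inherited"] + 1L
    }
  }
  list(nDetected = nDetected, nInSelfRenewing = nSelf, inheritance = inh)
}

#' Two-group comparison of depths by Student's t-test
#'
#' Two-tailed unpaired Student's t-test with pooled variance (the published
#' analyses use the equal-variance form); Welch's correction is available via
#' \code{varEqual = FALSE}.
#'
#' @param x,y numeric vectors.
#' @param varEqual pooled-variance (Student) when TRUE, Welch otherwise.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
depthCompare <- function(x, y, varEqual = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("comparison refused: each group needs at least 2 observations")
  ht <- stats::t.test(x, y, var.equal = varEqual)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Depth statistics of division records along the apico-basal axis
#'
#' Per-group mean, sd and n of division depth (micrometres from the apical
#' surface, increasing basally), with an optional two-group Student's t
#' comparison. The default grouping \code{"route"} splits neurogenic
#' divisions into indirect (daughter set contains an IP) versus direct
#' (contains a neuron, no IP); \code{"mode"} groups by the full taxonomy.
#'
#' @param records division records with \code{depth_um}.
#' @param groupBy \code{"route"} or \code{"mode"}.
#' @param compare optional character pair of group names to compare.
#' @param varEqual passed to [depthCompare()].
#' @return list with \code{summary} (group, n, mean, sd) and
#'   \code{comparison} (NULL unless requested).
#' @export
depthStats <- function(records, groupBy = c("route", "mode"), compare = NULL,
                       varEqual = TRUE) {
  groupBy <- match.arg(groupBy)
  records <- .ensureClassified(records)
  r <- records[!is.na(records$depth_um), ]
  grp <- if (groupBy == "mode") as.character(r$mode) else
    ifelse(as.character(r$mode) %in% c("asym_selfrenew_indirect",
                                       "symmetric_selfconsuming_indirect",
                                       "mixed_IP_neuron"), "indirect",
    ifelse(as.character(r$mode) %in% .DIRECT, "direct", NA_character_))
  keep <- !is.na(grp)
  r <- r[keep, ]; grp <- grp[keep]
  summ <- do.call(rbind, lapply(split(r$depth_um, grp), function(d)
    data.frame(n = length(d), mean = mean(d),
               sd = if (length(d) > 1) stats::sd(d) else NA_real_)))
  summ <- cbind(group = rownames(summ), summ)
  rownames(summ) <- NULL
  comparison <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2)
    d1 <- r$depth_um[grp == compare[1]]
    d2 <- r$depth_um[grp == compare[2]]
    comparison <- c(list(groups = compare), depthCompare(d1, d2, varEqual))
  }
  list(summary = summ, comparison = comparison)
}

#' Classify mitotic somal translocation (MST) direction
#'
#' Compares the net soma displacement along the apico-basal depth axis in the
#' window before cytokinesis against a threshold. Depth increases basally, so
#' a displacement of at least \code{threshold} micrometres towards larger
#' depth is basal MST, at least \code{threshold} towards the ventricle is
#' apical, and anything smaller (strict inequality at the boundary) is a
#' stationary division.
#'
#' @param track data.frame with columns \code{time_h} and \code{depth_um},
#'   time-ordered soma positions spanning the pre-division window.
#' @param divisionTime time of cytokinesis (hours, same clock as the track).
#' @param threshold displacement threshold in micrometres (default 10).
#' @param window length of the pre-division window in hours (default 2).
#' @return \code{"apical"}, \code{"basal"} or \code{"stationary"}.
#' @export
classifyMst <- function(track, divisionTime, threshold = 10, window = 2) {
  stopifnot(is.data.frame(track), all(c("time_h", "depth_um") %in% names(track)))
  if (missing(divisionTime) || is.null(divisionTime) || is.na(divisionTime))
    stop("track without a division time cannot be classified")
  t0 <- divisionTime - window
  if (min(track$time_h) > t0 || max(track$time_h) < divisionTime)
    stop("track does not span the pre-division window [",
         t0, ", ", divisionTime, "] hours")
  dAtDiv <- stats::approx(track$time_h, track$depth_um, xout = divisionTime)$y
  dAtT0 <- stats::approx(track$time_h, track$depth_um, xout = t0)$y
  disp <- dAtDiv - dAtT0  # positive = basal-ward
  if (disp >= threshold) "basal"
  else if (-disp >= threshold) "apical"
  else "stationary"
}
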