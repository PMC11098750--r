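## Deterministic fixtures encoding published cohort counts. No randomness:
## repeated calls are identical.

.divRow <- function(id, stage, mode, inheritFirst = TRUE, hes1First = FALSE,
                    hes1Second = FALSE, depth = NA_real_, mst = "unknown") {
  fates <- .FATE_OF_MODE[[mode]]
  m1 <- .markersForFate(fates[1], FALSE)
  m2 <- .markersForFate(fates[2], FALSE)
  data.frame(
    division_id = id, stage = stage, depth_um = depth,
    d1_sox2 = m1[["sox2"]], d1_eomes = m1[["eomes"]], d1_neun = m1[["neun"]],
    d1_process_inherited = inheritFirst, d1_hes1_detected = hes1First,
    d2_sox2 = m2[["sox2"]], d2_eomes = m2[["eomes"]], d2_neun = m2[["neun"]],
    d2_process_inherited = !inheritFirst, d2_hes1_detected = hes1Second,
    mst = mst, true_mode = unname(.MODE_TO_DIVISION[mode]),
    stringsAsFactors = FALSE)
}

#' Deterministic HES1 organoid cohort (276 divisions)
#'
#' Encodes the published week 8-11 organoid cohort stained for HES1: 276 bRG
#' divisions comprising 186 symmetric proliferative, 53 asymmetric
#' self-renewing and 37 symmetric self-consuming divisions. Exactly 16
#' asymmetric divisions carry a detectable-HES1 daughter; HES1 is always on
#' the non-differentiating (EOMES-/NEUN-) daughter, and of those 16 cells 8
#' inherited the basal process and 8 did not. The published counts fix only
#' the mode-level totals; the indirect/direct subtype splits (27/26 among
#' asymmetric, 19/18 among self-consuming) are construction choices recorded
#' in the \code{"metadata"} attribute.
#'
#' @return data.frame of 276 division records (see
#'   [generateDivisionDataset()] for the schema), deterministic across calls.
#' @export
fixtureHes1Cohort <- function() {
  stage <- "week8-11_organoid"
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  i <- 0L
  nid <- function() { i <<- i + 1L; sprintf("%s_div_%03d", stage, i) }

  for (k in seq_len(186)) add(.divRow(nid(), stage, "AA"))
  # 53 asymmetric: 27 bRG+IP, 26 bRG+neuron (daughter 1 is the bRG daughter).
  # HES1-detected subset: first 8 of each subtype; within it, the first 4
  # have the bRG daughter inheriting the process, the next 4 do not.
  for (mode in c("AB", "AC")) {
    nMode <- if (mode == "AB") 27L else 26L
    for (k in seq_len(nMode)) {
      hes1 <- k <= 8L
      inheritFirst <- if (hes1) k <= 4L else (k %% 2L == 1L)
      add(.divRow(nid(), stage, mode, inheritFirst = inheritFirst,
                  hes1First = hes1))
    }
  }
  for (k in seq_len(19)) add(.divRow(nid(), stage, "BB"))
  for (k in seq_len(18)) add(.divRow(nid(), stage, "CC"))

  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(
    mode_counts = c(symmetric_proliferative = 186L, asymmetric = 53L,
                    symmetric_selfconsuming = 37L),
    hes1_detected_asymmetric = 16L,
    hes1_inheritance_split = c(inherited = 8L, not_inherited = 8L),
    asym_subtype_split = c(indirect = 27L, direct = 26L),
    selfconsuming_subtype_split = c(indirect = 19L, direct = 18L))
  out
}

#' Deterministic fetal asymmetric-division cohort (82 divisions)
#'
#' Encodes the published gestational-week 14-17 fetal cohort of 82
#' asymmetrically dividing bRG cells: 52.4\% of basal-process-inheriting
#' daughters remained bRG (self-renewing) and 47.6\% differentiated.
#' Percentages are converted to integer counts by round-half-up
#' (52.4\% of 82 = 42.968 -> 43 self-renewing, 39 differentiating), recorded
#' in the \code{"metadata"} attribute. Every record has exactly one
#' process-inheriting daughter.
#'
#' @return data.frame of 82 asymmetric division records, deterministic across
#'   calls.
#' @export
fixtureFetalInheritance <- function() {
  stage <- "GW14-17_fetal"
  nSelf <- 43L   # round-half-up of 0.524 * 82
  nDiff <- 82L - nSelf
  rows <- list()
  i <- 0L
  for (k in seq_len(nSelf)) {  # bRG daughter (d1) inherits the process
    i <- i + 1L
    mode <- if (k %% 2L == 1L) "AB" else "AC"
    rows[[i]] <- .divRow(sprintf("%s_div_%03d", stage, i), stage, mode,
                         inheritFirst = TRUE)
  }
  for (k in seq_len(nDiff)) {  # differentiating daughter (d2) inherits
    i <- i + 1L
    mode <- if (k %% 2L == 1L) "AB" else "AC"
    rows[[i]] <- .divRow(sprintf("%s_div_%03d", stage, i), stage, mode,
                         inheritFirst = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(
    rounding = "round-half-up",
    inheriting_daughter_fate = c(self_renewing = nSelf, differentiating = nDiff),
    percent_self_renewing = round(100 * nSelf / 82, 1))
  out
}
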