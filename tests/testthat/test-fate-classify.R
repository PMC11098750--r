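test_that("marker calls map to fates with NEUN > EOMES > SOX2 precedence", {
  expect_equal(as.character(classifyFate("pos", "neg", "neg")), "bRG")
  # SOX2 retention in a differentiating daughter: still an IP
  expect_equal(as.character(classifyFate("pos", "pos", "neg")), "IP")
  expect_equal(as.character(classifyFate("neg", "pos", "neg")), "IP")
  # NEUN dominates whatever else is on
  expect_equal(as.character(classifyFate(c("pos", "neg"), c("pos", "neg"),
                                         c("pos", "pos"))),
               c("neuron", "neuron"))
  expect_equal(as.character(classifyFate("neg", "neg", "neg")), "unclassified")
  # not-assessed markers are treated as negative but flagged
  f <- classifyFate("pos", "na", "neg")
  expect_equal(as.character(f), "bRG")
  expect_true(attr(f, "naAsNegative"))
  expect_false(attr(classifyFate("pos", "neg", "neg"), "naAsNegative"))
  expect_error(classifyFate("positive", "neg", "neg"), "pos|neg|na")
})

test_that("classifyFate is total over all ternary marker combinations", {
  tok <- c("pos", "neg", "na")
  grid <- expand.grid(sox2 = tok, eomes = tok, neun = tok,
                      stringsAsFactors = FALSE)
  f <- classifyFate(grid$sox2, grid$eomes, grid$neun)
  expect_false(anyNA(f))
  expect_setequal(levels(f), c("bRG", "IP", "neuron", "unclassified"))
})

test_that("division modes follow the taxonomy and ignore daughter order", {
  mk <- function(s1, e1, n1, s2, e2, n2)
    data.frame(division_id = "d", stage = "s", depth_um = NA_real_,
               d1_sox2 = s1, d1_eomes = e1, d1_neun = n1,
               d1_process_inherited = TRUE, d1_hes1_detected = FALSE,
               d2_sox2 = s2, d2_eomes = e2, d2_neun = n2,
               d2_process_inherited = FALSE, d2_hes1_detected = FALSE,
               mst = "unknown", stringsAsFactors = FALSE)
  modeOf <- function(r) as.character(classifyDivision(r)$mode)
  # (bRG, IP) -> asymmetric self-renewing indirect
  r <- mk("pos", "neg", "neg", "pos", "pos", "neg")
  expect_equal(modeOf(r), "asym_selfrenew_indirect")
  # swapping the daughters leaves the mode unchanged
  rs <- mk("pos", "pos", "neg", "pos", "neg", "neg")
  expect_equal(modeOf(rs), "asym_selfrenew_indirect")
  expect_equal(modeOf(mk("pos", "neg", "neg", "pos", "neg", "neg")),
               "symmetric_proliferative")
  expect_equal(modeOf(mk("neg", "neg", "pos", "neg", "neg", "pos")),
               "symmetric_selfconsuming_direct")
  expect_equal(modeOf(mk("pos", "neg", "neg", "neg", "neg", "pos")),
               "asym_selfrenew_direct")
  expect_equal(modeOf(mk("neg", "pos", "neg", "pos", "pos", "neg")),
               "symmetric_selfconsuming_indirect")
  # IP + neuron: never observed; flagged with a warning
  expect_warning(m <- classifyDivision(mk("neg", "pos", "neg",
                                          "neg", "neg", "pos")),
                 "never")
  expect_equal(as.character(m$mode), "mixed_IP_neuron")
  # an unclassified daughter poisons the division
  expect_equal(modeOf(mk("neg", "neg", "neg", "pos", "neg", "neg")),
               "unclassifiable")
})

test_that("mode classification recovers the generating mode exactly", {
  rec <- classifyDivision(generateDivisionDataset(profileWeek8(), 2000,
                                                  seed = 17))
  expect_equal(as.character(rec$mode), rec$true_mode)
})

test_that("summarizeModes reports nested breakdowns that sum to one", {
  rec <- generateDivisionDataset(profileWeek8(), 3000, seed = 21)
  s <- summarizeModes(rec)
  b <- s$breakdowns
  for (brk in unique(b$breakdown)) {
    sub <- b[b$breakdown == brk, ]
    expect_equal(sum(sub$proportion), 1, tolerance = 1e-12)
  }
  nClassifiable <- sum(b$count[b$breakdown == "proliferative_vs_neurogenic"])
  expect_equal(nClassifiable, nrow(rec))
  # proportions land within 3 binomial SE of the generating split
  pv <- probVector(profileWeek8()@modeProbs)
  pNeuro <- 1 - pv[["AA"]]
  got <- b$proportion[b$breakdown == "proliferative_vs_neurogenic" &
                      b$level == "neurogenic"]
  expect_lt(abs(got - pNeuro), 3 * sqrt(pNeuro * (1 - pNeuro) / nrow(rec)))
  # an all-proliferative cohort is 100% proliferative
  allAA <- generateDivisionDataset(
    cohortProfile("pure", fateProbabilities(1, 0, 0, 0, 0)), 50, seed = 2)
  s2 <- summarizeModes(allAA)
  expect_equal(s2$breakdowns$proportion[
    s2$breakdowns$level == "proliferative"], 1)
})

test_that("inheritance crosstab counts process-inheriting daughter fates", {
  # all inheriting daughters self-renew -> 100%
  prof <- cohortProfile("x", fateProbabilities(0, 0.5, 0.5, 0, 0),
                        inheritanceSelfrenewalProb = 1)
  rec <- generateDivisionDataset(prof, 200, seed = 5)
  ic <- inheritanceCrosstab(rec)
  expect_equal(ic$pctSelfRenewingInheriting, 100)
  expect_equal(sum(ic$table), 2L * 200L)  # two daughters per division
  # inheritance independent of fate: percentage near 50 within 3 SE
  prof2 <- cohortProfile("y", fateProbabilities(0, 0.5, 0.5, 0, 0),
                         inheritanceSelfrenewalProb = 0.5)
  rec2 <- generateDivisionDataset(prof2, 5000, seed = 6)
  ic2 <- inheritanceCrosstab(rec2)
  se <- 100 * sqrt(0.25 / 5000)
  expect_lt(abs(ic2$pctSelfRenewingInheriting - 50), 3 * se)
  # no asymmetric divisions: empty table with a warning
  onlyAA <- generateDivisionDataset(
    cohortProfile("z", fateProbabilities(1, 0, 0, 0, 0)), 10, seed = 7)
  expect_warning(ic3 <- inheritanceCrosstab(onlyAA), "no asymmetric")
  expect_equal(sum(ic3$table), 0L)
})

test_that("HES1 assignment lands in the self-renewing daughter", {
  rec <- generateDivisionDataset(
    cohortProfile("h", fateProbabilities(0.3, 0.3, 0.2, 0.1, 0.1),
                  hes1DetectionProb = 0.5), 2000, seed = 8)
  ha <- hes1Assignment(rec)
  expect_gt(ha$nDetected, 0)
  expect_equal(ha$nInSelfRenewing, ha$nDetected)
  expect_equal(sum(ha$inheritance), ha$nDetected)
  # cohort without HES1 staining: zero-count summary
  rec$d1_hes1_detected <- FALSE
  rec$d2_hes1_detected <- FALSE
  ha0 <- hes1Assignment(rec)
  expect_equal(ha0$nDetected, 0L)
})

test_that("depth statistics match the closed-form Student's t oracle", {
  # constant depths: mean 500, sd 0
  rec <- generateDivisionDataset(profileWeek8(), 20, seed = 9)
  rec$depth_um <- 500
  ds <- depthStats(rec, groupBy = "mode")
  expect_true(all(ds$summary$mean == 500))
  expect_true(all(ds$summary$sd == 0 | is.na(ds$summary$sd)))
  # {1,2,3} vs {2,3,4}: pooled sd = 1, t = -1/sqrt(2/3), df = 4
  cmp <- depthCompare(c(1, 2, 3), c(2, 3, 4))
  expect_equal(abs(cmp$t), sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 2 * pt(-sqrt(3 / 2), 4), tolerance = 1e-12)
  expect_equal(round(cmp$p, 4), 0.2879)
  # groups that are too small refuse the comparison
  expect_error(depthCompare(1, c(2, 3)), "at least 2")
})

test_that("per-route depth means recover the generating values", {
  g <- generateDivisionDataset(profileGW17(), 1000, seed = 42, perMode = TRUE)
  ds <- depthStats(g, groupBy = "route", compare = c("indirect", "direct"))
  s <- ds$summary
  ind <- s[s$group == "indirect", ]
  dir <- s[s$group == "direct", ]
  expect_equal(ind$n, 2000L)
  expect_lt(abs(ind$mean - 800), 3 * 150 / sqrt(ind$n))
  expect_lt(abs(dir$mean - 1306), 3 * 150 / sqrt(dir$n))
  expect_lt(ds$comparison$p, 1e-10)
})

test_that("MST direction follows the thresholded displacement rule", {
  track <- function(d0, d1) data.frame(time_h = c(0, 10), depth_um = c(d0, d1))
  expect_equal(classifyMst(track(500, 500), divisionTime = 10), "stationary")
  # +25 um basal-ward displacement inside the 2-h pre-division window
  pre <- function(d0, d1) data.frame(time_h = c(0, 8, 10),
                                     depth_um = c(d0, d0, d1))
  expect_equal(classifyMst(pre(500, 525), divisionTime = 10,
                           threshold = 10, window = 2), "basal")
  expect_equal(classifyMst(pre(500, 475), divisionTime = 10,
                           threshold = 10, window = 2), "apical")
  # boundary: 9.9 um < 10 um threshold (strict) -> stationary
  tr <- data.frame(time_h = c(8, 10), depth_um = c(500, 509.9))
  expect_equal(classifyMst(tr, divisionTime = 10, threshold = 10, window = 2),
               "stationary")
  # exactly at threshold -> basal (>= convention)
  tr2 <- data.frame(time_h = c(8, 10), depth_um = c(500, 510))
  expect_equal(classifyMst(tr2, divisionTime = 10, threshold = 10, window = 2),
               "basal")
  expect_error(classifyMst(track(1, 2), divisionTime = NA), "division time")
  expect_error(classifyMst(data.frame(time_h = c(9.5, 10),
                                      depth_um = c(1, 2)),
                           divisionTime = 10, window = 2), "span")
})
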