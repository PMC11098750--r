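test_that("empty slice sets and impossible placements behave as specified", {
  res <- generateSliceSet(0, imageSize = 128, seed = 1)
  expect_length(res$truth@masksLive, 0L)
  expect_equal(length(unique(as.vector(res$live@pixels))), 1L)
  expect_equal(length(unique(as.vector(res$fixed@pixels))), 1L)
  expect_error(generateSliceSet(100, imageSize = 64, seed = 1),
               "non-overlapping")
})

test_that("slice sets are a pure function of (parameters, seed)", {
  a <- generateSliceSet(4, imageSize = 400, seed = 7)
  b <- generateSliceSet(4, imageSize = 400, seed = 7)
  expect_identical(a$live@pixels, b$live@pixels)
  expect_identical(a$fixed@pixels, b$fixed@pixels)
  expect_identical(a$truth@pairing, b$truth@pairing)
  expect_identical(lapply(a$truth@transforms, function(t) t@rotation),
                   lapply(b$truth@transforms, function(t) t@rotation))
  c <- generateSliceSet(4, imageSize = 400, seed = 8)
  expect_false(identical(a$live@pixels, c$live@pixels))
  # generation does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generateSliceSet(2, imageSize = 300, seed = 5))
  expect_identical(runif(1), before)
})

test_that("zero-noise fixed masks equal transformed live masks pixel for pixel", {
  res <- generateSliceSet(6, imageSize = 512, seed = 7,
                          noiseParams = list(areaJitter = 0, boundaryAmp = 0))
  size <- res$truth@imageSize
  warped <- matrix(0L, size, size)
  for (i in seq_along(res$truth@masksLive))
    warped <- warped + nnWarpMask(res$truth@masksLive[[i]],
                                  res$truth@transforms[[i]], size)
  fixedMask <- (res$fixed@pixels > 0.5) * 1L
  expect_identical(fixedMask, warped)
})

test_that("truth transforms respect the scale bound and pairing is a bijection", {
  res <- generateSliceSet(5, imageSize = 512, seed = 4)
  scales <- vapply(res$truth@transforms, function(t) t@scale, numeric(1))
  expect_true(all(scales >= 0.95 & scales <= 1.05))
  expect_setequal(res$truth@pairing, seq_len(5))
})

test_that("degenerate and empty cohorts are generated as specified", {
  expect_equal(nrow(generateDivisionDataset(profileWeek8(), 0)), 0L)
  allAA <- generateDivisionDataset(
    cohortProfile("pure", fateProbabilities(1, 0, 0, 0, 0)), 100, seed = 3)
  expect_true(all(allAA$true_mode == "symmetric_proliferative"))
  for (col in c("d1_sox2", "d2_sox2")) expect_true(all(allAA[[col]] == "pos"))
  for (col in c("d1_eomes", "d1_neun", "d2_eomes", "d2_neun"))
    expect_true(all(allAA[[col]] == "neg"))
  # invalid profile fails before sampling
  expect_error(generateDivisionDataset(
    cohortProfile("bad", fateProbabilities(1, 0, 0, 0, 0), depthSd = 150,
                  markerRetentionProb = 2), 10),
    "probabilities")
})

test_that("cohort sampling recovers the generating parameters within 3 SE", {
  n <- 10000
  prof <- profileWeek8()
  rec <- generateDivisionDataset(prof, n, seed = 1)
  pv <- probVector(prof@modeProbs)
  modeNames <- c(AA = "symmetric_proliferative", AB = "asym_selfrenew_indirect",
                 AC = "asym_selfrenew_direct",
                 BB = "symmetric_selfconsuming_indirect",
                 CC = "symmetric_selfconsuming_direct")
  for (m in names(pv)) {
    freq <- mean(rec$true_mode == modeNames[[m]])
    se <- sqrt(pv[[m]] * (1 - pv[[m]]) / n)
    expect_lt(abs(freq - pv[[m]]), 3 * se)
  }
  # per-daughter flag rates: HES1 detection among bRG daughters
  brg1 <- rec$d1_sox2 == "pos" & rec$d1_eomes == "neg" & rec$d1_neun == "neg"
  rate <- mean(rec$d1_hes1_detected[brg1])
  p <- prof@hes1DetectionProb
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / sum(brg1)))
  # HES1 never flagged on differentiating daughters
  expect_true(all(!rec$d1_hes1_detected[!brg1]))
  # depth mean per outcome within 3 SE of the generating mean
  aa <- rec$depth_um[rec$true_mode == "symmetric_proliferative"]
  expect_lt(abs(mean(aa) - prof@depthMeans[["AA"]]),
            3 * prof@depthSd / sqrt(length(aa)))
  expect_true(all(rec$depth_um >= 0))
  # exactly one process-inheriting daughter per record
  expect_true(all(xor(rec$d1_process_inherited, rec$d2_process_inherited)))
})

test_that("fixtures are deterministic and realize the published counts", {
  h1 <- fixtureHes1Cohort()
  expect_identical(h1, fixtureHes1Cohort())
  expect_equal(nrow(h1), 276L)
  f1 <- fixtureFetalInheritance()
  expect_identical(f1, fixtureFetalInheritance())
  expect_equal(nrow(f1), 82L)
  expect_true(all(f1$true_mode %in% c("asym_selfrenew_indirect",
                                      "asym_selfrenew_direct")))
  expect_true(all(xor(f1$d1_process_inherited, f1$d2_process_inherited)))
  md <- attr(f1, "metadata")
  expect_equal(sum(md$inheriting_daughter_fate), 82L)
  expect_equal(md$rounding, "round-half-up")
})
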