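test_that("fate-probability vectors are validated", {
  expect_error(fateProbabilities(0.5, 0.5, 0.5, 0, 0), "sum")
  expect_error(fateProbabilities(1.2, -0.2, 0, 0, 0), "\\[0, 1\\]")
  p <- fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
  expect_equal(unname(probVector(p)), c(0.6, 0.2, 0.1, 0.05, 0.05))
})

test_that("marginals evaluate the production-rate formulas exactly", {
  m <- marginals(fateProbabilities(1, 0, 0, 0, 0))
  expect_equal(c(m@pbarA, m@pbarB, m@pbarC), c(2, 0, 0))
  m <- marginals(fateProbabilities(0, 1, 0, 0, 0))
  expect_equal(c(m@pbarA, m@pbarB, m@pbarC), c(1, 1, 0))
  m <- marginals(fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05))
  expect_equal(c(m@pbarA, m@pbarB, m@pbarC), c(1.5, 0.3, 0.2))
})

test_that("marginals conserve two daughters per division", {
  set.seed(31)
  for (k in 1:100) {
    m <- marginals(randomFateProbs())
    expect_equal(m@pbarA + m@pbarB + m@pbarC, 2, tolerance = 1e-12)
  }
})

test_that("the recurrence iterates the printed update exactly", {
  p <- fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
  expect_equal(recurrenceCounts(p, A0 = 3, x = 0)[c("A", "B", "C")],
               c(A = 3, B = 0, C = 0))
  # pure self-amplification doubles each division
  pAA <- fateProbabilities(1, 0, 0, 0, 0)
  expect_equal(recurrenceCounts(pAA, 1, 3)[["A"]], 8)
  # hand-iterated worked vector: A_x multiplies by 1.5; B adds 0.3 A; C 0.2 A
  # x: 1 -> (1.5, .3, .2); 2 -> (2.25, .75, .5); 3 -> (3.375, 1.425, .95);
  # 4 -> (5.0625, 2.4375, 1.625)
  expect_equal(recurrenceCounts(p, 1, 4)[c("A", "B", "C")],
               c(A = 5.0625, B = 2.4375, C = 1.625), tolerance = 1e-12)
  expect_error(recurrenceCounts(p, 1, -1), ">= 0")
})

test_that("closed form equals the recurrence, including the singular limit", {
  p <- fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
  expect_equal(closedFormCounts(marginals(p), 1, 4)[c("A", "B", "C")],
               recurrenceCounts(p, 1, 4)[c("A", "B", "C")],
               tolerance = 1e-12)
  # pbarA = 1: one B per division through the analytic limit branch
  pAB <- fateProbabilities(0, 1, 0, 0, 0)
  cf <- closedFormCounts(marginals(pAB), 1, 7)
  expect_equal(cf[c("A", "B", "C")], c(A = 1, B = 7, C = 0))
  # pbarA = 2: pure doubling
  cf2 <- closedFormCounts(marginals(fateProbabilities(1, 0, 0, 0, 0)), 1, 10)
  expect_equal(cf2[c("A", "B", "C")], c(A = 1024, B = 0, C = 0))
})

test_that("closed form and recurrence agree over random vectors", {
  set.seed(13)
  for (k in 1:200) {
    p <- randomFateProbs()
    x <- sample(0:20, 1)
    expect_equal(closedFormCounts(marginals(p), 1, x)[c("A", "B", "C")],
                 recurrenceCounts(p, 1, x)[c("A", "B", "C")],
                 tolerance = 1e-10)
  }
})

test_that("bRG counts grow iff pbarA exceeds one", {
  set.seed(41)
  for (k in 1:50) {
    p <- randomFateProbs()
    m <- marginals(p)
    a <- vapply(0:6, function(x) closedFormCounts(m, 1, x)[["A"]], numeric(1))
    if (m@pbarA > 1 + 1e-9) expect_true(all(diff(a) > 0))
    if (m@pbarA < 1 - 1e-9) expect_true(all(diff(a) < 0))
  }
})

test_that("the asymptotic non-bRG ratio matches its formula and the limit", {
  m <- newMarginals(1.5, 0.3, 0.2)
  expect_equal(asymptoticRatio(m), 1)
  expect_equal(asymptoticRatio(marginals(fateProbabilities(1, 0, 0, 0, 0))), 0)
  expect_error(asymptoticRatio(newMarginals(1, 0.5, 0.5)), "pbarA > 1")
  # large-x closed form converges to the ratio
  ct <- closedFormCounts(m, 1, 50)
  expect_equal((ct[["B"]] + ct[["C"]]) / ct[["A"]], asymptoticRatio(m),
               tolerance = 1e-6)
})

test_that("stochastic simulation matches degenerate and average behaviour", {
  # degenerate outcomes are deterministic
  sim <- simulateLineages(fateProbabilities(1, 0, 0, 0, 0), 1, 3, 50, seed = 1)
  expect_true(all(sim$counts[, "A"] == 8 & sim$counts[, "B"] == 0 &
                    sim$counts[, "C"] == 0))
  simC <- simulateLineages(fateProbabilities(0, 0, 0, 0, 1), 1, 4, 50, seed = 2)
  expect_true(all(simC$counts[, "A"] == 0 & simC$counts[, "C"] == 2))
  # cell accounting: total cells = A0 + divisions performed, every replicate
  p <- fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
  sim2 <- simulateLineages(p, A0 = 2, x = 4, nReps = 200, seed = 3)
  expect_equal(unname(rowSums(sim2$counts)), 2 + sim2$divisions)
  # means approach the closed form within 3 SE
  sim3 <- simulateLineages(p, 1, 4, nReps = 2000, seed = 4)
  cf <- closedFormCounts(marginals(p), 1, 4)
  for (ty in c("A", "B", "C"))
    expect_lt(abs(sim3$mean[[ty]] - cf[[ty]]), 3 * sim3$se[[ty]])
  # determinism in the seed
  expect_identical(simulateLineages(p, 1, 3, 20, seed = 5)$counts,
                   simulateLineages(p, 1, 3, 20, seed = 5)$counts)
})

test_that("perturbation moves probability mass as specified", {
  p <- fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05)
  expect_equal(probVector(perturbFateProbabilities(p, "AA", "AB", 0)),
               probVector(p))
  # relative 20% of pAA -> pAB
  q <- perturbFateProbabilities(p, "AA", "AB", 0.2, relative = TRUE)
  expect_equal(unname(probVector(q)), c(0.48, 0.32, 0.1, 0.05, 0.05),
               tolerance = 1e-12)
  mq <- marginals(q)
  expect_equal(mq@pbarA, 1.38, tolerance = 1e-12)
  # the bRG output after 4 divisions drops by 28.4%
  drop <- 1 - closedFormCounts(mq, 1, 4)[["A"]] /
    closedFormCounts(marginals(p), 1, 4)[["A"]]
  expect_equal(round(100 * drop, 1), 28.4)
  # absolute mode
  q2 <- perturbFateProbabilities(p, "AA", "AB", 0.2, relative = FALSE)
  expect_equal(unname(probVector(q2)), c(0.4, 0.4, 0.1, 0.05, 0.05))
  expect_equal(marginals(q2)@pbarA, 1.3, tolerance = 1e-12)
  expect_error(perturbFateProbabilities(p, "BB", "AA", 0.2, relative = FALSE),
               "cannot move")
})

test_that("marginals invert from observed counts", {
  # trivial doubling
  inv <- invertMarginals(1, 5, c(A = 32, B = 0, C = 0))
  expect_equal(c(inv$marginals@pbarA, inv$marginals@pbarB,
                 inv$marginals@pbarC), c(2, 0, 0))
  expect_equal(inv$residual, 0)
  # round trip through the closed form
  inv2 <- invertMarginals(1, 4, closedFormCounts(newMarginals(1.5, 0.3, 0.2),
                                                 1, 4)[c("A", "B", "C")])
  expect_equal(c(inv2$marginals@pbarA, inv2$marginals@pbarB,
                 inv2$marginals@pbarC), c(1.5, 0.3, 0.2), tolerance = 1e-12)
  expect_lt(inv2$residual, 1e-12)
  expect_error(invertMarginals(1, 4, c(A = NA, B = 1, C = 1)), "finite")
  expect_error(invertMarginals(0, 4, c(A = 1, B = 1, C = 1)), "A0 > 0")
})

test_that("inversion round-trips random marginals with pbarA in [0.5, 2]", {
  set.seed(7)
  for (k in 1:50) {
    pa <- runif(1, 0.5, 2)
    rest <- 2 - pa
    pb <- runif(1, 0, rest)
    m <- newMarginals(pa, pb, rest - pb)
    x <- sample(1:10, 1)
    inv <- invertMarginals(1, x, closedFormCounts(m, 1, x)[c("A", "B", "C")])
    expect_equal(c(inv$marginals@pbarA, inv$marginals@pbarB,
                   inv$marginals@pbarC), c(pa, pb, rest - pb),
                 tolerance = 1e-9)
    expect_lt(inv$residual, 1e-9)
  }
})

test_that("inversion of the published week-8 output matches a numerical oracle", {
  observed <- c(A = 5.75, B = 1.21, C = 2.69)
  inv <- invertMarginals(1, 4, observed)
  # independent oracle: least-squares fit of the closed form by optim,
  # with the closed form written out directly
  fit <- optim(c(1.2, 0.5, 0.5), function(par) {
    pa <- par[1]; geom <- (pa^4 - 1) / (pa - 1)
    sum((c(pa^4, par[2] * geom, par[3] * geom) - observed)^2)
  }, method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(inv$marginals@pbarA, fit$par[1], tolerance = 1e-4)
  expect_equal(inv$marginals@pbarB, fit$par[2], tolerance = 1e-4)
  expect_equal(inv$marginals@pbarC, fit$par[3], tolerance = 1e-4)
  expect_equal(inv$marginals@pbarA, 1.5485, tolerance = 1e-4)
  expect_equal(inv$marginals@pbarB, 0.1397, tolerance = 1e-3)
  expect_equal(inv$marginals@pbarC, 0.3106, tolerance = 1e-3)
})
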