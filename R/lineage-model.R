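## Multitype branching model of bRG output. Types: A = bRG (the only dividing
## type in the model), B = IP, C = neuron; B and C are terminal exactly as in
## the printed recurrences, even though IPs divide biologically.

#' Marginal per-division production rates
#'
#' Evaluates \code{pbarA = 2 pAA + pAB + pAC}, \code{pbarB = pAB + 2 pBB},
#' \code{pbarC = pAC + 2 pCC}. They sum to 2 for any valid probability vector
#' (two daughters per division).
#'
#' @param p a [FateProbabilities-class].
#' @return a [Marginals-class].
#' @examples
#' marginals(fateProbabilities(0.6, 0.2, 0.1, 0.05, 0.05))  # (1.5, 0.3, 0.2)
#' @export
marginals <- function(p) {
  stopifnot(is(p, "FateProbabilities"))
  validObject(p)
  newMarginals(2 * p@pAA + p@pAB + p@pAC,
               p@pAB + 2 * p@pBB,
               p@pAC + 2 * p@pCC)
}

#' Expected cell counts by iterating the recurrence
#'
#' Iterates, exactly \code{x} times from (A0, 0, 0), the recurrences
#' \deqn{A_x = A_{x-1}(2p_{AA}+p_{AB}+p_{AC}),\quad
#'   B_x = B_{x-1} + A_{x-1}(p_{AB}+2p_{BB}),\quad
#'   C_x = C_{x-1} + A_{x-1}(p_{AC}+2p_{CC}).}
#'
#' @param p a [FateProbabilities-class].
#' @param A0 initial bRG count.
#' @param x number of divisions (>= 0).
#' @return named numeric: A, B, C, x, A0.
#' @export
recurrenceCounts <- function(p, A0 = 1, x = 1) {
  stopifnot(is(p, "FateProbabilities"))
  validObject(p)
  if (x < 0) stop("x must be >= 0")
  m <- marginals(p)
  A <- A0; B <- 0; C <- 0
  for (i in seq_len(x)) {
    Aprev <- A
    A <- Aprev * m@pbarA
    B <- B + Aprev * m@pbarB
    C <- C + Aprev * m@pbarC
  }
  c(A = A, B = B, C = C, x = x, A0 = A0)
}

#' Expected cell counts from the closed form
#'
#' Evaluates \eqn{A_x = A_0 \bar p_A^x}, \eqn{B_x = A_0 \bar p_B
#' (\bar p_A^x - 1)/(\bar p_A - 1)} and the analogous \eqn{C_x}. At
#' \eqn{\bar p_A = 1} (within 1e-9) the analytic limit \eqn{B_x = A_0 \bar
#' p_B x} is used.
#'
#' @param m a [Marginals-class] (or a [FateProbabilities-class], converted).
#' @param A0 initial bRG count.
#' @param x number of divisions (>= 0).
#' @return named numeric: A, B, C, x, A0.
#' @export
closedFormCounts <- function(m, A0 = 1, x = 1) {
  if (is(m, "FateProbabilities")) m <- marginals(m)
  stopifnot(is(m, "Marginals"))
  if (x < 0) stop("x must be >= 0")
  pa <- m@pbarA
  geom <- if (abs(pa - 1) < 1e-9) x else (pa^x - 1) / (pa - 1)
  c(A = A0 * pa^x, B = A0 * m@pbarB * geom, C = A0 * m@pbarC * geom,
    x = x, A0 = A0)
}

#' Asymptotic ratio of non-bRG to bRG cells
#'
#' For \eqn{\bar p_A > 1} the ratio (IP + neurons)/bRG converges to
#' \eqn{(2 - \bar p_A)/(\bar p_A - 1)}.
#'
#' @param m a [Marginals-class] (or [FateProbabilities-class]).
#' @return the limiting ratio.
#' @export
asymptoticRatio <- function(m) {
  if (is(m, "FateProbabilities")) m <- marginals(m)
  stopifnot(is(m, "Marginals"))
  if (m@pbarA <= 1)
    stop("asymptotic ratio requires pbarA > 1 (the bRG pool must grow; ",
         "it decreases when pbarA < 1)")
  (2 - m@pbarA) / (m@pbarA - 1)
}

#' Stochastic lineage simulation
#'
#' Simulates the branching process replicate by replicate: at each generation
#' every bRG (type A) cell independently draws one of the five division
#' outcomes; IPs and neurons are terminal and never divide.
#'
#' @param p a [FateProbabilities-class].
#' @param A0 initial bRG count.
#' @param x number of divisions (generations of divisions).
#' @param nReps number of replicates (>= 1).
#' @param seed integer seed.
#' @return list with \code{counts} (nReps x 3 matrix of final A, B, C),
#'   \code{mean}, \code{se} (per-type standard error over replicates) and
#'   \code{divisions} (total divisions performed per replicate).
#' @export
simulateLineages <- function(p, A0 = 1, x = 4, nReps = 1000, seed = 1L) {
  stopifnot(is(p, "FateProbabilities"))
  validObject(p)
  stopifnot(nReps >= 1, x >= 0, A0 >= 0)
  prob <- probVector(p)
  .withSeed(seed, {
    counts <- matrix(0, nReps, 3, dimnames = list(NULL, c("A", "B", "C")))
    divisions <- integer(nReps)
    for (r in seq_len(nReps)) {
      A <- A0; B <- 0; C <- 0; nDiv <- 0L
      for (g in seq_len(x)) {
        if (A == 0) break
        draw <- stats::rmultinom(1, A, prob)[, 1]
        nDiv <- nDiv + A
        A <- 2 * draw[["AA"]] + draw[["AB"]] + draw[["AC"]]
        B <- B + draw[["AB"]] + 2 * draw[["BB"]]
        C <- C + draw[["AC"]] + 2 * draw[["CC"]]
      }
      counts[r, ] <- c(A, B, C)
      divisions[r] <- nDiv
    }
    list(counts = counts, mean = colMeans(counts),
         se = apply(counts, 2, stats::sd) / sqrt(nReps),
         divisions = divisions)
  })
}

#' Shift probability mass between division outcomes
#'
#' Moves probability mass from one outcome to another, either a relative
#' fraction of the source outcome's probability (default, matching statements
#' like "reducing the rate of proliferative divisions by 20\%") or an
#' absolute amount.
#'
#' @param p a [FateProbabilities-class].
#' @param fromMode,toMode outcome codes among AA, AB, AC, BB, CC.
#' @param fraction fraction of \code{p[fromMode]} (relative) or absolute mass.
#' @param relative interpret \code{fraction} relatively (default TRUE).
#' @return a revalidated [FateProbabilities-class].
#' @export
perturbFateProbabilities <- function(p, fromMode, toMode, fraction,
                                     relative = TRUE) {
  stopifnot(is(p, "FateProbabilities"), fraction >= 0)
  fromMode <- match.arg(fromMode, .MODES)
  toMode <- match.arg(toMode, .MODES)
  v <- probVector(p)
  mass <- if (relative) fraction * v[fromMode] else fraction
  if (mass > v[fromMode] + 1e-12)
    stop(sprintf("cannot move %.4g from p%s = %.4g", mass, fromMode,
                 v[fromMode]))
  v[fromMode] <- v[fromMode] - mass
  v[toMode] <- v[toMode] + mass
  fateProbabilities(v[1], v[2], v[3], v[4], v[5])
}

#' Recover marginals from observed expected counts
#'
#' Inverts the closed form: \eqn{\bar p_A = (A_x/A_0)^{1/x}}, then
#' \eqn{\bar p_B, \bar p_C} from the geometric sums. The conservation
#' residual \eqn{|\bar p_A + \bar p_B + \bar p_C - 2|} is reported as a
#' model-consistency diagnostic (zero for counts produced by the model
#' itself; small for rounded published outputs).
#'
#' @param A0 initial bRG count (> 0).
#' @param x number of divisions (>= 1).
#' @param observed named numeric with components A, B, C (A > 0).
#' @return list with \code{marginals} ([Marginals-class]) and
#'   \code{residual}.
#' @export
invertMarginals <- function(A0, x, observed) {
  if (!all(is.finite(c(A0, x, observed[c("A", "B", "C")]))))
    stop("inputs must be finite")
  if (A0 <= 0 || x < 1 || observed[["A"]] <= 0)
    stop("need A0 > 0, x >= 1 and observed A > 0")
  pa <- (observed[["A"]] / A0)^(1 / x)
  geom <- if (abs(pa - 1) < 1e-9) x else (pa^x - 1) / (pa - 1)
  pb <- observed[["B"]] / (A0 * geom)
  pc <- observed[["C"]] / (A0 * geom)
  m <- newMarginals(pa, pb, pc)
  list(marginals = m, residual = abs(pa + pb + pc - 2))
}
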