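#' Simulate one single-cohort pedigree
#'
#' Draws a reproductive potential lambda_i i.i.d. from `lambdaDist` for each
#' of N mothers, then an offspring number k_i from the negative binomial
#' with mean lambda_i and overdispersion `phi` (Poisson when `phi = Inf`),
#' and records the mother index of every surviving offspring. A cohort with
#' zero total offspring is valid output.
#'
#' Uses R's global RNG stream; call `set.seed()` (or use [runExperiment()],
#' which manages seeds) for reproducibility.
#'
#' @param N integer number of mothers, >= 1.
#' @param lambdaDist a [LambdaDistribution-class].
#' @param phi positive overdispersion parameter, or `Inf` for Poisson.
#' @return A [PedigreeCohort-class].
#' @examples
#' set.seed(1)
#' simulateCohort(100, constantLambda(4.5), phi = Inf)
#' @export
simulateCohort <- function(N, lambdaDist, phi) {
  stopifnot(is(lambdaDist, "LambdaDistribution"))
  if (N < 1 || N != floor(N)) stop("N must be a positive integer")
  if (length(phi) != 1L || is.na(phi) || phi <= 0)
    stop("phi must be a single positive number (Inf allowed)")
  sup <- lambdaSupport(lambdaDist)
  lam <- if (length(sup) == 1L) rep.int(sup, N) else
    sample(sup, N, replace = TRUE, prob = lambdaWeights(lambdaDist))
  k <- if (is.infinite(phi)) stats::rpois(N, lam) else
    stats::rnbinom(N, size = phi, mu = lam)
  k[lam == 0] <- 0L
  new("PedigreeCohort", motherLambdas = lam,
      offspringMothers = rep.int(seq_len(N), k))
}

#' Sample offspring from a cohort and return their mother indices
#'
#' Uniform sampling without replacement of `n` offspring from the cohort.
#' Returns `NULL` (the replicate is flagged for skipping, not an error) when
#' the cohort holds fewer than `n` survivors.
#'
#' @param cohort a [PedigreeCohort-class].
#' @param n integer number of offspring to sample.
#' @return integer vector of `n` mother indices, or `NULL` if the cohort is
#'   too small.
#' @export
sampleOffspring <- function(cohort, n) {
  stopifnot(is(cohort, "PedigreeCohort"))
  total <- nOffspring(cohort)
  if (n > total) return(NULL)
  cohort@offspringMothers[sample.int(total, n)]
}

#' Count maternal half-sibling pairs in a sampled set of offspring
#'
#' With m_j the number of sampled offspring of mother j, the MHS pair count
#' is `sum(choose(m_j, 2))`: the number of unordered offspring pairs sharing
#' a mother (full-sib pairs included by definition).
#'
#' @param sampledMothers vector of mother identifiers, one per sampled
#'   offspring.
#' @return integer pair count.
#' @examples
#' countMhsPairs(c("A", "A", "A", "B", "B")) # 4
#' @export
countMhsPairs <- function(sampledMothers) {
  m <- tabulate(factor(sampledMothers))
  as.integer(sum(m * (m - 1) / 2))
}

#' Run a full pedigree-simulation experiment
#'
#' Simulates `nHistories` independent cohorts of N mothers; from each cohort
#' draws `nSamplingsPerHistory` independent samples of n offspring, counts
#' MHS pairs, and computes the full estimate set per sampling. Pools all
#' histories-by-samplings data points and summarizes them the way the
#' estimator-validation figures are built: mean and 2.5/97.5 percentile
#' interval of the Ne estimate, the ratio of the mean variance estimate to
#' the empirical variance, and the analogous CV ratio.
#'
#' Samplings within a history share the cohort, so data points are clustered
#' by history; interpret Monte-Carlo errors accordingly.
#'
#' @param N integer number of mothers.
#' @param phi positive overdispersion parameter, or `Inf`.
#' @param lambdaDist a [LambdaDistribution-class].
#' @param n offspring sample size per sampling.
#' @param nHistories number of independent cohorts (default 100).
#' @param nSamplingsPerHistory samples per cohort (default 1000).
#' @param seed integer root seed; per-history seeds are derived from it so
#'   each history is reproducible in isolation.
#' @return list with elements
#'   \describe{
#'     \item{summary}{named list: `trueNe`, `c`, `pi`, `meanNe1`, `varNe1`,
#'       `ciLow`, `ciHigh`, `meanV`, `meanCv`, `ratioV`, `ratioCv`,
#'       `fracHZero`, `mhsFraction` (pooled H / pooled pairs), `nSkipped`,
#'       `nReplicates`, `seed`.}
#'     \item{replicates}{data.frame with one row per retained sampling:
#'       `history`, `sampling`, `hObs`, `ne0`, `ne1`, `v`, `cv`.}
#'     \item{config}{the input configuration as a named list.}
#'   }
#' @examples
#' res <- runExperiment(100, Inf, constantLambda(4.5), n = 30,
#'                      nHistories = 5, nSamplingsPerHistory = 50, seed = 1)
#' res$summary$meanNe1
#' @export
runExperiment <- function(N, phi, lambdaDist, n,
                          nHistories = 100, nSamplingsPerHistory = 1000,
                          seed = NULL) {
  stopifnot(is(lambdaDist, "LambdaDistribution"))
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  histSeeds <- sample.int(.Machine$integer.max, nHistories)

  np <- nPairs(n)
  rows <- vector("list", nHistories)
  nSkipped <- 0L
  for (hidx in seq_len(nHistories)) {
    set.seed(histSeeds[hidx])
    cohort <- simulateCohort(N, lambdaDist, phi)
    h <- integer(nSamplingsPerHistory)
    ok <- logical(nSamplingsPerHistory)
    for (s in seq_len(nSamplingsPerHistory)) {
      mothers <- sampleOffspring(cohort, n)
      if (is.null(mothers)) next
      h[s] <- countMhsPairs(mothers)
      ok[s] <- TRUE
    }
    nSkipped <- nSkipped + sum(!ok)
    h <- h[ok]
    rows[[hidx]] <- data.frame(
      history = rep.int(hidx, sum(ok)), sampling = which(ok), hObs = h,
      ne0 = .ne0(np, h), ne1 = .ne1(np, h),
      v = .vhat(np, h), cv = .cvhat(np, h))
  }
  reps <- do.call(rbind, rows)

  dq <- derivedQuantities(N, phi, lambdaDist)
  ne1 <- reps$ne1
  ci <- stats::quantile(ne1, c(0.025, 0.975), names = FALSE)
  empCv <- stats::sd(ne1) / mean(ne1)
  summary <- list(
    trueNe = dq$ne, c = dq$c, pi = dq$pi,
    meanNe1 = mean(ne1), varNe1 = stats::var(ne1),
    ciLow = ci[1], ciHigh = ci[2],
    meanV = mean(reps$v), meanCv = mean(reps$cv),
    ratioV = mean(reps$v) / stats::var(ne1),
    ratioCv = mean(reps$cv) / empCv,
    fracHZero = mean(reps$hObs == 0),
    mhsFraction = sum(reps$hObs) / (nrow(reps) * np),
    nSkipped = nSkipped, nReplicates = nrow(reps), seed = seed)
  structure(list(summary = summary, replicates = reps,
                 config = list(N = N, phi = phi,
                               lambdaSupport = lambdaSupport(lambdaDist),
                               lambdaWeights = lambdaWeights(lambdaDist),
                               n = n, nHistories = nHistories,
                               nSamplingsPerHistory = nSamplingsPerHistory,
                               seed = seed)),
            class = "hsExperiment")
}

#' @export
print.hsExperiment <- function(x, ...) {
  s <- x$summary
  cat("Pedigree-simulation experiment:",
      sprintf("%d replicates (%d skipped)\n", s$nReplicates, s$nSkipped))
  cat(sprintf("  true Ne = %.4g (c = %.4g), mean Ne1 = %.4g [%.4g, %.4g]\n",
              s$trueNe, s$c, s$meanNe1, s$ciLow, s$ciHigh))
  cat(sprintf("  ratio mean(v)/Var(Ne1) = %.3f, ratio mean(cv)/CV = %.3f\n",
              s$ratioV, s$ratioCv))
  invisible(x)
}
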