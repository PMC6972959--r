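#' Number of pairs in a sample of n offspring
#'
#' @param n integer sample size(s), each >= 2.
#' @return numeric n(n-1)/2.
#' @examples
#' nPairs(10) # 45
#' @export
nPairs <- function(n) {
  if (any(is.na(n)) || any(n < 2) || any(n != floor(n)))
    stop("n must consist of integers >= 2")
  as.numeric(n) * (n - 1) / 2
}

#' Binomial model for the number of MHS pairs in a sample
#'
#' Under no overdispersion (c = 1), the number H of maternal half-sibling
#' pairs among `nPair` sample pairs is approximately binomial(nPair, pi).
#' `hPmf` is that pmf; `expectedH` and `varH` are its mean `nPair * pi` and
#' variance `nPair * pi * (1 - pi)`. When c > 1 the expectation remains a
#' good approximation but the binomial variance understates the true
#' variance of H (pairs are positively correlated through shared successful
#' mothers), increasingly so at large n.
#'
#' @param h integer MHS pair count(s) in `0:nPair`.
#' @param nPair number of pairs in the sample, n(n-1)/2.
#' @param pi MHS probability in (0, 1), see [mhsProbability()].
#' @return probability, mean, or variance, respectively.
#' @examples
#' hPmf(2, 3, 0.5)      # 0.375
#' expectedH(4950, 0.01) # 49.5
#' @export
hPmf <- function(h, nPair, pi) {
  if (any(h < 0) || any(h > nPair) || any(h != floor(h)))
    stop("h must consist of integers in [0, nPair]")
  if (pi <= 0 || pi >= 1) stop("pi must be in (0, 1)")
  stats::dbinom(h, nPair, pi)
}

#' @rdname hPmf
#' @export
expectedH <- function(nPair, pi) nPair * pi

#' @rdname hPmf
#' @export
varH <- function(nPair, pi) nPair * pi * (1 - pi)

# vectorized internal formulas on (nPair, h); exported wrappers take a
# SampleObservation
.ne0 <- function(nPair, h) ifelse(h > 0, nPair / h, NA_real_)
.ne1 <- function(nPair, h) (nPair + 1) / (h + 1)
.vhat <- function(nPair, h) (nPair + 1) * (nPair - h) / ((h + 1)^2 * (h + 2))
.cvhat <- function(nPair, h) sqrt((nPair - h) / ((nPair + 1) * (h + 2)))

#' Moment estimator of effective mother size
#'
#' `nPair/hObs`. Undefined when no MHS pair is observed: returns `NA_real_`
#' (a flagged undefined value, not an error) so that batch simulations can
#' count the failure rate. Even when defined it is strongly upward biased
#' for small samples; prefer [neUnbiased()].
#'
#' @param obs a [SampleObservation-class].
#' @return numeric estimate, or `NA_real_` when `hObs = 0`.
#' @examples
#' neMoment(SampleObservation(10, 5)) # 9
#' @export
neMoment <- function(obs) {
  stopifnot(is(obs, "SampleObservation"))
  .ne0(nPair(obs), hObs(obs))
}

#' Nearly unbiased (Chapman-type) estimator of effective mother size
#'
#' `(nPair + 1)/(hObs + 1)`: the add-one correction analogous to Chapman's
#' mark-recapture estimator. Always finite, bounded in \[1, nPair + 1\], and
#' downwardly biased by exactly [biasMean()] under the binomial model.
#'
#' @param obs a [SampleObservation-class].
#' @return numeric estimate.
#' @examples
#' neUnbiased(SampleObservation(10, 4)) # 9.2
#' @export
neUnbiased <- function(obs) {
  stopifnot(is(obs, "SampleObservation"))
  .ne1(nPair(obs), hObs(obs))
}

#' Analytic bias of the nearly unbiased estimator
#'
#' `b_mean = -Ne (1 - 1/Ne)^(nPair + 1)`: the exact bias of
#' `(nPair + 1)/(H + 1)` when H is binomial(nPair, 1/Ne). Always negative
#' and decaying geometrically in nPair, which is why the estimator is
#' "nearly" unbiased at moderate sample sizes.
#'
#' @param ne true effective mother size, > 1.
#' @param nPair number of pairs in the sample.
#' @return numeric bias (<= 0).
#' @examples
#' biasMean(100, nPairs(22)) # about -9.7
#' @export
biasMean <- function(ne, nPair) {
  if (any(ne <= 1)) stop("ne must exceed 1")
  -ne * (1 - 1 / ne)^(nPair + 1)
}

#' Variance estimator for the nearly unbiased Ne estimator
#'
#' `v = (nPair + 1)(nPair - hObs) / ((hObs + 1)^2 (hObs + 2))`. Zero iff
#' every sample pair is an MHS pair.
#'
#' @param obs a [SampleObservation-class].
#' @return non-negative numeric.
#' @examples
#' varEstimator(SampleObservation(10, 4)) # about 12.57
#' @export
varEstimator <- function(obs) {
  stopifnot(is(obs, "SampleObservation"))
  .vhat(nPair(obs), hObs(obs))
}

#' Analytic bias of the variance estimator
#'
#' `b_var = E[v] - V[Ne1]` under the binomial model:
#' `Ne^2 [ (1-1/Ne)^(nPair+2) + ((nPair+2)/Ne - 2)(1-1/Ne)^(nPair+1)
#'        + (1-1/Ne)^(2(nPair+1)) ]`.
#' Vanishes as nPair grows but has an interior peak in n at fixed Ne.
#'
#' @inheritParams biasMean
#' @return numeric bias.
#' @export
biasVar <- function(ne, nPair) {
  if (any(ne <= 1)) stop("ne must exceed 1")
  q <- 1 - 1 / ne
  ne^2 * (q^(nPair + 2) + ((nPair + 2) / ne - 2) * q^(nPair + 1) +
            q^(2 * (nPair + 1)))
}

#' Coefficient-of-variation estimator for the Ne estimator
#'
#' `cv = sqrt((nPair - hObs) / ((nPair + 1)(hObs + 2)))`, algebraically equal
#' to `sqrt(v)/ne1`. When `nPair >> hObs` it is approximately
#' `sqrt(1/(hObs + 2))`: the precision of the estimate is set almost
#' entirely by the number of MHS pairs found, not by n itself.
#'
#' @param obs a [SampleObservation-class].
#' @return non-negative numeric.
#' @examples
#' cvEstimator(SampleObservation(10, 4)) # about 0.385
#' @export
cvEstimator <- function(obs) {
  stopifnot(is(obs, "SampleObservation"))
  .cvhat(nPair(obs), hObs(obs))
}

#' Index of mother number, (N - 1)/c
#'
#' N and c cannot be estimated separately from MHS counts alone, but their
#' combination (N - 1)/c can: `ne1 - 1` (nearly unbiased variant) or
#' `nPair/hObs - 1` (moment variant, `NA` when `hObs = 0`). If c is stable
#' across years the index tracks temporal trends in mother number.
#'
#' @param obs a [SampleObservation-class].
#' @param useUnbiased logical; use the nearly unbiased variant (default) or
#'   the moment variant.
#' @return numeric index, `NA_real_` for the moment variant at `hObs = 0`.
#' @examples
#' motherIndex(SampleObservation(10, 4))                      # 8.2
#' motherIndex(SampleObservation(10, 5), useUnbiased = FALSE) # 8
#' @export
motherIndex <- function(obs, useUnbiased = TRUE) {
  stopifnot(is(obs, "SampleObservation"))
  if (useUnbiased) neUnbiased(obs) - 1 else neMoment(obs) - 1
}

#' Smallest sample size with relative bias below a threshold
#'
#' The requisite sample size: the smallest integer n >= 2 such that
#' `|biasMean(ne, n(n-1)/2)| < relBias * ne`. Since |b_mean| is strictly
#' decreasing in n, an upward integer search terminates at the answer.
#'
#' @param ne true effective mother size, > 1.
#' @param relBias relative bias threshold in (0, 1); default 0.10.
#' @return integer sample size.
#' @examples
#' requisiteSampleSize(100)   # 22
#' requisiteSampleSize(1000)  # 69
#' requisiteSampleSize(10000) # 216
#' @export
requisiteSampleSize <- function(ne, relBias = 0.1) {
  if (length(ne) != 1L || is.na(ne) || ne <= 1) stop("ne must exceed 1")
  if (relBias <= 0 || relBias >= 1) stop("relBias must be in (0, 1)")
  n <- 2L
  while (abs(biasMean(ne, nPairs(n))) >= relBias * ne) n <- n + 1L
  n
}

#' @describeIn estimateNe method for a SampleObservation.
#' @export
setMethod("estimateNe", "SampleObservation", function(obs, ...) {
  np <- nPair(obs)
  h <- hObs(obs)
  new("NeEstimates",
      n = obs@n, nPair = np, hObs = h,
      ne0 = .ne0(np, h), ne1 = .ne1(np, h),
      v = .vhat(np, h), cv = .cvhat(np, h),
      index = .ne1(np, h) - 1)
})

#' @describeIn estimateNe method for numeric `n`; supply `hObs`.
#' @param hObs observed MHS pair count (numeric method only).
#' @export
setMethod("estimateNe", "numeric", function(obs, hObs, ...) {
  estimateNe(SampleObservation(obs, hObs))
})
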