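#' Offspring-number probability mass function
#'
#' Probability that a mother with reproductive potential `lam` leaves `k`
#' surviving offspring at sampling, under negative binomial reproduction with
#' overdispersion parameter `phi`. The distribution has mean `lam` and
#' variance `lam + lam^2/phi`; `phi = Inf` selects the Poisson limit exactly.
#' `lam = 0` is treated as a point mass at k = 0 (a mother with zero
#' reproductive potential), for continuity of the model.
#'
#' @param k non-negative integer count(s) of surviving offspring.
#' @param lam non-negative reproductive potential (expected offspring).
#' @param phi positive overdispersion parameter, or `Inf` for Poisson.
#' @return numeric vector of probabilities.
#' @examples
#' nbOffspringPmf(0, lam = 1, phi = 1)   # geometric case: 0.5
#' nbOffspringPmf(3, lam = 2, phi = Inf) # Poisson
#' @export
nbOffspringPmf <- function(k, lam, phi) {
  if (any(k < 0) || any(k != floor(k)))
    stop("k must consist of non-negative integers")
  if (length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single non-negative number")
  if (length(phi) != 1L || is.na(phi) || phi <= 0)
    stop("phi must be a single positive number (Inf allowed)")
  if (lam == 0) return(as.numeric(k == 0))
  if (is.infinite(phi)) stats::dpois(k, lam) else stats::dnbinom(k, size = phi, mu = lam)
}

#' Combined overdispersion parameter c
#'
#' Summarizes the two sources of deviation from Poisson reproduction in one
#' parameter: `c = (1 + 1/phi) * E[lambda^2]/E[lambda]^2`. Nonparental
#' variation (family-correlated survival) enters through `phi`, parental
#' variation (age/size-dependent fecundity) through the moment ratio.
#' `c = 1` iff `phi = Inf` and lambda is constant.
#'
#' @param phi positive overdispersion parameter, or `Inf`.
#' @param momentRatio `E[lambda^2]/E[lambda]^2`, a number >= 1, or a
#'   [LambdaDistribution-class] from which it is computed.
#' @return numeric c >= 1.
#' @examples
#' overdispersionC(0.1302, 1.1519) # about 10
#' overdispersionC(Inf, 1)         # 1: Poisson, constant lambda
#' @export
overdispersionC <- function(phi, momentRatio) {
  if (is(momentRatio, "LambdaDistribution"))
    momentRatio <- momentRatio(momentRatio)
  if (length(phi) != 1L || is.na(phi) || phi <= 0)
    stop("phi must be a single positive number (Inf allowed)")
  if (any(momentRatio < 1 - 1e-12))
    stop("momentRatio must be >= 1 (Cauchy-Schwarz)")
  (1 + 1 / phi) * momentRatio
}

#' Probability that two random same-cohort offspring are maternal half-sibs
#'
#' The MHS probability `pi = c/(N + c - 1)` for a population of N mothers
#' with combined overdispersion c. Increasing in c at fixed N, decreasing in
#' N at fixed c; reduces to 1/N when c = 1.
#'
#' @param N integer number of mothers, >= 2.
#' @param c combined overdispersion, >= 1 (see [overdispersionC()]).
#' @return probability in (0, 1].
#' @examples
#' mhsProbability(100, 1)  # 1/100
#' mhsProbability(100, 10) # 10/109
#' @export
mhsProbability <- function(N, c) {
  .checkNc(N, c)
  c / (N + c - 1)
}

#' Effective mother size from census size and overdispersion
#'
#' `Ne = 1/pi = (N - 1)/c + 1`: the reciprocal of the MHS probability. This
#' is an inbreeding-type effective size; for a single cohort under
#' overlapping generations it is the effective breeding mother size. Equals
#' N iff c = 1, and is always <= N.
#'
#' @inheritParams mhsProbability
#' @return numeric Ne in \[1, N\].
#' @examples
#' effectiveMotherSize(991, 10) # 100
#' @export
effectiveMotherSize <- function(N, c) {
  .checkNc(N, c)
  (N - 1) / c + 1
}

#' Drift-based effective size under constant reproductive potential
#'
#' The classical variance/drift effective size `N/(1/lam + c - 1)` with
#' `c = 1 + 1/phi`, valid when lambda is constant across mothers. It agrees
#' asymptotically with the MHS-based effective mother size only when
#' lam = 1 (stationary population size).
#'
#' @param N integer number of mothers, >= 2.
#' @param lam positive constant reproductive potential.
#' @param phi positive overdispersion parameter, or `Inf`.
#' @return numeric effective size.
#' @examples
#' driftBasedNe(100, lam = 1, phi = Inf) # 100
#' driftBasedNe(100, lam = 2, phi = 1)   # 66.67
#' @export
driftBasedNe <- function(N, lam, phi) {
  if (length(lam) != 1L || is.na(lam) || lam <= 0)
    stop("lam must be a single positive number")
  if (length(phi) != 1L || is.na(phi) || phi <= 0)
    stop("phi must be a single positive number (Inf allowed)")
  c <- 1 + 1 / phi
  N / (1 / lam + c - 1)
}

#' Ratio of effective mother size to census mother size
#'
#' Exact ratio `Ne/N = 1/c + (1/N)(1 - 1/c)`, together with the large-N
#' approximation `1/c`. Strong overdispersion (large c) is what drives the
#' very small Ne/N ratios reported for high-fecundity marine species.
#'
#' @inheritParams mhsProbability
#' @return named list with elements `exact` and `approx`.
#' @examples
#' neCensusRatio(100, 10) # exact 0.109, approx 0.1
#' @export
neCensusRatio <- function(N, c) {
  .checkNc(N, c)
  list(exact = 1 / c + (1 / N) * (1 - 1 / c), approx = 1 / c)
}

#' Model quantities derived from (N, phi, f(lambda))
#'
#' Convenience wrapper computing the combined overdispersion c, the MHS
#' probability pi, the effective mother size Ne and the ratio Ne/N for a
#' fully specified reproduction model.
#'
#' @param N integer number of mothers, >= 2.
#' @param phi positive overdispersion parameter, or `Inf`.
#' @param lambdaDist a [LambdaDistribution-class].
#' @return named list with `N`, `c`, `pi`, `ne`, `neRatio`.
#' @examples
#' derivedQuantities(100, Inf, constantLambda(4.5))
#' @export
derivedQuantities <- function(N, phi, lambdaDist) {
  c <- overdispersionC(phi, lambdaDist)
  list(N = N, c = c, pi = mhsProbability(N, c),
       ne = effectiveMotherSize(N, c), neRatio = neCensusRatio(N, c)$exact)
}

.checkNc <- function(N, c) {
  if (length(N) != 1L || is.na(N) || N < 2 || N != floor(N))
    stop("N must be a single integer >= 2")
  if (length(c) != 1L || is.na(c) || c < 1)
    stop("c must be a single number >= 1")
  invisible(TRUE)
}
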