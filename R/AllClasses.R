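#' @import methods
NULL

# tolerance for probability-vector normalization checks
.WEIGHT_TOL <- 1e-9

#' Discrete distribution of reproductive potential among mothers
#'
#' `LambdaDistribution` represents the distribution f(lambda) of reproductive
#' potential (expected number of surviving offspring at sampling) across
#' mothers, as a discrete set of support points with probability weights.
#' Parental variation (age- or size-driven differences in mean fecundity)
#' enters the model only through the ratio of the second moment to the
#' squared first moment of this distribution.
#'
#' @slot support numeric vector of non-negative lambda values.
#' @slot weights numeric vector of probabilities, same length as `support`,
#'   summing to 1.
#'
#' @seealso [LambdaDistribution()], [momentRatio()], [buildLambdaDistribution()]
#' @export
setClass("LambdaDistribution",
  slots = c(support = "numeric", weights = "numeric")
)

setValidity("LambdaDistribution", function(object) {
  msg <- character()
  if (length(object@support) != length(object@weights))
    msg <- c(msg, "support and weights must have the same length")
  if (length(object@support) == 0L)
    msg <- c(msg, "support must be non-empty")
  if (any(!is.finite(object@support)) || any(object@support < 0))
    msg <- c(msg, "support values must be finite and non-negative")
  if (any(!is.finite(object@weights)) || any(object@weights < 0))
    msg <- c(msg, "weights must be finite and non-negative")
  else if (abs(sum(object@weights) - 1) > .WEIGHT_TOL)
    msg <- c(msg, "weights must sum to 1")
  else if (sum(object@support * object@weights) <= 0)
    msg <- c(msg, "mean of the distribution must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a LambdaDistribution
#'
#' @param support numeric vector of non-negative lambda values (expected
#'   surviving offspring per mother).
#' @param weights non-negative weights, one per support point; normalized to
#'   sum to 1. Defaults to uniform.
#' @return A [LambdaDistribution-class] object.
#' @examples
#' ld <- LambdaDistribution(c(1, 2, 4), c(0.5, 0.3, 0.2))
#' momentRatio(ld)
#' @export
LambdaDistribution <- function(support,
                               weights = rep(1 / length(support), length(support))) {
  support <- as.numeric(support)
  weights <- as.numeric(weights)
  s <- sum(weights)
  if (!is.finite(s) || s <= 0)
    stop("weights must have a positive, finite sum")
  new("LambdaDistribution", support = support, weights = weights / s)
}

#' Degenerate lambda distribution (constant reproductive potential)
#'
#' @param lam positive lambda shared by all mothers.
#' @return A [LambdaDistribution-class] with a single support point, so the
#'   moment ratio is exactly 1 (no parental variation).
#' @export
constantLambda <- function(lam) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be a positive finite number")
  LambdaDistribution(lam, 1)
}

#' Age structure of the mother population
#'
#' Proportions of mothers in each age class, used to build the distribution
#' of reproductive potential when fecundity is age-dependent.
#'
#' @slot ages strictly increasing numeric vector of age classes.
#' @slot proportions probabilities summing to 1, one per age class.
#' @seealso [stableAgeStructure()], [buildLambdaDistribution()]
#' @export
setClass("AgeStructure",
  slots = c(ages = "numeric", proportions = "numeric")
)

setValidity("AgeStructure", function(object) {
  msg <- character()
  if (length(object@ages) != length(object@proportions))
    msg <- c(msg, "ages and proportions must have the same length")
  if (length(object@ages) == 0L)
    msg <- c(msg, "at least one age class is required")
  if (is.unsorted(object@ages, strictly = TRUE))
    msg <- c(msg, "ages must be strictly increasing")
  if (any(!is.finite(object@proportions)) || any(object@proportions < 0))
    msg <- c(msg, "proportions must be finite and non-negative")
  else if (abs(sum(object@proportions) - 1) > .WEIGHT_TOL)
    msg <- c(msg, "proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AgeStructure
#'
#' @param ages strictly increasing numeric vector of age classes.
#' @param proportions non-negative weights, normalized to sum to 1.
#' @return An [AgeStructure-class] object.
#' @export
AgeStructure <- function(ages, proportions) {
  proportions <- as.numeric(proportions)
  s <- sum(proportions)
  if (!is.finite(s) || s <= 0)
    stop("proportions must have a positive, finite sum")
  new("AgeStructure", ages = as.numeric(ages), proportions = proportions / s)
}

#' A within-cohort kinship sample
#'
#' The sufficient data for all estimators in this package: the offspring
#' sample size `n` and the number of maternal half-sibling (MHS) pairs
#' `hObs` observed among the choose(n, 2) pairs. Full-sibling pairs count
#' as MHS pairs.
#'
#' @slot n integer offspring sample size (>= 2).
#' @slot hObs integer observed MHS pair count, between 0 and choose(n, 2).
#' @seealso [SampleObservation()], [estimateNe()], [readKinshipTable()]
#' @export
setClass("SampleObservation",
  slots = c(n = "integer", hObs = "integer")
)

setValidity("SampleObservation", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 2L)
    msg <- c(msg, "n must be a single integer >= 2")
  np <- as.numeric(object@n) * (object@n - 1) / 2
  if (length(object@hObs) != 1L || is.na(object@hObs) ||
      object@hObs < 0L || object@hObs > np)
    msg <- c(msg, "hObs must be a single integer in [0, choose(n, 2)]")
  if (length(msg)) msg else TRUE
})

#' Construct a SampleObservation
#'
#' @param n offspring sample size (integer >= 2).
#' @param hObs observed number of MHS pairs among the choose(n, 2) sample
#'   pairs.
#' @return A [SampleObservation-class] object.
#' @examples
#' obs <- SampleObservation(n = 10, hObs = 4)
#' nPair(obs)
#' @export
SampleObservation <- function(n, hObs) {
  new("SampleObservation", n = as.integer(n), hObs = as.integer(hObs))
}

#' Estimates of effective mother size from one kinship sample
#'
#' Holds the moment estimator, the nearly unbiased (Chapman-type) estimator,
#' its variance and coefficient-of-variation estimates, and the mother-number
#' index (N-1)/c. `ne0` and the moment-based index are `NA` when no MHS pair
#' was observed (the moment estimator is undefined at hObs = 0).
#'
#' @slot n,nPair,hObs the observation the estimates derive from.
#' @slot ne0 moment estimator nPair/hObs (`NA` when hObs = 0).
#' @slot ne1 nearly unbiased estimator (nPair + 1)/(hObs + 1).
#' @slot v variance estimate of `ne1`.
#' @slot cv coefficient-of-variation estimate of `ne1`.
#' @slot index estimate of (N - 1)/c, here ne1 - 1.
#' @seealso [estimateNe()]
#' @export
setClass("NeEstimates",
  slots = c(
    n = "integer", nPair = "numeric", hObs = "integer",
    ne0 = "numeric", ne1 = "numeric", v = "numeric", cv = "numeric",
    index = "numeric"
  )
)

#' A simulated single-cohort pedigree
#'
#' Result of one reproduction event of `N` mothers: each mother's realized
#' reproductive potential and, for every surviving offspring, the index of
#' its mother. Mother identity is what makes MHS pairs traceable.
#'
#' @slot motherLambdas numeric vector of length N, lambda drawn for each
#'   mother.
#' @slot offspringMothers integer vector, one entry per offspring, giving the
#'   mother index in `1:N`.
#' @seealso [simulateCohort()], [sampleOffspring()], [countMhsPairs()]
#' @export
setClass("PedigreeCohort",
  slots = c(motherLambdas = "numeric", offspringMothers = "integer")
)

setValidity("PedigreeCohort", function(object) {
  N <- length(object@motherLambdas)
  if (N < 1L) return("at least one mother is required")
  if (length(object@offspringMothers) &&
      (min(object@offspringMothers) < 1L || max(object@offspringMothers) > N))
    return("offspringMothers indices must lie in 1:N")
  TRUE
})
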