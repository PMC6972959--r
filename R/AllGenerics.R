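#' @rdname LambdaDistribution-class
#' @param x,object a package object.
#' @export
setGeneric("lambdaSupport", function(x) standardGeneric("lambdaSupport"))

#' @rdname LambdaDistribution-class
#' @export
setGeneric("lambdaWeights", function(x) standardGeneric("lambdaWeights"))

#' @rdname LambdaDistribution-class
#' @export
setGeneric("lambdaMean", function(x) standardGeneric("lambdaMean"))

#' @rdname LambdaDistribution-class
#' @export
setGeneric("lambdaSecondMoment", function(x) standardGeneric("lambdaSecondMoment"))

#' Moment ratio E\[lambda^2\]/E\[lambda\]^2 of a lambda distribution
#'
#' The only functional of f(lambda) the MHS-probability model needs. By
#' Cauchy-Schwarz it is >= 1, with equality iff lambda is constant across
#' mothers.
#'
#' @param x a [LambdaDistribution-class].
#' @return numeric >= 1.
#' @export
setGeneric("momentRatio", function(x) standardGeneric("momentRatio"))

#' @rdname SampleObservation-class
#' @param x,object a package object.
#' @export
setGeneric("nPair", function(x) standardGeneric("nPair"))

#' @rdname SampleObservation-class
#' @export
setGeneric("hObs", function(x) standardGeneric("hObs"))

#' @rdname PedigreeCohort-class
#' @param x,object a package object.
#' @export
setGeneric("nMothers", function(x) standardGeneric("nMothers"))

#' @rdname PedigreeCohort-class
#' @export
setGeneric("nOffspring", function(x) standardGeneric("nOffspring"))

#' @rdname PedigreeCohort-class
#' @export
setGeneric("offspringMothers", function(x) standardGeneric("offspringMothers"))

#' Estimate effective mother size from a kinship sample
#'
#' Computes the full set of estimators from (n, hObs): the moment estimator,
#' the nearly unbiased Chapman-type estimator, its variance and CV estimates,
#' and the mother-number index (N-1)/c.
#'
#' @param obs a [SampleObservation-class], or an integer sample size n (with
#'   `hObs` supplied).
#' @param ... passed on to methods.
#' @return A [NeEstimates-class] object.
#' @examples
#' estimateNe(SampleObservation(10, 4))
#' estimateNe(10, hObs = 4)
#' @export
setGeneric("estimateNe", function(obs, ...) standardGeneric("estimateNe"))
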