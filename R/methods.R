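#' @rdname LambdaDistribution-class
#' @export
setMethod("lambdaSupport", "LambdaDistribution", function(x) x@support)

#' @rdname LambdaDistribution-class
#' @export
setMethod("lambdaWeights", "LambdaDistribution", function(x) x@weights)

#' @rdname LambdaDistribution-class
#' @export
setMethod("lambdaMean", "LambdaDistribution", function(x)
  sum(x@support * x@weights))

#' @rdname LambdaDistribution-class
#' @export
setMethod("lambdaSecondMoment", "LambdaDistribution", function(x)
  sum(x@support^2 * x@weights))

#' @rdname momentRatio
#' @export
setMethod("momentRatio", "LambdaDistribution", function(x)
  lambdaSecondMoment(x) / lambdaMean(x)^2)

setMethod("show", "LambdaDistribution", function(object) {
  cat("LambdaDistribution with", length(object@support), "support point(s)\n")
  cat(sprintf("  E[lambda] = %.6g, E[lambda^2]/E[lambda]^2 = %.6g\n",
              lambdaMean(object), momentRatio(object)))
  k <- min(length(object@support), 6L)
  cat("  support:", paste(signif(object@support[seq_len(k)], 4), collapse = " "),
      if (length(object@support) > k) "...\n" else "\n")
})

setMethod("show", "AgeStructure", function(object) {
  cat("AgeStructure with", length(object@ages), "age class(es),",
      sprintf("ages %g-%g\n", min(object@ages), max(object@ages)))
})

#' @rdname SampleObservation-class
#' @export
setMethod("nPair", "SampleObservation", function(x)
  as.numeric(x@n) * (as.numeric(x@n) - 1) / 2)

#' @rdname SampleObservation-class
#' @export
setMethod("hObs", "SampleObservation", function(x) x@hObs)

setMethod("show", "SampleObservation", function(object) {
  cat(sprintf("SampleObservation: n = %d offspring, %g pairs, H_obs = %d MHS pair(s)\n",
              object@n, nPair(object), object@hObs))
})

setMethod("show", "NeEstimates", function(object) {
  cat("Effective mother size estimates",
      sprintf("(n = %d, H_obs = %d):\n", object@n, object@hObs))
  cat(sprintf("  Ne (nearly unbiased) : %.4g\n", object@ne1))
  cat(sprintf("  Ne (moment)          : %s\n",
              if (is.na(object@ne0)) "undefined (H_obs = 0)" else
                sprintf("%.4g", object@ne0)))
  cat(sprintf("  variance estimate    : %.4g\n", object@v))
  cat(sprintf("  CV estimate          : %.4g\n", object@cv))
  cat(sprintf("  index (N-1)/c        : %.4g\n", object@index))
})

#' Coerce NeEstimates to a one-row data.frame
#'
#' @param x a [NeEstimates-class].
#' @param ... unused.
#' @return data.frame with columns n, nPair, hObs, ne0, ne1, v, cv, index.
#' @export
as.data.frame.NeEstimates <- function(x, ...) {
  data.frame(n = x@n, nPair = x@nPair, hObs = x@hObs, ne0 = x@ne0,
             ne1 = x@ne1, v = x@v, cv = x@cv, index = x@index)
}

#' @rdname PedigreeCohort-class
#' @export
setMethod("nMothers", "PedigreeCohort", function(x) length(x@motherLambdas))

#' @rdname PedigreeCohort-class
#' @export
setMethod("nOffspring", "PedigreeCohort", function(x) length(x@offspringMothers))

#' @rdname PedigreeCohort-class
#' @export
setMethod("offspringMothers", "PedigreeCohort", function(x) x@offspringMothers)

setMethod("show", "PedigreeCohort", function(object) {
  cat(sprintf("PedigreeCohort: %d mothers, %d surviving offspring\n",
              nMothers(object), nOffspring(object)))
})
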