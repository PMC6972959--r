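# Wright-Fisher drift and temporal (Nei-Tajima) Ne estimation, used as the
# comparator method in the validation experiments.

# one generation of multinomial resampling for all loci at once, via the
# conditional-binomial decomposition (vectorized across loci)
.wfStep <- function(cnt, ne) {
  L <- nrow(cnt)
  A <- ncol(cnt)
  out <- matrix(0L, L, A)
  rem <- rep.int(as.integer(ne), L)
  prem <- rep(1, L)
  p <- cnt / ne
  for (a in seq_len(A - 1L)) {
    pa <- ifelse(prem > 0, pmin(pmax(p[, a] / prem, 0), 1), 0)
    x <- stats::rbinom(L, rem, pa)
    out[, a] <- x
    rem <- rem - x
    prem <- prem - p[, a]
  }
  out[, A] <- rem
  out
}

# multivariate hypergeometric draw of n gene copies per locus (vectorized)
.mvHyper <- function(cnt, n) {
  L <- nrow(cnt)
  A <- ncol(cnt)
  out <- matrix(0L, L, A)
  remDraw <- rep.int(as.integer(n), L)
  remPop <- rowSums(cnt)
  for (a in seq_len(A - 1L)) {
    x <- stats::rhyper(L, cnt[, a], remPop - cnt[, a], remDraw)
    out[, a] <- x
    remDraw <- remDraw - x
    remPop <- remPop - cnt[, a]
  }
  out[, A] <- remDraw
  out
}

#' Simulate Wright-Fisher allele-frequency trajectories
#'
#' Haploid Wright-Fisher drift: each generation, the `ne` gene copies at each
#' locus are resampled multinomially from the previous generation's
#' frequencies, independently across loci (no linkage).
#'
#' @param ne integer haploid population size.
#' @param nGen number of generations to simulate.
#' @param nLoci number of independent loci (default 500).
#' @param nAlleles alleles per locus (default 10); `ne * initFreq` copies of
#'   each allele initially, so `nAlleles * initFreq` must equal 1.
#' @param initFreq initial frequency of every allele (default 0.1).
#' @return integer array `[nGen + 1, nLoci, nAlleles]` of allele copy
#'   numbers; slice 1 is generation 0.
#' @examples
#' set.seed(1)
#' traj <- simulateWrightFisher(100, nGen = 9, nLoci = 20)
#' dim(traj)
#' @export
simulateWrightFisher <- function(ne, nGen, nLoci = 500, nAlleles = 10,
                                 initFreq = 1 / nAlleles) {
  if (abs(nAlleles * initFreq - 1) > 1e-12)
    stop("nAlleles * initFreq must equal 1")
  init <- ne * initFreq
  if (abs(init - round(init)) > 1e-9)
    stop("ne * initFreq must be an integer copy number")
  traj <- array(0L, c(nGen + 1L, nLoci, nAlleles))
  cnt <- matrix(as.integer(round(init)), nLoci, nAlleles)
  traj[1L, , ] <- cnt
  for (g in seq_len(nGen)) {
    cnt <- .wfStep(cnt, ne)
    traj[g + 1L, , ] <- cnt
  }
  traj
}

#' Draw temporal samples from simulated trajectories
#'
#' Takes a sample of `n` individuals (gene copies, haploid) without
#' replacement from the population at two generations, per locus
#' (multivariate hypergeometric).
#'
#' @param trajectories array from [simulateWrightFisher()].
#' @param n sample size per time point; must not exceed the population size.
#' @param genFirst,genSecond generations at which to sample (default 0 and
#'   the last simulated generation).
#' @return list of two `nLoci x nAlleles` sample frequency matrices, `x`
#'   (first) and `y` (second).
#' @export
sampleTemporal <- function(trajectories, n, genFirst = 0,
                           genSecond = dim(trajectories)[1] - 1) {
  ne <- sum(trajectories[1, 1, ])
  if (n > ne) stop("sample size exceeds population size")
  g1 <- trajectories[genFirst + 1L, , , drop = FALSE]
  g2 <- trajectories[genSecond + 1L, , , drop = FALSE]
  dim(g1) <- dim(g2) <- dim(trajectories)[2:3]
  list(x = .mvHyper(g1, n) / n, y = .mvHyper(g2, n) / n)
}

#' Standardized variance of temporal allele-frequency change (Fc)
#'
#' Nei-Tajima Fc: per allele, `(x - y)^2 / ((x + y)/2 - x*y)`. Alleles absent
#' from both samples, and shared-fixed alleles (zero denominator), are
#' excluded. With `method = "locus"` (default) the retained per-allele terms
#' are averaged within each locus and the locus values averaged unweighted;
#' `method = "pooled"` averages all retained allele terms across loci in one
#' pool (equivalent to weighting loci by retained allele count).
#'
#' @param x,y sample allele-frequency matrices (loci x alleles), rows summing
#'   to 1, or numeric vectors for a single locus.
#' @param method `"locus"` or `"pooled"`.
#' @return numeric Fc; `NA` if every allele is excluded.
#' @examples
#' fStatistic(c(0.5, 0.5), c(0.6, 0.4)) # 0.04
#' @export
fStatistic <- function(x, y, method = c("locus", "pooled")) {
  method <- match.arg(method)
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(y))) y <- matrix(y, 1)
  stopifnot(identical(dim(x), dim(y)))
  num <- (x - y)^2
  den <- (x + y) / 2 - x * y
  keep <- (x + y) > 0 & den > 0
  if (!any(keep)) return(NA_real_)
  if (method == "pooled")
    return(sum(num[keep] / den[keep]) / sum(keep))
  ratio <- matrix(0, nrow(x), ncol(x))
  ratio[keep] <- num[keep] / den[keep]
  perLocus <- rowSums(ratio) / rowSums(keep)
  mean(perLocus[rowSums(keep) > 0])
}

#' Temporal-method moment estimator of effective size
#'
#' Haploid Nei-Tajima moment estimator
#' `ne = t / (f - 1/s0 - 1/st + 1/censusN)`; the `1/censusN` term is the
#' plan-I correction for sampling without replacement from a census of known
#' size and is dropped when `censusN = NULL` (plan II). `ploidy = "diploid"`
#' uses `t / (2 (f - 1/(2 s0) - 1/(2 st) + 1/censusN))` with sample sizes in
#' individuals. Negative estimates (sampling noise exceeding drift signal)
#' are returned as-is; an exactly zero denominator gives `NA_real_`.
#'
#' @param f temporal F statistic, see [fStatistic()].
#' @param t generations elapsed between the two samples.
#' @param s0,st sample sizes at the first and second time point.
#' @param censusN census size for the plan-I correction, or `NULL`.
#' @param ploidy `"haploid"` (default) or `"diploid"`.
#' @return numeric estimate (possibly negative), or `NA_real_`.
#' @examples
#' neTemporal(0.1, t = 9, s0 = 50, st = 50) # 150
#' @export
neTemporal <- function(f, t, s0, st, censusN = NULL,
                       ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (t < 1) stop("t must be >= 1")
  if (s0 < 1 || st < 1) stop("sample sizes must be >= 1")
  corr <- if (is.null(censusN)) 0 else 1 / censusN
  den <- if (ploidy == "haploid") f - 1 / s0 - 1 / st + corr
         else 2 * (f - 1 / (2 * s0) - 1 / (2 * st) + corr)
  ifelse(den == 0, NA_real_, t / den)
}

#' Run a temporal-method simulation experiment
#'
#' For each replicate: simulate haploid Wright-Fisher drift at `nLoci`
#' independent loci, sample `sampleSize` individuals without replacement at
#' generations `genFirst` and `genSecond`, compute the Fc statistic across
#' loci, and convert it to an Ne estimate with [neTemporal()]. The default
#' estimator variant is the haploid plan-I form (census correction `1/ne`,
#' elapsed time `genSecond - genFirst`, locus-averaged Fc); all pieces are
#' configurable for sensitivity analysis.
#'
#' @param ne true haploid population size.
#' @param sampleSize individuals sampled per time point.
#' @param nReplicates number of independent replicates.
#' @param nLoci,nAlleles,initFreq see [simulateWrightFisher()].
#' @param genFirst,genSecond sampling generations (defaults 0 and 9).
#' @param tElapsed generations assumed elapsed in the estimator (default
#'   `genSecond - genFirst`).
#' @param fMethod Fc averaging, `"locus"` or `"pooled"`.
#' @param correction finite-population correction applied with the sampling
#'   terms: `"planI"` (default) subtracts `1/s0 + 1/st - 1/ne`, the
#'   classical Nei-Tajima plan-I form for sampling without replacement;
#'   `"bothEnds"` subtracts `1/s0 + 1/st - 2/ne`, matching a scheme in which
#'   both samples are hypergeometric draws from the standing population
#'   (each sample's variance carries its own finite-population factor), and
#'   gives the best parameter recovery under this simulator; `"none"`
#'   subtracts only `1/s0 + 1/st` (with-replacement sampling assumed).
#' @param seed integer root seed.
#' @return list with `summary` (named list: `meanNeTm`, `medianNeTm`,
#'   `ciLow`, `ciHigh` (2.5/97.5 percentiles), `negativeRate`, `naRate`,
#'   `meanF`, `nReplicates`, `seed`), `replicates` (data.frame with `fStat`,
#'   `neTm`, `status`), and `config`.
#' @examples
#' res <- runTemporalExperiment(100, sampleSize = 5, nReplicates = 20,
#'                              nLoci = 50, seed = 1)
#' res$summary$meanNeTm
#' @export
runTemporalExperiment <- function(ne, sampleSize, nReplicates,
                                  nLoci = 500, nAlleles = 10,
                                  initFreq = 1 / nAlleles,
                                  genFirst = 0, genSecond = 9,
                                  tElapsed = genSecond - genFirst,
                                  fMethod = c("locus", "pooled"),
                                  correction = c("planI", "bothEnds", "none"),
                                  seed = NULL) {
  fMethod <- match.arg(fMethod)
  correction <- match.arg(correction)
  if (!is.null(seed)) set.seed(seed)
  fs <- numeric(nReplicates)
  for (r in seq_len(nReplicates)) {
    traj <- simulateWrightFisher(ne, nGen = genSecond, nLoci = nLoci,
                                 nAlleles = nAlleles, initFreq = initFreq)
    sm <- sampleTemporal(traj, sampleSize, genFirst, genSecond)
    fs[r] <- fStatistic(sm$x, sm$y, method = fMethod)
  }
  censusN <- switch(correction, planI = ne, bothEnds = ne / 2, none = NULL)
  netm <- neTemporal(fs, t = tElapsed, s0 = sampleSize, st = sampleSize,
                     censusN = censusN)
  status <- ifelse(is.na(netm), "undefined",
                   ifelse(netm < 0, "negative", "ok"))
  ci <- stats::quantile(netm, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  summary <- list(
    meanNeTm = mean(netm, na.rm = TRUE),
    medianNeTm = stats::median(netm, na.rm = TRUE),
    ciLow = ci[1], ciHigh = ci[2],
    negativeRate = mean(netm < 0, na.rm = TRUE),
    naRate = mean(is.na(netm)),
    meanF = mean(fs, na.rm = TRUE),
    nReplicates = nReplicates, seed = seed)
  structure(list(summary = summary,
                 replicates = data.frame(fStat = fs, neTm = netm,
                                         status = status),
                 config = list(ne = ne, sampleSize = sampleSize,
                               nReplicates = nReplicates, nLoci = nLoci,
                               nAlleles = nAlleles, initFreq = initFreq,
                               genFirst = genFirst, genSecond = genSecond,
                               tElapsed = tElapsed, fMethod = fMethod,
                               correction = correction, seed = seed)),
            class = "tmExperiment")
}

#' @export
print.tmExperiment <- function(x, ...) {
  s <- x$summary
  cat("Temporal-method experiment:", s$nReplicates, "replicates\n")
  cat(sprintf("  mean NeTM = %.4g, median = %.4g [%.4g, %.4g]\n",
              s$meanNeTm, s$medianNeTm, s$ciLow, s$ciHigh))
  cat(sprintf("  negative rate = %.3f, undefined rate = %.3f\n",
              s$negativeRate, s$naRate))
  invisible(x)
}
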