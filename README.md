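# halfsibNe

Estimation of contemporary **effective mother size** (N<sub>e</sub>) from
the number of maternal half-sibling (MHS) pairs found among offspring
sampled from a single cohort.

## The problem and who this is for

Genomic data now make sibship assignment essentially error-free, which turns
a simple count — how many of the `choose(n, 2)` pairs in a sample of `n`
same-cohort offspring share a mother — into an estimator of effective
population size. This is aimed at conservation geneticists and fisheries
scientists working with high-fecundity species (teleosts in particular),
where reproductive skew makes classical N<sub>e</sub> estimators unreliable
and N<sub>e</sub>/N can be orders of magnitude below 1.

## The model and estimator

Mother *i* leaves a negative-binomially distributed number of surviving
offspring with mean λ<sub>i</sub> (her reproductive potential, distributed
as f(λ) across mothers) and overdispersion φ (family-correlated survival;
φ = ∞ is Poisson). Both deviations from equal Poisson reproduction combine
into one parameter

> c = (1 + 1/φ) · E[λ²]/E[λ]²  (c ≥ 1),

the probability that two random same-cohort offspring are maternal half-sibs
is π ≈ c/(N + c − 1), and the effective mother size is its reciprocal:

> N<sub>e</sub> = 1/π = (N − 1)/c + 1,  so N<sub>e</sub>/N ≈ 1/c.

With `n_pair = n(n−1)/2` and `H_obs` observed MHS pairs (full-sib pairs
count as MHS), the package's central estimator is the Chapman-type

> N̂<sub>e,1</sub> = (n_pair + 1)/(H_obs + 1),

with exact binomial-model bias b<sub>mean</sub> = −N<sub>e</sub>(1 −
1/N<sub>e</sub>)<sup>n_pair+1</sup>, a closed-form variance estimator
v̂ = (n_pair+1)(n_pair−H_obs)/((H_obs+1)²(H_obs+2)) and CV estimator
ĉv = √((n_pair−H_obs)/((n_pair+1)(H_obs+2))) ≈ √(1/(H_obs+2)). Inverting
b<sub>mean</sub> answers the design question "how many offspring for <10%
bias?" — 22, 69 and 216 for N<sub>e</sub> = 100, 1000, 10000.

Also included: an age-structured fecundity model (von Bertalanffy
weight-proportional fecundity over a stable age structure) to build f(λ),
an individual-based pedigree simulator that validates the estimators, and a
Wright–Fisher temporal-method (Nei–Tajima) comparator.

## Worked example

Suppose you sample 50 offspring from one cohort and sibship assignment finds
11 MHS pairs among the 1225 pairs:

```r
library(halfsibNe)
estimateNe(SampleObservation(n = 50, hObs = 11))
#> Effective mother size estimates (n = 50, H_obs = 11):
#>   Ne (nearly unbiased) : 102.2
#>   Ne (moment)          : 111.4
#>   variance estimate    : 795.1
#>   CV estimate          : 0.276
#>   index (N-1)/c        : 101.2
```

About 102 effective mothers, with a ~28% coefficient of variation (set
almost entirely by the 11 pairs found, not by n); the uncorrected moment
estimate (1225/11 ≈ 111) is visibly higher — the add-one correction removes
most of its small-sample bias. The index (N−1)/c tracks trends in mother
number across years when c is stable, even though N and c are not separately
identifiable.

The same numbers arise from a kinship table
(`readKinshipTable("pairs.tsv")`) with columns `offspring_id`/`mother_id`,
or via the CLI: `Rscript inst/cli/halfsibne.R estimate --n 50 --hobs 11`.

Validating the estimator against a simulated pedigree with known truth
(N = 100 mothers, Poisson reproduction, mean 4.5 offspring each):

```r
runExperiment(N = 100, phi = Inf, lambdaDist = constantLambda(4.5),
              n = 50, nHistories = 10, nSamplingsPerHistory = 100, seed = 1)
#> Pedigree-simulation experiment: 1000 replicates (0 skipped)
#>   true Ne = 100 (c = 1), mean Ne1 = 98.36 [58.38, 153.2]
#>   ratio mean(v)/Var(Ne1) = 1.204, ratio mean(cv)/CV = 0.982
```

The estimator mean lands on the true N<sub>e</sub> = 100 (the analytic bias
at n = 50 is negligible, −0.0004), and the bracket is the 2.5–97.5
percentile range of the 1000 replicate estimates. See the vignette
(`vignettes/effective-mother-size.Rmd`) for the model assumptions, the
variance-ratio behavior, and the temporal-method sensitivity analysis.

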