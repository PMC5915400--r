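#' Binomial upper limit of a mutation rate from a negative screen
#'
#' With `N` spores screened and zero switcher colonies observed, the largest
#' rate still compatible with the data at level `alpha` is the root of
#' `P(K = 0 | N, mu) = (1 - mu)^N = alpha`, i.e. `mu = 1 - alpha^(1/N)`.
#' The Poisson zero-class approximation `-log(alpha) / N` is returned
#' alongside; for a screen of a million spores at `alpha = 0.05` both round
#' to 3e-6.
#'
#' @param nScreened number of spores screened (>= 1).
#' @param nEvents observed mutant colonies; must be 0 (a positive count needs
#'   a likelihood-based estimator, which this package does not provide).
#' @param alpha significance level in (0, 1).
#' @return list with `muMax` (exact), `muMaxPoisson`, and the inputs.
#' @examples
#' binomialUpperLimit(1e6)$muMax  # ~3e-6
#' @export
binomialUpperLimit <- function(nScreened, nEvents = 0, alpha = 0.05) {
  if (nScreened < 1) stop("nScreened must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (nEvents > 0)
    stop("events were observed: the zero-class bound does not apply; ",
         "use a likelihood-based rate estimator")
  list(muMax = 1 - alpha^(1 / nScreened),
       muMaxPoisson = -log(alpha) / nScreened,
       nScreened = nScreened, alpha = alpha)
}

#' Event-count lower bound on a mutation rate
#'
#' `rate = events / (generations x populations x opportunities per
#' generation)`; e.g. nine fixation events over 25 sexual generations in 20
#' populations of 2.5 million crossover opportunities give 7.2e-9 per sexual
#' generation.
#'
#' @param nEvents observed mutation/fixation events.
#' @param nGenerations sexual generations per population.
#' @param nPopulations number of replicate populations.
#' @param nOpportunities mutational opportunities per generation (e.g.
#'   potential crossing-overs).
#' @return list with `rate` and the inputs.
#' @export
rateLowerBound <- function(nEvents, nGenerations, nPopulations,
                           nOpportunities) {
  denom <- nGenerations * nPopulations * nOpportunities
  if (denom <= 0) stop("denominator product must be positive")
  if (nEvents == 0)
    warning("zero events: the result is 0 and is not a lower bound")
  list(rate = nEvents / denom, nEvents = nEvents,
       nGenerations = nGenerations, nPopulations = nPopulations,
       nOpportunities = nOpportunities)
}

#' Correct a rate for loss of new genotypes in a bottleneck
#'
#' A new genotype present once can be lost when the population is subsampled;
#' dividing by the survival probability gives
#' `corrected = rate / (1 - lossProbability)`.
#'
#' @param rate uncorrected rate.
#' @param lossProbability probability a new genotype is lost, in [0, 1).
#' @return list with `corrected`, `rate`, `lossProbability`.
#' @examples
#' lossCorrectedRate(7.2e-9, 0.37)$corrected  # ~1.14e-8
#' @export
lossCorrectedRate <- function(rate, lossProbability) {
  if (lossProbability < 0 || lossProbability >= 1)
    stop("lossProbability must be in [0, 1)")
  list(corrected = rate / (1 - lossProbability), rate = rate,
       lossProbability = lossProbability)
}

#' Probability that a rare genotype is missed in a subsample
#'
#' Exact binomial zero-class probability `(1 - f)^n` of drawing no copy of a
#' genotype at frequency `f` in a subsample of `n` cells, with the Poisson
#' approximation `exp(-n f)`. When `n * f = 1` both are close to `exp(-1)`,
#' about 0.37.
#'
#' @param nSampled subsample size (>= 1).
#' @param mutantFrequency genotype frequency in (0, 1).
#' @return list with `exact`, `poisson`, and the inputs.
#' @export
subsampleLossProbability <- function(nSampled, mutantFrequency) {
  if (nSampled < 1) stop("nSampled must be >= 1")
  if (mutantFrequency < 0 || mutantFrequency >= 1)
    stop("mutantFrequency must be in [0, 1)")
  list(exact = (1 - mutantFrequency)^nSampled,
       poisson = exp(-nSampled * mutantFrequency),
       nSampled = nSampled, mutantFrequency = mutantFrequency)
}

#' Independent asci represented in a spore subsample
#'
#' Spores are pooled from `nAsci` asci of `sporesPerAscus` spores each and
#' `nSporesSampled` spores are drawn without replacement. The number of
#' distinct asci contributing at least one sampled spore is estimated by
#' Monte-Carlo over `nReplicates` samplings and, alongside, by the
#' hypergeometric closed form
#' `nAsci * (1 - choose(T - m, k) / choose(T, k))` with `T` total spores,
#' `m = sporesPerAscus` and `k` the sample size.
#'
#' @param nAsci number of asci in the pool.
#' @param nSporesSampled spores drawn (at most `nAsci * sporesPerAscus`).
#' @param sporesPerAscus spores per ascus (default 4, a zygotic ascus).
#' @param nReplicates Monte-Carlo replicate samplings (default 1000).
#' @return list with `mcMean`, `mcSd`, `closedForm`, and the inputs.
#' @examples
#' independentAsci(nAsci = 20, nSporesSampled = 8, nReplicates = 50)
#' @export
independentAsci <- function(nAsci, nSporesSampled, sporesPerAscus = 4,
                            nReplicates = 1000) {
  total <- nAsci * sporesPerAscus
  if (nSporesSampled > total)
    stop("cannot sample more spores than the pool contains")
  if (nSporesSampled < 1) stop("nSporesSampled must be >= 1")
  # closed form: P(an ascus contributes no spore) = C(T-m, k) / C(T, k)
  i <- seq_len(sporesPerAscus) - 1
  pMiss <- prod((total - nSporesSampled - i) / (total - i))
  closedForm <- nAsci * (1 - pMiss)
  counts <- vapply(seq_len(nReplicates), function(r) {
    spores <- sample.int(total, nSporesSampled)
    length(unique((spores - 1L) %/% as.integer(sporesPerAscus)))
  }, numeric(1))
  list(mcMean = mean(counts), mcSd = sd(counts), closedForm = closedForm,
       nAsci = nAsci, sporesPerAscus = sporesPerAscus,
       nSporesSampled = nSporesSampled, nReplicates = nReplicates)
}

#' Plating density
#'
#' Cells spread over a circular plate: `nCells / (pi * (d/2)^2)` in cells per
#' square millimetre. Five million cells on a 4.5 cm plate are about 3.1e3
#' cells per mm^2.
#'
#' @param nCells number of cells plated.
#' @param plateDiameterCm plate diameter in centimetres.
#' @return cells per mm^2.
#' @export
platingDensity <- function(nCells, plateDiameterCm) {
  if (plateDiameterCm <= 0) stop("plate diameter must be positive")
  nCells / (pi * (plateDiameterCm * 10 / 2)^2)
}
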