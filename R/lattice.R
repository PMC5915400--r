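#' Seed an empty lattice with founder cells
#'
#' Populates `round(density * sideLength^2)` uniformly random sites. Each
#' founder is independently a switcher with probability `switcherFreq`, mating
#' type P with probability 1/2 (Mendelian segregation at the mating-type
#' locus), and — if a switcher — in the will-switch phase with probability
#' 1/2. Every founder receives a unique clone id; intraclonal-origin flags are
#' drawn per strategy from `intraclonalFracs`.
#'
#' Uses the current RNG state; call `set.seed()` (or [runSimulation()], which
#' seeds from its parameters) for reproducibility.
#'
#' @param params a [SimParams-class] object.
#' @param switcherFreq founder switcher probability; defaults to
#'   `initialSwitcherFreq` of `params`.
#' @param intraclonalFracs named numeric `c(switcher =, nonswitcher =)` giving
#'   the probability that a founder of each strategy derives from an
#'   intraclonal zygote.
#' @return A [Lattice-class] object.
#' @examples
#' set.seed(1)
#' lat <- seedGrid(SimParams(sideLength = 50, density = 0.01))
#' occupancy(lat)  # round(0.01 * 2500) = 25 founders
#' @export
seedGrid <- function(params, switcherFreq = params@initialSwitcherFreq,
                     intraclonalFracs = c(switcher = 0, nonswitcher = 0)) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  if (switcherFreq < 0 || switcherFreq > 1)
    stop("switcherFreq must be in [0, 1]")
  L <- params@sideLength
  N <- L * L
  n <- round(params@density * N)
  if (n < 2)
    stop("configuration error: density seeds fewer than 2 founders")
  sites <- sample.int(N, n)
  strat <- ifelse(runif(n) < switcherFreq, .ST_SWITCHER, .ST_NONSWITCHER)
  type <- ifelse(runif(n) < 0.5, .MT_P, .MT_M)
  phase <- ifelse(strat == .ST_SWITCHER,
                  ifelse(runif(n) < 0.5, .PH_WILL, .PH_WONT), .PH_NA)
  pIntra <- ifelse(strat == .ST_SWITCHER,
                   intraclonalFracs[["switcher"]],
                   intraclonalFracs[["nonswitcher"]])
  intra <- as.integer(runif(n) < pIntra)

  z <- function() matrix(0L, L, L)
  mt <- z(); st <- z(); ph <- z(); cl <- z(); ic <- z()
  mt[sites] <- as.integer(type)
  st[sites] <- as.integer(strat)
  ph[sites] <- as.integer(phase)
  cl[sites] <- seq_len(n)
  ic[sites] <- intra
  new("Lattice", matingType = mt, strategy = st, switchPhase = ph,
      cloneId = cl, intraclonal = ic, mated = z(),
      boundary = params@boundary)
}

.growParams <- function(lattice, params) {
  list(R = params@growthChance, s = params@switchingCost,
       c = params@intraclonalCost, torus = lattice@boundary == "torus",
       bern = params@pedigree == "bernoulli")
}

.latticeFromCpp <- function(res, boundary) {
  lat <- new("Lattice", matingType = res$matingType, strategy = res$strategy,
             switchPhase = res$switchPhase, cloneId = res$cloneId,
             intraclonal = res$intraclonal,
             mated = matrix(0L, nrow(res$matingType), ncol(res$matingType)),
             boundary = boundary)
  attr(lat, "rounds") <- res$rounds
  attr(lat, "filled") <- res$filled
  attr(lat, "divisions") <- res$divisions
  lat
}

#' One asexual growth round
#'
#' Visits the currently occupied sites in a fresh uniformly random order; a
#' cell with at least one empty Moore neighbour divides with probability
#' `R * (1 - s)` for switchers, `R` for non-switchers, additionally scaled by
#' the intraclonal cost `c` for intraclonal-origin cells. Division follows the
#' switching pedigree: a will-switch mother yields exactly one cell of the
#' opposite mating type (set won't-switch) while the other keeps the type and
#' stays competent; a won't-switch mother yields one newly competent cell.
#' Non-switchers never change mating type. Occupancy never decreases.
#'
#' @inheritParams seedGrid
#' @param lattice a [Lattice-class] object.
#' @return The updated [Lattice-class]; attribute `"divisions"` counts the
#'   divisions performed.
#' @export
growthRound <- function(lattice, params) {
  if (occupancy(lattice) < 1) stop("growth requires an occupied site")
  g <- .growParams(lattice, params)
  res <- cpp_grow(lattice@matingType, lattice@strategy, lattice@switchPhase,
                  lattice@cloneId, lattice@intraclonal,
                  g$R, g$s, g$c, g$torus, 1, Inf, g$bern)
  .latticeFromCpp(res, lattice@boundary)
}

#' Run asexual growth until the lattice is full
#'
#' Repeats [growthRound()] until no empty site remains (or, if
#' `maxRounds` is finite, for at most that many rounds — the truncated-growth
#' knob used to study how sexual-cycle frequency affects fixation speed).
#'
#' @inheritParams growthRound
#' @param maxRounds growth rounds allowed; defaults to
#'   `params@maxGrowthRounds`.
#' @return The grown [Lattice-class]; attributes `"rounds"` (rounds used) and
#'   `"filled"`.
#' @examples
#' p <- SimParams(sideLength = 10, density = 0.02, seed = 7)
#' set.seed(7)
#' lat <- seedGrid(p, switcherFreq = 0)  # 2 founders
#' full <- runGrowth(lat, p)
#' occupancy(full)  # 100
#' @export
runGrowth <- function(lattice, params, maxRounds = params@maxGrowthRounds) {
  if (occupancy(lattice) < 1) stop("growth requires an occupied site")
  g <- .growParams(lattice, params)
  cap <- params@sideLength^2 * 1000
  res <- cpp_grow(lattice@matingType, lattice@strategy, lattice@switchPhase,
                  lattice@cloneId, lattice@intraclonal,
                  g$R, g$s, g$c, g$torus, maxRounds, cap, g$bern)
  if (!res$filled && !is.finite(maxRounds))
    stop("growth did not fill the grid")
  .latticeFromCpp(res, lattice@boundary)
}

#' One mating round
#'
#' Unmated cells are visited in a uniformly random order and each mates with a
#' uniformly chosen eligible partner: an unmated opposite-mating-type Moore
#' neighbour in `"moore"` mode, or any unmated opposite-type cell in
#' `"global"` mode. The round repeats until no eligible pair remains.
#' Eligibility ignores strategy and clone identity — mating within a clone is
#' allowed, and is exactly what distinguishes switcher clones.
#'
#' @inheritParams growthRound
#' @param requireFull error if the grid is not fully occupied (the default;
#'   set `FALSE` when growth was truncated via `maxGrowthRounds`).
#' @return A [MatingOutcome-class] with the zygote table and mated matrix.
#' @export
matingRound <- function(lattice, params, requireFull = TRUE) {
  occ <- occupancy(lattice)
  if (requireFull && occ < length(lattice@matingType))
    stop("mating requires a fully occupied grid")
  res <- cpp_mate(lattice@matingType, lattice@strategy, lattice@cloneId,
                  params@matingMode == "global",
                  lattice@boundary == "torus")
  z <- data.frame(siteA = res$siteA, siteB = res$siteB,
                  strategyA = res$strategyA, strategyB = res$strategyB,
                  cloneA = res$cloneA, cloneB = res$cloneB,
                  intraclonal = res$intraclonal)
  new("MatingOutcome", zygotes = z, mated = res$mated,
      nOccupied = as.integer(occ))
}

#' Gamete pool for the next transfer
#'
#' Assuming Mendelian segregation at the switching locus, a switcher-by-
#' switcher zygote contributes only switcher gametes, a heterozygous zygote
#' half switcher and half non-switcher gametes, so the new switcher frequency
#' is `(2 n_SWxSW + n_SWxNS) / (2 n_zygotes)`. Intraclonal-origin fractions
#' for the next founders are computed per strategy with the same gamete
#' weighting.
#'
#' @param outcome a [MatingOutcome-class].
#' @return list with `switcherFreq` and `intraclonalFracs` (named
#'   `c(switcher =, nonswitcher =)`).
#' @examples
#' # 3 SWxSW + 1 NSxNS zygotes: switcher frequency (6 + 0) / 8 = 0.75
#' z <- data.frame(siteA = 1:4, siteB = 5:8,
#'                 strategyA = c(1L, 1L, 1L, 2L), strategyB = c(1L, 1L, 1L, 2L),
#'                 cloneA = 1:4, cloneB = 5:8, intraclonal = FALSE)
#' out <- new("MatingOutcome", zygotes = z,
#'            mated = matrix(0L, 3, 3), nOccupied = 9L)
#' nextFounderPool(out)$switcherFreq
#' @export
nextFounderPool <- function(outcome) {
  z <- zygotes(outcome)
  if (nrow(z) == 0)
    stop(structure(class = c("switchsim_extinction", "error", "condition"),
                   list(message = "no zygotes: population extinct",
                        call = sys.call())))
  nSwParents <- (z$strategyA == .ST_SWITCHER) + (z$strategyB == .ST_SWITCHER)
  # gamete weights per zygote and strategy
  wSw <- nSwParents          # 0, 1 or 2 switcher gametes out of 2
  wNs <- 2 - nSwParents
  switcherFreq <- sum(wSw) / (2 * nrow(z))
  fr <- function(w) if (sum(w) == 0) 0 else sum(w * z$intraclonal) / sum(w)
  list(switcherFreq = switcherFreq,
       intraclonalFracs = c(switcher = fr(wSw), nonswitcher = fr(wNs)))
}

#' Mated fraction by strategy
#'
#' @param lattice the [Lattice-class] that was mated.
#' @param outcome the corresponding [MatingOutcome-class].
#' @return named numeric `c(switcher =, nonswitcher =)`; `NaN` for an absent
#'   strategy.
#' @export
matedFractions <- function(lattice, outcome) {
  st <- lattice@strategy
  m <- matedMatrix(outcome)
  c(switcher = sum(m[st == .ST_SWITCHER]) / sum(st == .ST_SWITCHER),
    nonswitcher = sum(m[st == .ST_NONSWITCHER]) / sum(st == .ST_NONSWITCHER))
}

#' Integer-coded snapshot of a lattice
#'
#' @param lattice a [Lattice-class].
#' @return integer matrix coded 0 empty, 1 P switcher, 2 M switcher,
#'   3 P non-switcher, 4 M non-switcher.
#' @seealso [writeGridSnapshot()], [plotLattice()].
#' @export
gridCodes <- function(lattice) {
  mt <- lattice@matingType
  st <- lattice@strategy
  out <- matrix(0L, nrow(mt), ncol(mt))
  out[mt == .MT_P & st == .ST_SWITCHER] <- 1L
  out[mt == .MT_M & st == .ST_SWITCHER] <- 2L
  out[mt == .MT_P & st == .ST_NONSWITCHER] <- 3L
  out[mt == .MT_M & st == .ST_NONSWITCHER] <- 4L
  out
}
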