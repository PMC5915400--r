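#' Simulation parameters
#'
#' Full parameterization of one lattice simulation: grid geometry, seeding
#' density, per-round growth chance, selection against switchers, intraclonal
#' mating cost, mating mode, transfer cap and RNG seed.
#'
#' @slot sideLength integer, lattice side length (default 200, so 40,000 sites).
#' @slot boundary `"bounded"` (edges are walls) or `"torus"` (wrap-around).
#' @slot density fraction of sites seeded at the start of each growth phase,
#'   in (0, 1]; `round(density * sideLength^2)` founders must be at least 2.
#' @slot growthChance per-round division probability `R` of a non-switcher
#'   with an empty neighbour (default 0.5).
#' @slot switchingCost selection coefficient `s` in [0, 0.5]; switchers divide
#'   with probability `R * (1 - s)`.
#' @slot intraclonalCost multiplicative factor `c` in (0, 1] applied to the
#'   division probability of founders derived from an intraclonal zygote
#'   (default 1, no cost); it persists for one growth phase only.
#' @slot matingMode `"moore"` (mate an unmated opposite-type Moore neighbour)
#'   or `"global"` (mass action: any unmated opposite-type cell).
#' @slot maxTransfers cap on growth/mating cycles (default 500).
#' @slot initialSwitcherFreq founder switcher probability at the first seeding.
#' @slot maxGrowthRounds growth rounds allowed per transfer; `Inf` (default)
#'   grows until the grid is full, a finite value truncates the growth phase
#'   and mating then proceeds on the partially filled grid.
#' @slot pedigree `"deterministic"` for the canonical one-daughter-switches
#'   pedigree, `"bernoulli"` for the phase-reassignment sensitivity variant.
#' @slot seed integer RNG seed; every result is reproducible from
#'   (parameters, seed).
#'
#' @seealso [SimParams()] for the constructor, [runSimulation()].
#' @export
setClass("SimParams", representation(
  sideLength = "integer",
  boundary = "character",
  density = "numeric",
  growthChance = "numeric",
  switchingCost = "numeric",
  intraclonalCost = "numeric",
  matingMode = "character",
  maxTransfers = "integer",
  initialSwitcherFreq = "numeric",
  maxGrowthRounds = "numeric",
  pedigree = "character",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@sideLength) != 1 || is.na(object@sideLength) ||
      object@sideLength < 4)
    msg <- c(msg, "sideLength must be a single integer >= 4")
  if (!object@boundary %in% c("bounded", "torus"))
    msg <- c(msg, "boundary must be 'bounded' or 'torus'")
  if (length(object@density) != 1 || is.na(object@density) ||
      object@density <= 0 || object@density > 1)
    msg <- c(msg, "density must be in (0, 1]")
  else if (round(object@density * object@sideLength^2) < 2)
    msg <- c(msg, "density seeds fewer than 2 founders")
  if (object@growthChance <= 0 || object@growthChance > 1)
    msg <- c(msg, "growthChance R must be in (0, 1]")
  if (object@switchingCost < 0 || object@switchingCost > 0.5)
    msg <- c(msg, "switchingCost s must be in [0, 0.5]")
  if (object@intraclonalCost <= 0 || object@intraclonalCost > 1)
    msg <- c(msg, "intraclonalCost c must be in (0, 1]")
  if (!object@matingMode %in% c("moore", "global"))
    msg <- c(msg, "matingMode must be 'moore' or 'global'")
  if (object@maxTransfers < 1)
    msg <- c(msg, "maxTransfers must be >= 1")
  if (object@initialSwitcherFreq < 0 || object@initialSwitcherFreq > 1)
    msg <- c(msg, "initialSwitcherFreq must be in [0, 1]")
  if (!(is.infinite(object@maxGrowthRounds) || object@maxGrowthRounds >= 1))
    msg <- c(msg, "maxGrowthRounds must be >= 1 or Inf")
  if (!object@pedigree %in% c("deterministic", "bernoulli"))
    msg <- c(msg, "pedigree must be 'deterministic' or 'bernoulli'")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param sideLength lattice side length.
#' @param boundary `"bounded"` or `"torus"`.
#' @param density fraction of sites seeded, in (0, 1].
#' @param growthChance per-round division probability `R`.
#' @param switchingCost selection coefficient `s` against switchers, [0, 0.5].
#' @param intraclonalCost multiplicative cost `c` for intraclonal-origin
#'   founders, (0, 1].
#' @param matingMode `"moore"` or `"global"`.
#' @param maxTransfers cap on growth/mating cycles.
#' @param initialSwitcherFreq founder switcher probability at first seeding.
#' @param maxGrowthRounds growth rounds per transfer (`Inf` = grow until full).
#' @param pedigree `"deterministic"` or `"bernoulli"`.
#' @param seed integer RNG seed.
#'
#' @return A validated [SimParams-class] object.
#' @examples
#' p <- SimParams(sideLength = 30, density = 0.2, switchingCost = 0.1, seed = 1)
#' p
#' @export
SimParams <- function(sideLength = 200L, boundary = "bounded", density = 0.5,
                      growthChance = 0.5, switchingCost = 0,
                      intraclonalCost = 1, matingMode = "moore",
                      maxTransfers = 500L, initialSwitcherFreq = 0.5,
                      maxGrowthRounds = Inf, pedigree = "deterministic",
                      seed = 1L) {
  new("SimParams",
      sideLength = as.integer(sideLength), boundary = boundary,
      density = as.numeric(density), growthChance = as.numeric(growthChance),
      switchingCost = as.numeric(switchingCost),
      intraclonalCost = as.numeric(intraclonalCost),
      matingMode = matingMode, maxTransfers = as.integer(maxTransfers),
      initialSwitcherFreq = as.numeric(initialSwitcherFreq),
      maxGrowthRounds = as.numeric(maxGrowthRounds),
      pedigree = pedigree, seed = as.integer(seed))
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@sideLength, "x", object@sideLength,
      paste0("(", object@boundary, ")"),
      "density", object@density, "\n",
      " R =", object@growthChance, " s =", object@switchingCost,
      " c =", object@intraclonalCost, " mating:", object@matingMode, "\n",
      " maxTransfers =", object@maxTransfers,
      " initialSwitcherFreq =", object@initialSwitcherFreq,
      " seed =", object@seed, "\n")
})

#' Lattice state of the cellular automaton
#'
#' Per-site integer matrices describing the population: mating type (0 empty,
#' 1 P, 2 M), strategy (0 none, 1 switcher, 2 non-switcher), switching phase
#' (0 not applicable, 1 will switch, 2 will not switch; non-switchers always
#' 0), clone id (founder label of the current growth phase, 0 for empty),
#' intraclonal-origin flag and mated flag (0/1).
#'
#' @slot matingType,strategy,switchPhase,cloneId,intraclonal,mated integer
#'   matrices of identical square dimension.
#' @slot boundary `"bounded"` or `"torus"`.
#' @seealso [seedGrid()], [runGrowth()], [matingRound()], [gridCodes()].
#' @export
setClass("Lattice", representation(
  matingType = "matrix",
  strategy = "matrix",
  switchPhase = "matrix",
  cloneId = "matrix",
  intraclonal = "matrix",
  mated = "matrix",
  boundary = "character"
))

setValidity("Lattice", function(object) {
  d <- dim(object@matingType)
  msg <- character()
  if (d[1] != d[2]) msg <- c(msg, "lattice must be square")
  for (sl in c("strategy", "switchPhase", "cloneId", "intraclonal", "mated")) {
    if (!identical(dim(slot(object, sl)), d))
      msg <- c(msg, paste0("slot '", sl, "' dimension mismatch"))
  }
  mt <- object@matingType
  if (!all(mt %in% 0:2)) msg <- c(msg, "matingType codes must be 0/1/2")
  empty <- mt == 0L
  if (any(object@strategy[empty] != 0L) || any(object@cloneId[empty] != 0L) ||
      any(object@mated[empty] != 0L))
    msg <- c(msg, "empty sites must carry no attributes")
  if (any(object@strategy[!empty] == 0L))
    msg <- c(msg, "occupied sites must have a strategy")
  ns <- !empty & object@strategy == .ST_NONSWITCHER
  if (any(object@switchPhase[ns] != .PH_NA))
    msg <- c(msg, "non-switchers must have switchPhase 'not applicable'")
  sw <- !empty & object@strategy == .ST_SWITCHER
  if (any(!object@switchPhase[sw] %in% c(.PH_WILL, .PH_WONT)))
    msg <- c(msg, "switchers must be in the will- or won't-switch phase")
  if (!object@boundary %in% c("bounded", "torus"))
    msg <- c(msg, "boundary must be 'bounded' or 'torus'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Lattice", function(object) {
  occ <- sum(object@matingType != 0L)
  n <- length(object@matingType)
  cat("Lattice", nrow(object@matingType), "x", ncol(object@matingType),
      paste0("(", object@boundary, "):"), occ, "/", n, "occupied;",
      sum(object@strategy == .ST_SWITCHER), "switchers,",
      sum(object@strategy == .ST_NONSWITCHER), "non-switchers;",
      sum(object@mated), "mated\n")
})

#' Outcome of one mating round
#'
#' @slot zygotes data.frame with one row per zygote: `siteA`, `siteB` (lattice
#'   site indices), `strategyA`, `strategyB` (1 switcher, 2 non-switcher),
#'   `cloneA`, `cloneB` and `intraclonal` (both parents from the same clone).
#' @slot mated integer matrix marking mated sites.
#' @slot nOccupied number of occupied sites when mating ran.
#' @seealso [matingRound()], [nextFounderPool()].
#' @export
setClass("MatingOutcome", representation(
  zygotes = "data.frame",
  mated = "matrix",
  nOccupied = "integer"
))

setValidity("MatingOutcome", function(object) {
  z <- object@zygotes
  msg <- character()
  if (nrow(z) > 0) {
    sites <- c(z$siteA, z$siteB)
    if (anyDuplicated(sites)) msg <- c(msg, "a cell appears in two zygotes")
    if (2 * nrow(z) > object@nOccupied)
      msg <- c(msg, "more mated cells than occupied sites")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MatingOutcome", function(object) {
  z <- object@zygotes
  cat("MatingOutcome:", nrow(z), "zygotes among", object@nOccupied,
      "cells (", sum(z$intraclonal), "intraclonal )\n")
})

#' Per-transfer trajectory of one simulation
#'
#' @slot records data.frame with one row per transfer: `transfer`,
#'   `nonSwitcherFreq` (frequency among gametes after mating), `zygotes`,
#'   `matedFracSwitcher`, `matedFracNonSwitcher`, `growthRounds`.
#' @slot termination one of `"fixed_switcher"`, `"fixed_nonswitcher"`,
#'   `"extinct"`, `"transfer_cap"`.
#' @slot transfersRun number of transfers executed.
#' @slot params the [SimParams-class] that produced the run.
#' @seealso [runSimulation()], [trajectory()], [termination()].
#' @export
setClass("Trajectory", representation(
  records = "data.frame",
  termination = "character",
  transfersRun = "integer",
  params = "SimParams"
))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (!object@termination %in%
      c("fixed_switcher", "fixed_nonswitcher", "extinct", "transfer_cap"))
    msg <- c(msg, "unknown termination state")
  f <- object@records$nonSwitcherFreq
  f <- f[!is.na(f)]
  if (length(f) && (any(f < 0) || any(f > 1)))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (object@transfersRun > object@params@maxTransfers)
    msg <- c(msg, "transfersRun exceeds maxTransfers")
  if (length(f)) {
    last <- f[length(f)]
    if (object@termination == "fixed_switcher" && last != 0)
      msg <- c(msg, "fixed_switcher requires final non-switcher frequency 0")
    if (object@termination == "fixed_nonswitcher" && last != 1)
      msg <- c(msg, "fixed_nonswitcher requires final non-switcher frequency 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", object@transfersRun, "transfers, termination:",
      object@termination, "\n")
  f <- object@records$nonSwitcherFreq
  f <- f[!is.na(f)]
  if (length(f))
    cat(" final non-switcher frequency:", f[length(f)], "\n")
})

#' Result of a density-by-cost invasion sweep
#'
#' @slot summary data.frame per sweep cell: `density`, `cost`,
#'   `meanFinalNonSwitcherRatio`, `sdFinalRatio`, `nReplicates`, `nExtinct`
#'   (extinct replicates are excluded from the mean and counted here).
#' @slot replicates data.frame per run: `density`, `cost`, `replicate`,
#'   `seed`, `finalNonSwitcherRatio`, `termination`, `transfers`.
#' @slot densities,costs the sweep axes.
#' @slot baseParams the shared [SimParams-class] template.
#' @seealso [invasionSweep()], [polymorphismCheck()], [plotSweepHeatmap()].
#' @export
setClass("SweepResult", representation(
  summary = "data.frame",
  replicates = "data.frame",
  densities = "numeric",
  costs = "numeric",
  baseParams = "SimParams"
))

setValidity("SweepResult", function(object) {
  msg <- character()
  m <- object@summary$meanFinalNonSwitcherRatio
  m <- m[!is.na(m)]
  if (length(m) && (any(m < 0) || any(m > 1)))
    msg <- c(msg, "mean final ratios must lie in [0, 1]")
  s <- object@summary$sdFinalRatio
  if (any(!is.na(s) & s < 0)) msg <- c(msg, "SD must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult:", length(object@densities), "densities x",
      length(object@costs), "costs,",
      max(object@replicates$replicate), "replicates per cell\n")
  print(object@summary, row.names = FALSE)
})

#' Specification for the synthetic competition-data generator
#'
#' Describes a set of flow-cytometry-style competition assays with known
#' ground truth: a true per-generation selection coefficient, a marker effect
#' composed additively on the log-fitness scale, and multinomial counting
#' noise at fixed sampling depth.
#'
#' @slot trueS expected corrected per-generation selection coefficient of the
#'   focal strain i relative to strain j (positive favours i).
#' @slot markerEffect per-generation log-fitness cost of carrying the
#'   fluorescent marker.
#' @slot markerOn `"i"` or `"j"`: which competitor carries the marker.
#' @slot transfers,foldGrowth competition regime: number of transfers and fold
#'   growth per transfer (generations = transfers * log2(foldGrowth)).
#' @slot samplingDepth cells counted per flow-cytometry measurement (>= 100).
#' @slot nReplicates biological replicates to generate.
#' @slot initialFreqI frequency of strain i in the starting mix, in (0, 1).
#' @slot betweenReplicateSd optional SD of a per-replicate jitter on the
#'   selection coefficient (default 0).
#' @slot regime label: `"asexual_exponential"`, `"asexual_saturated"` or
#'   `"sexual"`.
#' @slot seed integer RNG seed.
#' @seealso [GeneratorSpec()], [generateAsexual()], [generateSexual()].
#' @export
setClass("GeneratorSpec", representation(
  trueS = "numeric",
  markerEffect = "numeric",
  markerOn = "character",
  transfers = "integer",
  foldGrowth = "numeric",
  samplingDepth = "integer",
  nReplicates = "integer",
  initialFreqI = "numeric",
  betweenReplicateSd = "numeric",
  regime = "character",
  seed = "integer"
))

setValidity("GeneratorSpec", function(object) {
  msg <- character()
  if (object@samplingDepth < 100)
    msg <- c(msg, "samplingDepth must be at least 100")
  if (object@initialFreqI <= 0 || object@initialFreqI >= 1)
    msg <- c(msg, "initialFreqI must be in (0, 1)")
  if (!object@markerOn %in% c("i", "j"))
    msg <- c(msg, "markerOn must be 'i' or 'j'")
  if (object@foldGrowth <= 1)
    msg <- c(msg, "foldGrowth must exceed 1")
  if (object@transfers < 1) msg <- c(msg, "transfers must be >= 1")
  if (object@nReplicates < 1) msg <- c(msg, "nReplicates must be >= 1")
  if (object@betweenReplicateSd < 0)
    msg <- c(msg, "betweenReplicateSd must be >= 0")
  if (!object@regime %in%
      c("asexual_exponential", "asexual_saturated", "sexual"))
    msg <- c(msg, "unknown regime label")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneratorSpec-class
#' @param trueS,markerEffect,markerOn,transfers,foldGrowth,samplingDepth
#'   see the class slots.
#' @param nReplicates,initialFreqI,betweenReplicateSd,regime,seed see the
#'   class slots.
#' @return A validated [GeneratorSpec-class] object.
#' @export
GeneratorSpec <- function(trueS = 0, markerEffect = 0, markerOn = "i",
                          transfers = 5L, foldGrowth = 100,
                          samplingDepth = 1e5, nReplicates = 8L,
                          initialFreqI = 0.5, betweenReplicateSd = 0,
                          regime = "asexual_saturated", seed = 1L) {
  new("GeneratorSpec", trueS = as.numeric(trueS),
      markerEffect = as.numeric(markerEffect), markerOn = markerOn,
      transfers = as.integer(transfers), foldGrowth = as.numeric(foldGrowth),
      samplingDepth = as.integer(samplingDepth),
      nReplicates = as.integer(nReplicates),
      initialFreqI = as.numeric(initialFreqI),
      betweenReplicateSd = as.numeric(betweenReplicateSd),
      regime = regime, seed = as.integer(seed))
}

setMethod("show", "GeneratorSpec", function(object) {
  cat("GeneratorSpec:", object@regime, " trueS =", object@trueS,
      " markerEffect =", object@markerEffect, "on", object@markerOn, "\n",
      " t =", object@transfers, "x log2(", object@foldGrowth, ") =",
      round(object@transfers * log2(object@foldGrowth), 1), "generations;",
      object@nReplicates, "replicates at depth", object@samplingDepth, "\n")
})
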