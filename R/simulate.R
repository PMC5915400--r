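#' Run one multi-transfer simulation
#'
#' Alternates seeding, asexual growth to a full grid, mating and Mendelian
#' reseeding until either strategy fixes, the population goes extinct (no
#' zygotes formed), or `maxTransfers` is reached. The RNG is seeded from
#' `params@seed`, so identical parameters give identical trajectories.
#'
#' @param params a [SimParams-class] object.
#' @return A [Trajectory-class] with one record per transfer.
#' @examples
#' p <- SimParams(sideLength = 20, density = 0.5, switchingCost = 0.4,
#'                maxTransfers = 50, seed = 42)
#' tr <- runSimulation(p)
#' termination(tr)
#' @export
runSimulation <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)
  freq <- params@initialSwitcherFreq
  intraFr <- c(switcher = 0, nonswitcher = 0)
  partial <- is.finite(params@maxGrowthRounds)
  rec <- vector("list", params@maxTransfers)
  term <- "transfer_cap"
  run <- 0L

  for (tr in seq_len(params@maxTransfers)) {
    lat <- seedGrid(params, freq, intraFr)
    lat <- runGrowth(lat, params)
    out <- matingRound(lat, params, requireFull = !partial)
    mf <- matedFractions(lat, out)
    nz <- nrow(zygotes(out))
    run <- tr
    if (nz == 0) {
      rec[[tr]] <- data.frame(transfer = tr, nonSwitcherFreq = NA_real_,
                              zygotes = 0L,
                              matedFracSwitcher = mf[["switcher"]],
                              matedFracNonSwitcher = mf[["nonswitcher"]],
                              growthRounds = attr(lat, "rounds"))
      term <- "extinct"
      break
    }
    pool <- nextFounderPool(out)
    freq <- pool$switcherFreq
    intraFr <- pool$intraclonalFracs
    rec[[tr]] <- data.frame(transfer = tr, nonSwitcherFreq = 1 - freq,
                            zygotes = nz,
                            matedFracSwitcher = mf[["switcher"]],
                            matedFracNonSwitcher = mf[["nonswitcher"]],
                            growthRounds = attr(lat, "rounds"))
    if (freq == 1) { term <- "fixed_switcher"; break }
    if (freq == 0) { term <- "fixed_nonswitcher"; break }
  }

  new("Trajectory", records = do.call(rbind, rec[seq_len(run)]),
      termination = term, transfersRun = run, params = params)
}

#' Density-by-cost invasion sweep
#'
#' Runs the full factorial of (density, switching cost) cells with
#' `replicates` independent runs per cell. Per-run seeds are derived from the
#' master seed by a counter, so results are reproducible and independent of
#' execution order. All cell configurations are validated before any run
#' starts. Extinct replicates are excluded from the cell mean and reported in
#' `nExtinct`.
#'
#' @param base a [SimParams-class] template; its `density` and `switchingCost`
#'   are overwritten per cell.
#' @param densities,costs sweep axes (non-empty).
#' @param replicates runs per cell (default 10).
#' @param seed master integer seed.
#' @return A [SweepResult-class].
#' @seealso [polymorphismCheck()], [writeSweepCsv()], [plotSweepHeatmap()].
#' @export
invasionSweep <- function(base, densities, costs, replicates = 10L,
                          seed = base@seed) {
  stopifnot(is(base, "SimParams"), length(densities) >= 1,
            length(costs) >= 1, replicates >= 1)
  # canonical cell order, so derived seeds (and hence results) do not depend
  # on the order in which axes are supplied
  densities <- sort(unique(densities))
  costs <- sort(unique(costs))
  cells <- expand.grid(density = densities, cost = costs,
                       KEEP.OUT.ATTRS = FALSE)
  # fail fast: every cell must be a valid configuration
  for (k in seq_len(nrow(cells))) {
    p <- base
    p@density <- cells$density[k]
    p@switchingCost <- cells$cost[k]
    validObject(p)
  }
  grid <- expand.grid(replicate = seq_len(replicates),
                      density = densities, cost = costs,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    p <- base
    p@density <- grid$density[k]
    p@switchingCost <- grid$cost[k]
    p@seed <- as.integer((seed + k) %% .Machine$integer.max)
    tr <- runSimulation(p)
    data.frame(density = grid$density[k], cost = grid$cost[k],
               replicate = grid$replicate[k], seed = p@seed,
               finalNonSwitcherRatio = finalNonSwitcherFreq(tr),
               termination = termination(tr),
               transfers = transfersRun(tr))
  })
  reps <- do.call(rbind, rows)
  agg <- lapply(split(reps, list(reps$density, reps$cost), drop = FALSE),
                function(d) {
    ok <- d$termination != "extinct"
    data.frame(density = d$density[1], cost = d$cost[1],
               meanFinalNonSwitcherRatio =
                 if (any(ok)) mean(d$finalNonSwitcherRatio[ok]) else NA_real_,
               sdFinalRatio =
                 if (sum(ok) > 1) sd(d$finalNonSwitcherRatio[ok]) else NA_real_,
               nReplicates = sum(ok), nExtinct = sum(!ok))
  })
  summary <- do.call(rbind, agg)
  summary <- summary[order(summary$cost, summary$density), ]
  rownames(summary) <- NULL
  new("SweepResult", summary = summary, replicates = reps,
      densities = as.numeric(densities), costs = as.numeric(costs),
      baseParams = base)
}

#' Flag apparent polymorphism at the transfer cap
#'
#' A replicate that reaches the transfer cap with a final non-switcher
#' frequency inside `bounds` (default [0.1, 0.9]) is flagged as an apparent
#' polymorphism. Runs that fixed, went extinct, or sat near an absorbing
#' boundary are not flagged.
#'
#' @param sweep a [SweepResult-class] with per-replicate endpoints.
#' @param bounds length-2 numeric, the flagged frequency band.
#' @return data.frame per sweep cell with `nFlagged`; attribute
#'   `"totalFlagged"` holds the overall count.
#' @export
polymorphismCheck <- function(sweep, bounds = c(0.1, 0.9)) {
  reps <- sweepReplicates(sweep)
  flag <- reps$termination == "transfer_cap" &
    !is.na(reps$finalNonSwitcherRatio) &
    reps$finalNonSwitcherRatio >= bounds[1] &
    reps$finalNonSwitcherRatio <= bounds[2]
  agg <- aggregate(flag, by = list(density = reps$density, cost = reps$cost),
                   FUN = sum)
  names(agg)[3] <- "nFlagged"
  agg <- agg[order(agg$cost, agg$density), ]
  rownames(agg) <- NULL
  attr(agg, "totalFlagged") <- sum(flag)
  agg
}
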