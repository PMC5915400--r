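#' Generate asexual competition data with known ground truth
#'
#' Emulates a flow-cytometry competition assay. The latent frequency of the
#' focal strain i evolves deterministically: per generation the log ratio
#' `log(p_i / p_j)` changes by `trueS` minus the marker cost for whichever
#' strain carries it (effects compose additively on the log-fitness scale, so
#' the additive marker correction is exact), over
#' `t = transfers * log2(foldGrowth)` generations. Observed counts are drawn
#' binomially at `samplingDepth` before and after. Matching isogenic
#' marked-vs-unmarked control records (true strain effect 0) are produced for
#' marker correction, and `markerSwap = TRUE` yields the reciprocally marked
#' record set.
#'
#' @param spec a [GeneratorSpec-class].
#' @param markerSwap also generate the record set with the marker on the
#'   other strain.
#' @param includeControls generate matching isogenic marker-control records.
#' @param infiniteDepth skip counting noise: "counts" are the exact expected
#'   values `depth * frequency` (the deterministic no-noise limit).
#' @return A [competitionRecords()] table with a `set` column
#'   (`"competition"` or `"control"`); attribute `"groundTruth"` carries
#'   `trueS` and `markerEffect`.
#' @examples
#' spec <- GeneratorSpec(trueS = 0.035, markerEffect = 0.01, seed = 3)
#' rec <- generateAsexual(spec)
#' comp <- rec[rec$set == "competition", ]
#' ctrl <- rec[rec$set == "control", ]
#' sHat <- markerCorrect(
#'   mean(perGeneration(logRatioSelection(comp), 5, 100)),
#'   mean(perGeneration(logRatioSelection(ctrl), 5, 100)))
#' sHat  # close to 0.035
#' @export
generateAsexual <- function(spec, markerSwap = FALSE, includeControls = TRUE,
                            infiniteDepth = FALSE) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  set.seed(spec@seed)
  t <- spec@transfers * log2(spec@foldGrowth)
  sides <- if (markerSwap) c(spec@markerOn, setdiff(c("i", "j"),
                                                    spec@markerOn))
           else spec@markerOn
  sets <- if (includeControls) c("competition", "control") else "competition"

  rows <- list()
  for (side in sides) {
    for (set in sets) {
      strainEffect <- if (set == "competition") spec@trueS else 0
      markerTerm <- if (side == "i") -spec@markerEffect else spec@markerEffect
      for (r in seq_len(spec@nReplicates)) {
        adv <- strainEffect + markerTerm
        if (spec@betweenReplicateSd > 0)
          adv <- adv + rnorm(1, 0, spec@betweenReplicateSd)
        f0 <- spec@initialFreqI
        f1 <- plogis(qlogis(f0) + t * adv)
        if (f1 <= 0 || f1 >= 1)
          stop("parameters drive the latent frequency outside (0, 1)")
        rows[[length(rows) + 1]] <- cbind(
          .sampleCounts(f0, f1, spec@samplingDepth, infiniteDepth),
          data.frame(transfers = spec@transfers,
                     foldGrowth = spec@foldGrowth, regime = spec@regime,
                     markerOn = side, replicateId = r, set = set))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("competition_records", "data.frame")
  attr(out, "groundTruth") <- list(trueS = spec@trueS,
                                   markerEffect = spec@markerEffect)
  out
}

.sampleCounts <- function(f0, f1, depth, infiniteDepth) {
  if (infiniteDepth) {
    data.frame(countIBefore = depth * f0, countJBefore = depth * (1 - f0),
               countIAfter = depth * f1, countJAfter = depth * (1 - f1))
  } else {
    ib <- rbinom(1, depth, f0)
    ia <- rbinom(1, depth, f1)
    data.frame(countIBefore = ib, countJBefore = depth - ib,
               countIAfter = ia, countJAfter = depth - ia)
  }
}

#' Generate sexual competition data with known relative fitness
#'
#' After-frequencies derive from before-frequencies through an assigned
#' relative fitness `w` of the focal strain: the frequency ratio is
#' multiplied by `w` over one sexual round, so [sexualSelection()] recovers
#' `s = 1 - w`. `w` may be a single value, one value per density (a
#' density-indexed map), or a function of the before-frequency for
#' frequency-dependent competition.
#'
#' @param spec a [GeneratorSpec-class]; `initialFreqI`, `samplingDepth`,
#'   `nReplicates` and `seed` are used.
#' @param w numeric (length 1 or `length(densities)`) or
#'   `function(freqBefore)` returning a positive relative fitness.
#' @param densities density labels for the treatment series (default a
#'   single unit density).
#' @param infiniteDepth skip counting noise.
#' @return A [competitionRecords()] table with a `density` column.
#' @export
generateSexual <- function(spec, w, densities = 1, infiniteDepth = FALSE) {
  stopifnot(is(spec, "GeneratorSpec"))
  validObject(spec)
  set.seed(spec@seed)
  wFun <- if (is.function(w)) {
    w
  } else {
    wv <- rep_len(w, length(densities))
    function(f, d) wv[match(d, densities)]
  }
  rows <- list()
  for (d in densities) {
    for (r in seq_len(spec@nReplicates)) {
      f0 <- spec@initialFreqI
      wd <- if (is.function(w)) w(f0) else wFun(f0, d)
      if (!is.finite(wd) || wd <= 0)
        stop("relative fitness w must be positive")
      ratio1 <- f0 / (1 - f0) * wd
      f1 <- ratio1 / (1 + ratio1)
      rows[[length(rows) + 1]] <- cbind(
        .sampleCounts(f0, f1, spec@samplingDepth, infiniteDepth),
        data.frame(transfers = 1L, foldGrowth = spec@foldGrowth,
                   regime = "sexual", markerOn = spec@markerOn,
                   replicateId = r, density = d, set = "competition"))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("competition_records", "data.frame")
  attr(out, "groundTruth") <- list(w = w)
  out
}

#' Hand-constructed fixture lattices
#'
#' Small, fully specified lattice states with documented expected mating
#' outcomes, for exercising the cellular automaton without random seeding:
#'
#' * `"single_clone_5x5"` — one P switcher (will-switch) at the centre of an
#'   otherwise empty 5x5 grid.
#' * `"checkerboard_4x4"` — full 4x4 grid of non-switchers with alternating
#'   P/M types and distinct clones: every cell has an opposite-type
#'   neighbour (all cells mateable) and a maximum matching pairs all 16
#'   cells into 8 zygotes.
#' * `"all_P_3x3"` — full 3x3 grid, all P non-switchers: zero zygotes.
#' * `"two_clone_10x10"` — full 10x10 grid; columns 1-5 are one all-P
#'   non-switcher clone, columns 6-10 one all-M clone. Mating is possible
#'   only across the contact zone (columns 5 and 6): at most 10 zygotes.
#' * `"two_clone_10x10_switcher"` — the same two clones but switchers whose
#'   types alternate within each clone (the pattern switching generates):
#'   every cell can mate (a maximum matching pairs all 100 cells).
#'
#' @param name catalog entry name.
#' @return A [Lattice-class].
#' @examples
#' lat <- fixtureGrids("checkerboard_4x4")
#' set.seed(1)
#' out <- matingRound(lat, SimParams(sideLength = 4, density = 1))
#' nrow(zygotes(out))
#' @export
fixtureGrids <- function(name) {
  catalog <- c("single_clone_5x5", "checkerboard_4x4", "all_P_3x3",
               "two_clone_10x10", "two_clone_10x10_switcher")
  if (!name %in% catalog)
    stop("unknown fixture '", name, "'; available: ",
         paste(catalog, collapse = ", "))
  build <- function(L, mt, st, ph, cl, ic = 0L) {
    z <- matrix(0L, L, L)
    occ <- mt != 0L
    icm <- z; icm[occ] <- ic
    new("Lattice", matingType = mt, strategy = st, switchPhase = ph,
        cloneId = cl, intraclonal = icm, mated = z, boundary = "bounded")
  }
  switch(name,
    single_clone_5x5 = {
      L <- 5L
      mt <- matrix(0L, L, L); st <- mt; ph <- mt; cl <- mt
      mt[3, 3] <- .MT_P; st[3, 3] <- .ST_SWITCHER
      ph[3, 3] <- .PH_WILL; cl[3, 3] <- 1L
      build(L, mt, st, ph, cl)
    },
    checkerboard_4x4 = {
      L <- 4L
      idx <- outer(seq_len(L), seq_len(L), `+`)
      mt <- matrix(ifelse(idx %% 2 == 0, .MT_P, .MT_M), L, L)
      st <- matrix(.ST_NONSWITCHER, L, L)
      ph <- matrix(.PH_NA, L, L)
      cl <- matrix(seq_len(L * L), L, L)
      build(L, mt, st, ph, cl)
    },
    all_P_3x3 = {
      L <- 3L
      build(L, matrix(.MT_P, L, L), matrix(.ST_NONSWITCHER, L, L),
            matrix(.PH_NA, L, L), matrix(seq_len(L * L), L, L))
    },
    two_clone_10x10 = {
      L <- 10L
      half <- col(matrix(0, L, L)) <= L / 2
      mt <- matrix(.MT_M, L, L); mt[half] <- .MT_P
      st <- matrix(.ST_NONSWITCHER, L, L)
      ph <- matrix(.PH_NA, L, L)
      cl <- matrix(2L, L, L); cl[half] <- 1L
      build(L, mt, st, ph, cl)
    },
    two_clone_10x10_switcher = {
      L <- 10L
      half <- col(matrix(0, L, L)) <= L / 2
      idx <- outer(seq_len(L), seq_len(L), `+`)
      mt <- matrix(ifelse(idx %% 2 == 0, .MT_P, .MT_M), L, L)
      st <- matrix(.ST_SWITCHER, L, L)
      ph <- matrix(ifelse(idx %% 2 == 0, .PH_WILL, .PH_WONT), L, L)
      cl <- matrix(2L, L, L); cl[half] <- 1L
      build(L, mt, st, ph, cl)
    })
}
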