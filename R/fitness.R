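#' Build a table of competition records
#'
#' One row per competition: counts of the two competing strains before and
#' after, the transfer regime and which strain carried the fluorescent
#' marker. This is the input contract for all estimators — raw flow-cytometry
#' files are out of scope, counts are the interface.
#'
#' @param countIBefore,countJBefore,countIAfter,countJAfter non-negative
#'   counts of strains i and j at the two measurements.
#' @param transfers number of transfers between measurements.
#' @param foldGrowth fold increase per transfer (e.g. 100 for a 1% daily
#'   transfer).
#' @param regime `"asexual_exponential"`, `"asexual_saturated"` or
#'   `"sexual"`.
#' @param markerOn `"i"` or `"j"`.
#' @param replicateId replicate labels.
#' @return data.frame of class `competition_records`.
#' @export
competitionRecords <- function(countIBefore, countJBefore, countIAfter,
                               countJAfter, transfers = 5L, foldGrowth = 100,
                               regime = "asexual_saturated", markerOn = "i",
                               replicateId = seq_along(countIBefore)) {
  counts <- cbind(countIBefore, countJBefore, countIAfter, countJAfter)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(regime %in% c("asexual_exponential", "asexual_saturated", "sexual")))
    stop("unknown regime label")
  if (!all(markerOn %in% c("i", "j"))) stop("markerOn must be 'i' or 'j'")
  out <- data.frame(countIBefore = countIBefore, countJBefore = countJBefore,
                    countIAfter = countIAfter, countJAfter = countJAfter,
                    transfers = transfers, foldGrowth = foldGrowth,
                    regime = regime, markerOn = markerOn,
                    replicateId = replicateId)
  class(out) <- c("competition_records", "data.frame")
  out
}

.checkCounts <- function(records, pseudocount) {
  cols <- c("countIBefore", "countJBefore", "countIAfter", "countJAfter")
  m <- as.matrix(records[cols])
  if (any(m == 0)) {
    if (!pseudocount)
      stop("zero counts; re-run with pseudocount = TRUE to add Haldane's 0.5")
    m <- m + 0.5
  }
  m
}

#' Log-ratio selection coefficient per competition
#'
#' `s_ij = log(p_i,after / p_j,after) - log(p_i,before / p_j,before)` with
#' natural logarithms; positive values mean the focal strain i gained.
#' The estimator is antisymmetric under swapping i and j, and invariant to
#' multiplying all counts by a constant.
#'
#' @param records a [competitionRecords()] table.
#' @param pseudocount add 0.5 to every count when zeros are present
#'   (default `FALSE`: zero counts are an error). When applied, the result
#'   carries attribute `pseudocount = TRUE`.
#' @return numeric vector of per-competition selection coefficients.
#' @examples
#' r <- competitionRecords(500, 500, 600, 400)
#' logRatioSelection(r)  # log(1.5) ~= 0.405
#' @export
logRatioSelection <- function(records, pseudocount = FALSE) {
  m <- .checkCounts(records, pseudocount)
  s <- unname(log(m[, "countIAfter"] / m[, "countJAfter"]) -
                log(m[, "countIBefore"] / m[, "countJBefore"]))
  if (pseudocount &&
      any(as.matrix(records[c("countIBefore", "countJBefore",
                              "countIAfter", "countJAfter")]) == 0))
    attr(s, "pseudocount") <- TRUE
  s
}

#' Total generations of a competition regime
#'
#' `t = transfers * log2(foldGrowth)`: five transfers at 100-fold growth are
#' ~33 generations, at 500-fold ~45 generations.
#'
#' @param transfers number of transfers (>= 1).
#' @param foldGrowth fold increase of binary fission per transfer (> 1).
#' @return total generations.
#' @export
totalGenerations <- function(transfers, foldGrowth) {
  if (any(foldGrowth <= 1)) stop("foldGrowth must exceed 1")
  if (any(transfers < 1)) stop("transfers must be >= 1")
  transfers * log2(foldGrowth)
}

#' Scale a selection coefficient to per generation
#'
#' @param s per-competition selection coefficient(s).
#' @inheritParams totalGenerations
#' @return `s / totalGenerations(transfers, foldGrowth)`.
#' @export
perGeneration <- function(s, transfers, foldGrowth) {
  s / totalGenerations(transfers, foldGrowth)
}

#' Correct a selection estimate for the marker effect
#'
#' Selection coefficients are assumed additive, so the cost of the
#' fluorescent marker (measured in isogenic marked-vs-unmarked control
#' competitions under the same regime) subtracts out:
#' `s_corrected = s_total - s_marker`.
#'
#' @param sTotal selection estimate from the strain-vs-strain competition.
#' @param sMarker marker-effect estimate from the isogenic control.
#' @param regimeTotal,regimeMarker optional regime labels; if both are given
#'   they must match.
#' @return `sTotal - sMarker`.
#' @export
markerCorrect <- function(sTotal, sMarker, regimeTotal = NULL,
                          regimeMarker = NULL) {
  if (!is.null(regimeTotal) && !is.null(regimeMarker) &&
      !identical(regimeTotal, regimeMarker))
    stop("marker control and competition were measured under different regimes")
  sTotal - sMarker
}

#' Sexual-competition selection coefficient
#'
#' Relative fitness over one sexual round:
#' `log(w) = log(p_i,after / p_j,after) - log(p_i,before / p_j,before)` and
#' `s = 1 - w`. Positive `s` means the focal strain i is selected against.
#' The estimate does not depend on the initial mixing ratio.
#'
#' @inheritParams logRatioSelection
#' @return numeric vector of selection coefficients.
#' @examples
#' r <- competitionRecords(500, 500, 250, 750, regime = "sexual")
#' sexualSelection(r)  # w = 1/3, s = 2/3
#' @export
sexualSelection <- function(records, pseudocount = FALSE) {
  1 - exp(logRatioSelection(records, pseudocount = pseudocount))
}

#' Summarise replicate estimates
#'
#' @param estimates numeric vector of per-replicate selection estimates.
#' @return data.frame with `mean`, `se` (standard error of the mean; `NA`
#'   when fewer than 2 replicates) and `n`.
#' @export
replicateSummary <- function(estimates) {
  n <- sum(!is.na(estimates))
  data.frame(mean = mean(estimates, na.rm = TRUE),
             se = if (n >= 2) sd(estimates, na.rm = TRUE) / sqrt(n)
                  else NA_real_,
             n = n)
}
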