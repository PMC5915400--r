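#' @name accessors
#' @title Accessors for switchsim objects
#' @description Small accessor generics so user code never touches slots
#'   directly.
#' @param x a switchsim object.
#' @return `trajectory()` the per-transfer data.frame; `termination()` the
#'   termination state; `transfersRun()` the number of transfers executed;
#'   `zygotes()` the zygote table of a [MatingOutcome-class];
#'   `matedMatrix()` the 0/1 mated matrix; `sweepSummary()` and
#'   `sweepReplicates()` the per-cell and per-run tables of a
#'   [SweepResult-class]; `occupancy()` the number of occupied sites of a
#'   [Lattice-class]; `finalNonSwitcherFreq()` the last recorded non-switcher
#'   frequency of a [Trajectory-class].
NULL

#' @rdname accessors
#' @export
setGeneric("trajectory", function(x) standardGeneric("trajectory"))
#' @rdname accessors
#' @export
setGeneric("termination", function(x) standardGeneric("termination"))
#' @rdname accessors
#' @export
setGeneric("transfersRun", function(x) standardGeneric("transfersRun"))
#' @rdname accessors
#' @export
setGeneric("zygotes", function(x) standardGeneric("zygotes"))
#' @rdname accessors
#' @export
setGeneric("matedMatrix", function(x) standardGeneric("matedMatrix"))
#' @rdname accessors
#' @export
setGeneric("sweepSummary", function(x) standardGeneric("sweepSummary"))
#' @rdname accessors
#' @export
setGeneric("sweepReplicates", function(x) standardGeneric("sweepReplicates"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("finalNonSwitcherFreq",
           function(x) standardGeneric("finalNonSwitcherFreq"))

#' @rdname accessors
#' @export
setMethod("trajectory", "Trajectory", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("termination", "Trajectory", function(x) x@termination)
#' @rdname accessors
#' @export
setMethod("transfersRun", "Trajectory", function(x) x@transfersRun)
#' @rdname accessors
#' @export
setMethod("zygotes", "MatingOutcome", function(x) x@zygotes)
#' @rdname accessors
#' @export
setMethod("matedMatrix", "MatingOutcome", function(x) x@mated)
#' @rdname accessors
#' @export
setMethod("matedMatrix", "Lattice", function(x) x@mated)
#' @rdname accessors
#' @export
setMethod("sweepSummary", "SweepResult", function(x) x@summary)
#' @rdname accessors
#' @export
setMethod("sweepReplicates", "SweepResult", function(x) x@replicates)
#' @rdname accessors
#' @export
setMethod("occupancy", "Lattice", function(x) sum(x@matingType != 0L))
#' @rdname accessors
#' @export
setMethod("finalNonSwitcherFreq", "Trajectory", function(x) {
  f <- x@records$nonSwitcherFreq
  f <- f[!is.na(f)]
  if (length(f)) f[length(f)] else NA_real_
})
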