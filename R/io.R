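.paramKeys <- c("sideLength", "boundary", "density", "growthChance",
                "switchingCost", "intraclonalCost", "matingMode",
                "maxTransfers", "initialSwitcherFreq", "maxGrowthRounds",
                "pedigree", "seed")

#' Load simulation parameters from a config file
#'
#' Reads a YAML or JSON file whose keys mirror the [SimParams()] arguments.
#' Precedence is defaults < config file < `overrides` (e.g. command-line
#' flags). Unknown keys are rejected by name.
#'
#' @param path config file (`.yaml`, `.yml` or `.json`); `NULL` for pure
#'   defaults.
#' @param overrides named list of values that win over the file.
#' @return A validated [SimParams-class].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("density: 0.3\nswitchingCost: 0.2", cfg)
#' loadConfig(cfg, overrides = list(density = 0.5))@density  # 0.5 wins
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    ext <- tolower(sub(".*\\.", "", basename(path)))
    vals <- switch(ext,
      yaml = , yml = yaml::read_yaml(path),
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      stop("unsupported config format '.", ext, "' (use YAML or JSON)"))
    if (is.null(vals)) vals <- list()
  }
  for (v in list(vals, overrides)) {
    bad <- setdiff(names(v), .paramKeys)
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  merged <- modifyList(vals, overrides)
  do.call(SimParams, merged)
}

#' Write a trajectory as CSV
#'
#' One row per transfer, UTF-8, '.' decimal separator.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCsv <- function(traj, path) {
  write.csv(trajectory(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep as long-format CSV
#'
#' One replicate per row with the header
#' `density,cost,replicate,final_nonswitcher_ratio,termination,transfers`.
#'
#' @param sweep a [SweepResult-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSweepCsv <- function(sweep, path) {
  reps <- sweepReplicates(sweep)
  out <- data.frame(density = reps$density, cost = reps$cost,
                    replicate = reps$replicate,
                    final_nonswitcher_ratio = reps$finalNonSwitcherRatio,
                    termination = reps$termination,
                    transfers = reps$transfers)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a lattice snapshot as a plain-text matrix
#'
#' Integer codes 0 empty, 1 P switcher, 2 M switcher, 3 P non-switcher,
#' 4 M non-switcher, one lattice row per line; optionally a companion 0/1
#' mated-status matrix.
#'
#' @param lattice a [Lattice-class].
#' @param path output file.
#' @param matedPath optional file for the mated matrix.
#' @param mated optional mated matrix (e.g. from [matedMatrix()] of a
#'   [MatingOutcome-class]); defaults to the lattice's own slot.
#' @return `path`, invisibly.
#' @export
writeGridSnapshot <- function(lattice, path, matedPath = NULL, mated = NULL) {
  write.table(gridCodes(lattice), path, row.names = FALSE,
              col.names = FALSE)
  if (!is.null(matedPath)) {
    if (is.null(mated)) mated <- matedMatrix(lattice)
    write.table(mated, matedPath, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.paramsAsList <- function(params) {
  setNames(lapply(.paramKeys, function(k) slot(params, k)), .paramKeys)
}

#' Write a run manifest
#'
#' A JSON record sufficient to reproduce a run exactly: the command, the
#' resolved parameters, the master seed, the package version, a timestamp and
#' the list of output files.
#'
#' @param path output JSON file.
#' @param command short command label (e.g. `"simulate"`).
#' @param params the resolved [SimParams-class].
#' @param seed master seed used.
#' @param outputs character vector of files written alongside.
#' @return the manifest list, invisibly.
#' @seealso [readManifest()]
#' @export
writeManifest <- function(path, command, params, seed = params@seed,
                          outputs = character()) {
  manifest <- list(command = command,
                   parameters = .paramsAsList(params),
                   seed = seed,
                   package = "switchsim",
                   version = as.character(packageVersion("switchsim")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a run manifest back
#'
#' @param path manifest JSON file.
#' @return list with the manifest fields; `parameters` is rebuilt into a
#'   [SimParams-class] under `$params`.
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  pars <- m$parameters
  if (is.list(pars) && !is.null(pars$maxGrowthRounds) &&
      identical(pars$maxGrowthRounds, "Inf"))
    pars$maxGrowthRounds <- Inf
  m$params <- do.call(SimParams, pars)
  m
}

#' Heat-map of an invasion sweep
#'
#' Tiles coloured by the mean final non-switcher ratio per (density, cost)
#' cell, with a black dot sized by the replicate standard deviation.
#'
#' @param sweep a [SweepResult-class].
#' @return a ggplot object.
#' @export
plotSweepHeatmap <- function(sweep) {
  s <- sweepSummary(sweep)
  s$density <- factor(s$density)
  s$cost <- factor(s$cost)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$density, y = .data$cost,
                                  fill = .data$meanFinalNonSwitcherRatio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(ggplot2::aes(size = .data$sdFinalRatio),
                        colour = "black", na.rm = TRUE) +
    ggplot2::scale_fill_gradient(low = "#fff5eb", high = "#7f2704",
                                 limits = c(0, 1),
                                 name = "mean final\nnon-switcher ratio") +
    ggplot2::scale_size_area(max_size = 4, name = "SD") +
    ggplot2::labs(x = "population density", y = "cost of switching")
}

#' Plot a lattice snapshot
#'
#' Switchers in reds/oranges (P/M), non-switchers in blues, empty sites
#' white; optionally grey out unmated cells.
#'
#' @param lattice a [Lattice-class].
#' @param mated optional mated matrix to overlay; unmated cells are dimmed.
#' @return a ggplot object.
#' @export
plotLattice <- function(lattice, mated = NULL) {
  codes <- gridCodes(lattice)
  df <- data.frame(row = as.vector(row(codes)), col = as.vector(col(codes)),
                   code = factor(as.vector(codes), levels = 0:4,
                                 labels = c("empty", "P switcher",
                                            "M switcher", "P non-switcher",
                                            "M non-switcher")))
  if (!is.null(mated)) df$mated <- as.vector(mated) == 1
  cols <- c("empty" = "white", "P switcher" = "#d7301f",
            "M switcher" = "#fc8d59", "P non-switcher" = "#74a9cf",
            "M non-switcher" = "#045a8d")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$code)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = cols, name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(mated))
    p <- p + ggplot2::geom_tile(data = df[!df$mated, ], fill = "white",
                                alpha = 0.6)
  p
}
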