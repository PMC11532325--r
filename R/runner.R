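## Orchestration of simulation experiments: single runs, the full
## 5 landscapes x 3 grazing regimes design, and file outputs.

#' Build a run configuration
#'
#' @param landscape Archetype id 1..5, shipped profile name, or an
#'   \code{\link{archetype_profile}}.
#' @param regime Scenario name ("none", "moderate", "overgrazing") or a
#'   \code{\link{grazing_scenario}}.
#' @param years Simulation horizon in years (default 50).
#' @param grid Grid dimensions (width, height), default c(100, 100).
#' @param cell_size Cell edge in meters (default 10).
#' @param seed RNG seed (default 0).
#' @param params Functional-group parameter set.
#' @param out_dir Optional output directory; when set,
#'   \code{\link{run_scenario}} writes the time series, final-abundance
#'   summary, initial/final dominance maps and a run-metadata file there.
#' @return A \code{run_config}.
#' @export
run_config <- function(landscape = 1, regime = "none", years = 50L,
                       grid = c(100L, 100L), cell_size = 10, seed = 0L,
                       params = fg_defaults(), out_dir = NULL) {
  years <- as.integer(years)
  if (years < 0L) stop("years must be >= 0", call. = FALSE)
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L)) {
    stop("grid must be two positive integers", call. = FALSE)
  }
  if (!inherits(regime, "grazing_scenario")) regime <- grazing_scenario(regime)
  structure(list(landscape = landscape, regime = regime, years = years,
                 grid = grid, cell_size = cell_size, seed = as.integer(seed),
                 params = params, out_dir = out_dir),
            class = "run_config")
}

.landscape_tag <- function(landscape) {
  if (inherits(landscape, "archetype_profile")) landscape$name
  else if (is.numeric(landscape)) sprintf("landscape%d", as.integer(landscape))
  else as.character(landscape)
}

#' Run one grazing scenario
#'
#' Initialises the landscape from the archetype profile, advances it
#' \code{years} annual steps and records the landscape-mean abundance of every
#' functional group each year (year 0 is the freshly initialised state). All
#' randomness (initialisation, grazed-cell choice, dispersal) flows from
#' \code{config$seed}, so identical configurations replay identically.
#'
#' @param config A \code{\link{run_config}}.
#' @return List with \code{series} (data.frame year, group, abundance),
#'   \code{initial} and \code{final} landscapes, and \code{config}.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  init <- init_landscape(config$landscape, dims = config$grid,
                         cell_size = config$cell_size, params = config$params)
  ls <- init
  groups <- ls$groups
  rec <- matrix(NA_real_, nrow = config$years + 1L, ncol = length(groups),
                dimnames = list(NULL, groups))
  rec[1L, ] <- landscape_abundance(ls)
  if (config$years > 0L) {
    for (y in seq_len(config$years)) {
      ls <- annual_step(ls, config$regime)
      rec[y + 1L, ] <- landscape_abundance(ls)
    }
  }
  series <- data.frame(
    year = rep(0:config$years, times = length(groups)),
    group = rep(groups, each = config$years + 1L),
    abundance = as.vector(rec), stringsAsFactors = FALSE)
  out <- list(series = series, initial = init, final = ls, config = config)
  if (!is.null(config$out_dir)) .write_run_outputs(out)
  out
}

.write_run_outputs <- function(run) {
  cfg <- run$config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- sprintf("%s_%s", .landscape_tag(cfg$landscape), cfg$regime$regime)
  utils::write.table(run$series, file.path(cfg$out_dir,
                                           sprintf("%s_series.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fin <- data.frame(group = run$initial$groups,
                    initial = unname(landscape_abundance(run$initial)),
                    final = unname(landscape_abundance(run$final)))
  utils::write.table(fin, file.path(cfg$out_dir, sprintf("%s_final.tsv", tag)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (when in c("initial", "final")) {
    map <- dominance_map(run[[when]])
    write_dominance_map(map, file.path(cfg$out_dir,
                                       sprintf("%s_%s_map.tsv", tag, when)))
    render_dominance_map(map, file.path(cfg$out_dir,
                                        sprintf("%s_%s_map.png", tag, when)),
                         title = sprintf("%s — %s (%s)", tag,
                                         cfg$regime$regime, when))
  }
  meta <- c(sprintf("landscape: %s", .landscape_tag(cfg$landscape)),
            sprintf("regime: %s (%.0f%% cells, %d events/year)",
                    cfg$regime$regime, 100 * cfg$regime$cell_fraction,
                    cfg$regime$events_per_year),
            sprintf("years: %d", cfg$years),
            sprintf("grid: %d x %d (cell %g m)", cfg$grid[1], cfg$grid[2],
                    cfg$cell_size),
            sprintf("seed: %d", cfg$seed),
            sprintf("steppesim version: %s",
                    as.character(utils::packageVersion("steppesim"))))
  writeLines(meta, file.path(cfg$out_dir, sprintf("%s_meta.txt", tag)))
  invisible(run)
}

#' Plan of the full simulation experiment
#'
#' @param landscapes Archetype ids (default 1:5).
#' @param regimes Regime names (default all three).
#' @return data.frame of all landscape x regime combinations.
#' @export
experiment_plan <- function(landscapes = 1:5,
                            regimes = c("none", "moderate", "overgrazing")) {
  expand.grid(landscape = landscapes, regime = regimes,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run the full experiment (every landscape under every grazing regime)
#'
#' Each combination is run once (the model is deterministic apart from the
#' seeded dispersal module). Every run uses the same seed so that regimes are
#' compared on identically initialised landscapes.
#'
#' @param landscapes,regimes As \code{\link{experiment_plan}}.
#' @param years,grid,cell_size,seed,params,out_dir As \code{\link{run_config}}.
#' @param quiet Suppress per-run progress messages (default TRUE).
#' @param keep_landscapes Keep the initial and final landscape objects of
#'   every run in memory (default FALSE: a full 100 x 100 experiment would
#'   otherwise hold 30 grids).
#' @return List with \code{summary} (tidy long data.frame: landscape, regime,
#'   group, year, abundance), \code{final} (final-abundance table) and
#'   \code{runs} (the individual run results).
#' @export
run_experiment <- function(landscapes = 1:5,
                           regimes = c("none", "moderate", "overgrazing"),
                           years = 50L, grid = c(100L, 100L), cell_size = 10,
                           seed = 0L, params = fg_defaults(), out_dir = NULL,
                           quiet = TRUE, keep_landscapes = FALSE) {
  plan <- experiment_plan(landscapes, regimes)
  runs <- vector("list", nrow(plan))
  pieces <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    if (!quiet) {
      message(sprintf("[steppesim] landscape %s, %s grazing",
                      plan$landscape[i], plan$regime[i]))
    }
    cfg <- run_config(plan$landscape[i], plan$regime[i], years = years,
                      grid = grid, cell_size = cell_size, seed = seed,
                      params = params, out_dir = out_dir)
    runs[[i]] <- run_scenario(cfg)
    if (!keep_landscapes) runs[[i]]$initial <- runs[[i]]$final <- NULL
    s <- runs[[i]]$series
    s$landscape <- .landscape_tag(plan$landscape[i])
    s$regime <- plan$regime[i]
    pieces[[i]] <- s[, c("landscape", "regime", "group", "year", "abundance")]
  }
  summary <- do.call(rbind, pieces)
  final <- summary[summary$year == max(summary$year), ]
  names(runs) <- sprintf("%s_%s", vapply(plan$landscape, .landscape_tag,
                                         character(1)), plan$regime)
  if (!is.null(out_dir)) {
    utils::write.table(summary, file.path(out_dir, "experiment_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summary = summary, final = final, runs = runs, plan = plan)
}
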