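## Grid state container, archetype profiles, initialisation, summaries, I/O.
##
## State layout: one abundance matrix per functional group with one row per
## cell (row-major, 0-based (row, col) coordinates) and one column per age
## 0..max_age. Age 0 holds the current year's germinant cohort; ages >= 1 are
## established plants. A separate n_cells x n_groups matrix holds the
## transient propagule pool (seed events awaiting germination).

.cell_index <- function(ls, row, col) row * ls$width + col + 1L

#' Create an empty landscape
#'
#' @param dims Integer (width, height) in cells; default 100 x 100.
#' @param cell_size Cell edge length in meters (default 10).
#' @param params Functional-group parameter set (default packaged set).
#' @return A \code{steppe_landscape} with every cell empty.
#' @export
empty_landscape <- function(dims = c(100L, 100L), cell_size = 10,
                            params = fg_defaults()) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims < 1L)) {
    stop("dims must be two positive integers (width, height)", call. = FALSE)
  }
  n <- dims[1] * dims[2]
  # age matrices start with the germinant column only and grow as cohorts age
  ab <- lapply(params, function(g) matrix(0, nrow = n, ncol = 1L))
  structure(list(
    width = dims[1], height = dims[2], cell_size = cell_size,
    params = params, groups = names(params),
    ab = ab,
    seeds = matrix(0, nrow = n, ncol = length(params),
                   dimnames = list(NULL, names(params)))
  ), class = "steppe_landscape")
}

n_cells <- function(ls) ls$width * ls$height

#' @export
print.steppe_landscape <- function(x, ...) {
  cat(sprintf("<steppe_landscape> %d x %d cells (%g m each)\n",
              x$width, x$height, x$cell_size))
  ab <- landscape_abundance(x)
  for (g in names(ab)) cat(sprintf("  %-20s %6.2f %%\n", g, ab[[g]]))
  invisible(x)
}

#' Default stage mix for initial populations
#'
#' The propagule share is fixed at 0.2; the plant share (0.8) is split
#' between immature and mature in proportion to the time a plant spends in
#' each stage ((mature_age - 1) : (max_age - mature_age + 1)), so long-lived,
#' late-maturing groups start as essentially mature stands while short-lived
#' groups carry a substantial immature fraction.
#'
#' @param params An \code{fg_params} object.
#' @return Named numeric (propagule, immature, mature) summing to 1.
#' @export
default_stage_mix <- function(params) {
  im_dur <- max(0L, params$mature_age - 1L)
  ma_dur <- params$max_age - params$mature_age + 1L
  im <- 0.8 * im_dur / (im_dur + ma_dur)
  c(propagule = 0.2, immature = im, mature = 0.8 - im)
}

#' Construct a landscape archetype profile
#'
#' @param targets Named numeric of per-group target mean abundance (percent,
#'   0..100); names are functional-group ids (informal names accepted).
#' @param stage_mix Optional named list of per-group stage mixes, each a
#'   numeric (propagule, immature, mature) summing to 1; groups not listed
#'   use \code{\link{default_stage_mix}}.
#' @param name Optional profile label.
#' @return An \code{archetype_profile}.
#' @export
archetype_profile <- function(targets, stage_mix = NULL, name = "custom") {
  names(targets) <- .normalize_group(names(targets))
  if (any(targets < 0 | targets > 100)) {
    stop("profile target percentages must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(stage_mix)) {
    names(stage_mix) <- .normalize_group(names(stage_mix))
    for (m in stage_mix) {
      if (length(m) != 3L || abs(sum(m) - 1) > 1e-8 || any(m < 0)) {
        stop("each stage mix needs 3 non-negative shares summing to 1",
             call. = FALSE)
      }
    }
  }
  structure(list(name = name, targets = targets, stage_mix = stage_mix),
            class = "archetype_profile")
}

#' Shipped landscape archetype profiles
#'
#' Five vegetation types of the Central Anatolian steppe belt: (1)
#' tree-dominated woodland steppe, (2) woodland steppe with less abundant
#' trees, (3) herbaceous-dominated steppe with abundant non-spiny subshrubs,
#' (4) non-spiny subshrub-dominated steppe with low total abundance, and (5)
#' spiny subshrub-dominated steppe. Tree means are 50% (type 1) and 10%
#' (type 2); the remaining targets encode the verbal type descriptions and
#' can be overridden via \code{\link{archetype_profile}}.
#'
#' @return Named list of five \code{archetype_profile} objects
#'   ("landscape1" .. "landscape5").
#' @export
archetype_profiles <- function() {
  mk <- function(i, label, ...) {
    archetype_profile(c(...), name = label)
  }
  list(
    landscape1 = mk(1, "tree-dominated woodland steppe",
                    resprouter_tree = 50, non_spiny_subshrub = 10,
                    spiny_subshrub = 10, perennial_forb = 15,
                    perennial_gramineae = 15, annual = 2),
    landscape2 = mk(2, "woodland steppe with less abundant trees",
                    resprouter_tree = 10, non_spiny_subshrub = 25,
                    spiny_subshrub = 20, perennial_forb = 20,
                    perennial_gramineae = 25, annual = 3),
    landscape3 = mk(3, "herbaceous-dominated steppe with abundant non-spiny subshrubs",
                    resprouter_tree = 0, non_spiny_subshrub = 30,
                    spiny_subshrub = 10, perennial_forb = 25,
                    perennial_gramineae = 25, annual = 6),
    landscape4 = mk(4, "non-spiny subshrub-dominated steppe with low total abundance",
                    resprouter_tree = 0, non_spiny_subshrub = 25,
                    spiny_subshrub = 5, perennial_forb = 10,
                    perennial_gramineae = 10, annual = 3),
    landscape5 = mk(5, "spiny subshrub-dominated steppe",
                    resprouter_tree = 0, non_spiny_subshrub = 10,
                    spiny_subshrub = 40, perennial_forb = 15,
                    perennial_gramineae = 15, annual = 3)
  )
}

#' Initialise a landscape from an archetype profile
#'
#' For each group, cells are occupied independently with probability p and an
#' occupied cell receives a dense within-cell plant abundance
#' A ~ Uniform(0.75, 1) (mean 0.875), with p = target / 87.5 so that the
#' expected landscape mean equals the profile target. Occupied cells carry
#' dense local cover — an established stand covers most of its own 10 m cell
#' — and the landscape mean is set through occupancy, mirroring a vegetation
#' mosaic of well-vegetated patches and gaps. For targets above 87.5% every
#' cell is occupied and A ~ Uniform(2t - 1, 1) (t the target as a fraction).
#' The plant abundance is split between an immature
#' cohort (random age in 1..mature_age-1) and a mature cohort (random age in
#' mature_age..min(max_age - 1, 2 mature_age)) according to the stage mix;
#' the propagule share seeds the initial propagule pool.
#'
#' @param profile An \code{archetype_profile} (or the 1-based index / name of
#'   a shipped profile).
#' @param dims,cell_size,params As \code{\link{empty_landscape}}.
#' @return A \code{steppe_landscape}. Uses the current RNG state.
#' @export
init_landscape <- function(profile, dims = c(100L, 100L), cell_size = 10,
                           params = fg_defaults()) {
  if (is.numeric(profile) || (is.character(profile) && length(profile) == 1L &&
                              !inherits(profile, "archetype_profile"))) {
    shipped <- archetype_profiles()
    profile <- if (is.numeric(profile)) shipped[[as.integer(profile)]]
               else shipped[[profile]]
    if (is.null(profile)) stop("unknown archetype id", call. = FALSE)
  }
  stopifnot(inherits(profile, "archetype_profile"))
  ls <- empty_landscape(dims, cell_size, params)
  n <- n_cells(ls)
  bad <- setdiff(names(profile$targets), ls$groups)
  if (length(bad)) {
    stop(sprintf("unknown group '%s' in profile", bad[1]), call. = FALSE)
  }
  # Place taller groups first and restrict each group to cells where its
  # mature stage survives the resource level set by the already-placed
  # canopy: the initial state is a viable standing community, not a random
  # scatter that partially dies off in year one. Occupancy is scaled so the
  # expected landscape mean still equals the target.
  occ_strata <- matrix(0, n, .N_STRATA)
  ord <- names(sort(vapply(ls$params[names(profile$targets)], `[[`,
                           integer(1), "stratum_mature"), decreasing = TRUE))
  for (g in ord) {
    t_pct <- profile$targets[[g]]
    if (t_pct <= 0) next
    p <- ls$params[[g]]
    t <- t_pct / 100
    sm <- p$stratum_mature
    shade <- if (sm < .N_STRATA)
      rowSums(occ_strata[, (sm + 1L):.N_STRATA, drop = FALSE]) else numeric(n)
    th <- abundance_thresholds()
    res <- 3L - findInterval(shade, c(th[["low"]], th[["medium"]]))
    suitable <- which(p$survival["mature", ][res])
    if (!length(suitable)) next
    # perennial and woody groups form dense patches; short-lived therophytes
    # stand as diffuse, lower-cover carpets spread over more cells
    A_range <- if (p$max_age <= 2L) c(0.25, 0.75) else c(0.75, 1)
    mean_A <- mean(A_range)
    p_occ <- min(1, (t / mean_A) * n / length(suitable))
    if (t <= mean_A) {
      occ <- suitable[stats::runif(length(suitable)) < p_occ]
      A <- stats::runif(length(occ), A_range[1], A_range[2])
    } else {
      occ <- seq_len(n)
      A <- stats::runif(n, 2 * t - 1, 1)
    }
    if (length(occ) == 0L) next
    # initial mature cohorts sit in the younger mature ages (up to twice the
    # maturation age), consistent with long-grazed, recently established stands
    hi <- max(p$mature_age, min(p$max_age - 1L, 2L * p$mature_age))
    ls <- .ensure_age(ls, g, hi)
    mix <- if (!is.null(profile$stage_mix) && !is.null(profile$stage_mix[[g]]))
      profile$stage_mix[[g]] else default_stage_mix(p)
    plant <- mix[2] + mix[3]
    im_f <- if (plant > 0) mix[2] / plant else 0
    if (p$mature_age < 2L) im_f <- 0  # no immature stage exists
    if (im_f > 0) {
      ages_im <- sample.int(p$mature_age - 1L, length(occ), replace = TRUE)
      idx <- cbind(occ, ages_im + 1L)
      ls$ab[[g]][idx] <- ls$ab[[g]][idx] + A * im_f
    }
    ages_ma <- p$mature_age - 1L +
      sample.int(hi - p$mature_age + 1L, length(occ), replace = TRUE)
    idx <- cbind(occ, ages_ma + 1L)
    ls$ab[[g]][idx] <- ls$ab[[g]][idx] + A * (1 - im_f)
    occ_strata[occ, p$stratum_mature] <-
      occ_strata[occ, p$stratum_mature] + A * (1 - im_f)
    occ_strata[occ, p$stratum_immature] <-
      occ_strata[occ, p$stratum_immature] + A * im_f * p$size_class / 4
    if (mix[1] > 0 && p$fecundity > 0) {
      # a propagule-carrying cell holds a full year's local seed rain
      ls$seeds[occ, g] <- ls$seeds[occ, g] + p$fecundity
    }
  }
  ls
}

# Established (age >= 1) per-cell abundance of one group.
.established <- function(ls, group) {
  m <- ls$ab[[group]]
  rowSums(m[, -1L, drop = FALSE])
}

# Per-cell total including the current germinant cohort (cap accounting).
.group_total <- function(ls, group) rowSums(ls$ab[[group]])

#' Landscape-mean abundance (percent)
#'
#' 100 times the mean over all cells of the group's established plant cover
#' (immature plus mature cohorts; the transient germinant cohort and the
#' propagule pool do not count as standing vegetation).
#'
#' @param ls A \code{steppe_landscape}.
#' @param group Group id (informal names accepted), or NULL for all groups.
#' @return Percent in [0, 100]; named vector when \code{group} is NULL.
#' @export
landscape_abundance <- function(ls, group = NULL) {
  if (is.null(group)) {
    return(vapply(ls$groups, function(g) landscape_abundance(ls, g),
                  numeric(1)))
  }
  g <- .normalize_group(group)
  if (!g %in% ls$groups) stop(sprintf("unknown group '%s'", group), call. = FALSE)
  100 * sum(.established(ls, g)) / n_cells(ls)
}

#' Per-cell dominant functional group
#'
#' Labels each cell with the group of maximal established abundance. Ties are
#' broken in favour of the group with the taller mature stratum, then by
#' canonical group order; cells with no established plants are "empty".
#'
#' @param ls A \code{steppe_landscape}.
#' @return Character matrix (height x width; row r, column c is grid cell
#'   (r-1, c-1)) of group ids or "empty".
#' @export
dominance_map <- function(ls) {
  strata <- vapply(ls$params, `[[`, integer(1), "stratum_mature")
  ord <- order(-strata, seq_along(ls$groups))
  tot <- vapply(ls$groups[ord], function(g) .established(ls, g),
                numeric(n_cells(ls)))
  if (is.null(dim(tot))) tot <- matrix(tot, nrow = 1)
  win <- max.col(tot, ties.method = "first")
  lab <- ls$groups[ord][win]
  lab[rowSums(tot) == 0] <- "empty"
  matrix(lab, nrow = ls$height, ncol = ls$width, byrow = TRUE)
}

#' Tabulate all cohorts of a landscape
#'
#' @param ls A \code{steppe_landscape}.
#' @return data.frame with columns row, col (0-based), group, stage, age,
#'   abundance — one row per non-empty cohort, plus one "propagule" row per
#'   cell with pending seed events (abundance = event count).
#' @export
cohorts <- function(ls) {
  out <- list()
  for (g in ls$groups) {
    m <- ls$ab[[g]]
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      cell <- nz[, 1] - 1L
      age <- nz[, 2] - 1L  # column j holds age j - 1
      out[[g]] <- data.frame(
        row = cell %/% ls$width, col = cell %% ls$width,
        group = g, stage = stage_of_age(ls$params[[g]], age),
        age = age, abundance = m[nz], stringsAsFactors = FALSE)
    }
  }
  sd <- which(ls$seeds > 0, arr.ind = TRUE)
  if (nrow(sd)) {
    cell <- sd[, 1] - 1L
    out$propagules <- data.frame(
      row = cell %/% ls$width, col = cell %% ls$width,
      group = ls$groups[sd[, 2]], stage = "propagule", age = 0L,
      abundance = ls$seeds[sd], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(row = integer(), col = integer(), group = character(),
                      stage = character(), age = integer(),
                      abundance = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$row, res$col, res$group, res$age), , drop = FALSE]
}

#' Place a cohort in a landscape (mainly for tests and small examples)
#'
#' @param ls A \code{steppe_landscape}.
#' @param row,col 0-based cell coordinates.
#' @param group Group id (informal names accepted).
#' @param age Cohort age in years (0 = germinant).
#' @param abundance Abundance in [0, 1]; the per-cell group total is capped
#'   at 1 (saturating addition).
#' @return The modified landscape.
#' @export
place_cohort <- function(ls, row, col, group, age, abundance) {
  g <- .normalize_group(group)
  if (!g %in% ls$groups) stop(sprintf("unknown group '%s'", group), call. = FALSE)
  p <- ls$params[[g]]
  if (age < 0 || age > p$max_age) stop("age outside 0..max_age", call. = FALSE)
  if (abundance < 0 || abundance > 1) stop("abundance outside [0, 1]", call. = FALSE)
  if (row < 0 || row >= ls$height || col < 0 || col >= ls$width) {
    stop("cell coordinates outside the grid", call. = FALSE)
  }
  ls <- .ensure_age(ls, g, age)
  i <- .cell_index(ls, row, col)
  headroom <- 1 - .group_total(ls, g)[i]
  ls$ab[[g]][i, age + 1L] <- ls$ab[[g]][i, age + 1L] + min(abundance, headroom)
  ls
}

#' Write / read landscape state
#'
#' Lossless tabular text round-trip of grid dimensions, cohorts and the
#' propagule pool. The format is tab-separated with a header line
#' \code{row col group stage age abundance}, preceded by one comment line
#' carrying the grid geometry.
#'
#' @param ls A \code{steppe_landscape}.
#' @param path File path.
#' @return \code{write_state}: \code{path} invisibly; \code{read_state}: the
#'   landscape.
#' @export
write_state <- function(ls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# steppesim-landscape width=%d height=%d cell_size=%g",
                     ls$width, ls$height, ls$cell_size), con)
  utils::write.table(cohorts(ls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_state
#' @param params Parameter set used to rebuild the landscape.
#' @export
read_state <- function(path, params = fg_defaults()) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# steppesim-landscape ", lines[1])) {
    stop("line 1: missing landscape header comment", call. = FALSE)
  }
  geom <- regmatches(lines[1], gregexpr("[a-z_]+=[0-9.]+", lines[1]))[[1]]
  kv <- stats::setNames(
    as.numeric(sub(".*=", "", geom)), sub("=.*", "", geom))
  for (fld in c("width", "height", "cell_size")) {
    if (is.na(kv[fld])) stop("line 1: malformed geometry header", call. = FALSE)
  }
  ls <- empty_landscape(c(kv[["width"]], kv[["height"]]), kv[["cell_size"]],
                        params)
  df <- tryCatch(
    utils::read.table(text = lines[-1], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("parse error after line 2: %s",
                                     conditionMessage(e)), call. = FALSE))
  if (!nrow(df)) return(ls)
  need <- c("row", "col", "group", "stage", "age", "abundance")
  if (!all(need %in% names(df))) {
    stop("line 2: header must name row, col, group, stage, age, abundance",
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    line_no <- i + 2L
    if (!r$group %in% ls$groups) {
      stop(sprintf("line %d: unknown group '%s'", line_no, r$group),
           call. = FALSE)
    }
    if (r$row < 0 || r$row >= ls$height || r$col < 0 || r$col >= ls$width) {
      stop(sprintf("line %d: cell (%d, %d) outside grid", line_no, r$row, r$col),
           call. = FALSE)
    }
    idx <- .cell_index(ls, r$row, r$col)
    if (r$stage == "propagule") {
      ls$seeds[idx, r$group] <- ls$seeds[idx, r$group] + r$abundance
    } else {
      p <- ls$params[[r$group]]
      if (r$age < 0 || r$age > p$max_age || r$abundance < 0 || r$abundance > 1) {
        stop(sprintf("line %d: age or abundance out of range", line_no),
             call. = FALSE)
      }
      ls <- .ensure_age(ls, r$group, r$age)
      ls$ab[[r$group]][idx, r$age + 1L] <- r$abundance
    }
  }
  ls
}

#' Write a dominance map as a delimited label matrix
#'
#' @param map A matrix from \code{\link{dominance_map}}.
#' @param path File path.
#' @return \code{path}, invisibly.
#' @export
write_dominance_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Render a dominance map to PNG
#'
#' Bird's-eye view with the conventional colouring: trees green, non-spiny
#' subshrubs red, spiny subshrubs purple, perennial forbs orange, perennial
#' gramineae blue, annual herbs grey; empty cells white.
#'
#' @param map A matrix from \code{\link{dominance_map}}.
#' @param path Output PNG path.
#' @param title Optional plot title.
#' @return \code{path}, invisibly.
#' @export
render_dominance_map <- function(map, path, title = NULL) {
  pal <- c(empty = "#FFFFFF",
           resprouter_tree = "#2E8B57", non_spiny_subshrub = "#D62728",
           spiny_subshrub = "#7B3FA0", perennial_forb = "#FF8C00",
           perennial_gramineae = "#1F77B4", annual = "#9E9E9E")
  lv <- names(pal)
  z <- matrix(match(map, lv), nrow = nrow(map))
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, if (is.null(title)) 1 else 3, 1))
  graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = pal, zlim = c(1, length(lv)),
                  axes = FALSE, main = title)
  invisible(path)
}
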