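## The annual demographic step: aging and stage promotion, stratum-based
## resource levels, survival, seed rain and germination.
##
## Sub-step order within a year: (1) grazing disturbance, (2) aging /
## promotion / senescence, (3) per-cell per-stratum resource computation,
## (4) survival pass, (5) seed production and dispersal, (6) germination.

# A group whose total abundance in a cell falls below this floor (about one
# plant on a 10 m x 10 m cell) is not demographically viable and is removed
# after lossy sub-steps. Every newborn germinant cohort lies above it
# (minimum fraction x seed saturation = 0.25 * 1/5), so the floor only
# retires grazed or shaded-out remnants. The floor applies to the cell's
# whole population of the group, not to single cohorts, so age structure
# fragmented by resprout age-resets is not penalised.
.MIN_AB <- 0.01

.prune <- function(m) {
  tot <- rowSums(m)
  dead <- tot > 0 & tot < .MIN_AB
  if (any(dead)) m[dead, ] <- 0
  m
}

.N_STRATA <- 5L

# Age matrices carry columns only up to the oldest living cohort (column j is
# age j - 1); they grow by one column per year until max_age is reachable.
# Column ranges of the immature and mature stages given the current width.
.imm_cols <- function(p, nc) {
  if (nc < 2L || p$mature_age < 2L) integer(0) else 2L:min(p$mature_age, nc)
}
.mat_cols <- function(p, nc) {
  if (nc < p$mature_age + 1L) integer(0) else (p$mature_age + 1L):nc
}

# Pad a group's age matrix with zero columns so that `age` is addressable.
.ensure_age <- function(ls, g, age) {
  nc <- ncol(ls$ab[[g]])
  if (nc < age + 1L) {
    ls$ab[[g]] <- cbind(ls$ab[[g]],
                        matrix(0, nrow(ls$ab[[g]]), age + 1L - nc))
  }
  ls
}

# n_cells x 5 matrix of shading scores: column s holds the weighted abundance
# of cohorts occupying strata strictly above s. Matures weigh 1, immatures
# and germinants size_class / 4 (relative height).
.shading_scores <- function(ls) {
  n <- n_cells(ls)
  occ <- matrix(0, n, .N_STRATA)
  for (g in ls$groups) {
    p <- ls$params[[g]]
    m <- ls$ab[[g]]
    w_im <- p$size_class / 4
    mc <- .mat_cols(p, ncol(m))
    if (length(mc)) {
      occ[, p$stratum_mature] <- occ[, p$stratum_mature] +
        rowSums(m[, mc, drop = FALSE])
    }
    ic <- .imm_cols(p, ncol(m))
    if (length(ic)) {
      occ[, p$stratum_immature] <- occ[, p$stratum_immature] +
        rowSums(m[, ic, drop = FALSE]) * w_im
    }
    occ[, 1L] <- occ[, 1L] + m[, 1L] * w_im  # germinants sit in stratum 1
  }
  S <- matrix(0, n, .N_STRATA)
  above <- numeric(n)
  for (s in (.N_STRATA - 1L):1L) {
    above <- above + occ[, s + 1L]
    S[, s] <- above
  }
  S
}

# Integer resource codes per cell per stratum: 1 low, 2 medium, 3 high.
.resource_codes <- function(S) {
  th <- abundance_thresholds()
  matrix(3L - findInterval(S, c(th[["low"]], th[["medium"]])),
         nrow = nrow(S))
}

#' Resource level available at a stratum of one cell
#'
#' Taller plants pre-empt light: the shading score of a stratum is the
#' abundance-weighted cover of cohorts in strictly higher strata (matures
#' weigh 1, immatures and germinants size_class/4). Scores below 0.33 leave
#' the resource level high, scores in [0.33, 0.66) medium, and denser shade
#' low.
#'
#' @param ls A \code{steppe_landscape}.
#' @param row,col 0-based cell coordinates.
#' @param stratum Canopy layer 1..5.
#' @return "low", "medium" or "high".
#' @export
compute_resource <- function(ls, row, col, stratum) {
  stratum <- as.integer(stratum)
  if (length(stratum) != 1L || is.na(stratum) || stratum < 1L ||
      stratum > .N_STRATA) {
    stop("stratum must be in 1..5", call. = FALSE)
  }
  S <- .shading_scores(ls)
  .resource_levels[.resource_codes(S)[.cell_index(ls, row, col), stratum]]
}

# Aging: every cohort gets one year older; germinants become immature (or
# mature for groups maturing at age 1); cohorts beyond max_age die.
.age_pass <- function(ls) {
  for (g in ls$groups) {
    m <- ls$ab[[g]]
    nc <- ncol(m)
    if (nc == ls$params[[g]]$max_age + 1L) {
      # the oldest cohort would exceed max_age: senescence
      ls$ab[[g]] <- cbind(0, m[, -nc, drop = FALSE])
    } else {
      ls$ab[[g]] <- cbind(0, m)
    }
  }
  ls
}

# Survival pass: a cohort is removed iff its (stage, resource) survival entry
# is FALSE, with the resource evaluated at the cohort's stratum.
.survival_pass <- function(ls, res) {
  for (g in ls$groups) {
    p <- ls$params[[g]]
    m <- ls$ab[[g]]
    nc <- ncol(m)
    blocks <- list(
      germinant = list(cols = 1L, stratum = 1L),
      immature = list(cols = .imm_cols(p, nc), stratum = p$stratum_immature),
      mature = list(cols = .mat_cols(p, nc), stratum = p$stratum_mature)
    )
    for (stg in names(blocks)) {
      b <- blocks[[stg]]
      if (!length(b$cols)) next
      surv <- p$survival[stg, ]                     # logical by resource
      dies <- !surv[res[, b$stratum]]
      if (any(dies)) m[dies, b$cols] <- 0
    }
    ls$ab[[g]] <- m
  }
  ls
}

.disperse_pass <- function(ls) {
  n <- n_cells(ls)
  for (g in ls$groups) {
    ev <- .disperse_group(ls, g)
    if (length(ev$target)) {
      ls$seeds[, g] <- ls$seeds[, g] + tabulate(ev$target, nbins = n)
    }
  }
  ls
}

#' Germinant abundance produced by a seed pool
#'
#' A germinant cohort forms when at least one seed event reached the cell,
#' the group's germination level at the cell's ground-stratum resource is
#' positive, and germinants can survive that resource level. Its abundance is
#' the germination fraction times the seed saturation
#' \code{min(1, events / fecundity)}.
#'
#' @param params An \code{fg_params} object.
#' @param resource "low", "medium" or "high" (resource at stratum 1).
#' @param events Number of seed events that reached the cell this year.
#' @return Abundance of the new germinant cohort (0 when none forms).
#' @export
germination_abundance <- function(params, resource, events) {
  resource <- match.arg(resource, .resource_levels)
  if (events < 1) return(0)
  if (!params$survival["germinant", resource]) return(0)
  rate <- params$germination_rate[[resource]]
  level_to_fraction(rate) * min(1, events / max(1L, params$fecundity))
}

.germination_pass <- function(ls, res) {
  r1 <- res[, 1L]
  for (g in ls$groups) {
    p <- ls$params[[g]]
    ev <- ls$seeds[, g]
    frac <- level_to_fraction(p$germination_rate)[r1]
    gsurv <- p$survival["germinant", ][r1]
    ab0 <- frac * pmin(1, ev / max(1L, p$fecundity)) * (ev >= 1) * gsurv
    headroom <- pmax(0, 1 - .group_total(ls, g))
    ab0 <- pmin(ab0, headroom)
    ab0[ab0 < .MIN_AB] <- 0
    ls$ab[[g]][, 1L] <- ab0
  }
  ls$seeds[] <- 0
  ls
}

#' Advance a landscape by one year
#'
#' Applies, in order: grazing disturbance, aging/promotion/senescence,
#' resource computation, survival, seed production and dispersal, and
#' germination. Dispersal (and the choice of grazed cells) uses the current
#' RNG state; everything else is deterministic.
#'
#' @param ls A \code{steppe_landscape}.
#' @param scenario A \code{\link{grazing_scenario}}; grazing exclusion when
#'   omitted.
#' @return The landscape one year on.
#' @export
annual_step <- function(ls, scenario = grazing_scenario("none")) {
  grazed <- select_grazed_cells(ls, scenario)
  ls <- apply_grazing(ls, grazed, scenario)
  ls <- .age_pass(ls)
  res <- .resource_codes(.shading_scores(ls))
  ls <- .survival_pass(ls, res)
  ls <- .disperse_pass(ls)
  ls <- .germination_pass(ls, res)
  ls
}
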