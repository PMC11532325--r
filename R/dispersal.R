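## Stochastic seed dispersal on the lattice.
##
## A seed first draws a distance band -- short [0, l1), medium [l1, l2) or
## long [l2, Inf) -- with probabilities proportional to the fractional value
## of the band's capacity level. Within the short and medium bands the
## distance is uniform; beyond the medium limit the density decays
## exponentially, at rate k1 per long-band width (l3 - l2) out to the long
## limit l3 and at the steeper rate k2 beyond it. Direction is uniform on the
## circle and the seed lands in the cell containing the sampled point;
## off-grid seeds are lost (absorbing boundary).

#' Band-choice probabilities of a dispersal specification
#'
#' Dispersal capacity uses a 4-level scale (No, Low, Med, High) whose weights
#' double per level: No = 0, Low = 0.25, Med = 0.5, High = 1. A seed picks
#' the short, medium or long band with probability proportional to its
#' band's weight (e.g. High/Med/Low gives (1, 0.5, 0.25)/1.75).
#'
#' @param dispersal The \code{dispersal} element of an \code{fg_params}.
#' @return Numeric length 3 (short, medium, long) summing to 1, or all zero
#'   when every band capacity is 0.
#' @export
dispersal_band_probs <- function(dispersal) {
  lv <- c(dispersal$s_rate, dispersal$m_rate, dispersal$h_rate)
  w <- ifelse(lv == 0, 0, 2^(lv - 3))
  if (sum(w) == 0) return(c(short = 0, medium = 0, long = 0))
  stats::setNames(w / sum(w), c("short", "medium", "long"))
}

# Inverse-CDF sampler for the long-band distance offset t = d - l2 >= 0.
# Piecewise exponential: f(t) prop exp(-k1 t / W) on [0, W),
# exp(-k1) * exp(-k2 (t - W) / W) on [W, Inf), W = l3 - l2.
.sample_long_offset <- function(n, k_disp, W) {
  k1 <- k_disp[1]; k2 <- k_disp[2]
  massA <- W * (1 - exp(-k1)) / k1
  massB <- W * exp(-k1) / k2
  pA <- massA / (massA + massB)
  u <- stats::runif(n)
  v <- stats::runif(n)
  t <- numeric(n)
  head <- u < pA
  t[head] <- -W / k1 * log(1 - v[head] * (1 - exp(-k1)))
  t[!head] <- W - W / k2 * log(v[!head])
  t
}

#' Sample seed dispersal distances
#'
#' @param n Number of seeds.
#' @param dispersal The \code{dispersal} element of an \code{fg_params}.
#' @return Numeric vector of n distances in meters; length 0 with a warning
#'   if every band capacity is zero.
#' @export
sample_dispersal_distances <- function(n, dispersal) {
  pr <- dispersal_band_probs(dispersal)
  if (sum(pr) == 0 || n == 0) return(numeric(0))
  l <- dispersal$limits
  band <- sample.int(3L, n, replace = TRUE, prob = pr)
  d <- numeric(n)
  ns <- sum(band == 1L); nm <- sum(band == 2L); nl <- sum(band == 3L)
  if (ns) d[band == 1L] <- stats::runif(ns, 0, l[1])
  if (nm) d[band == 2L] <- stats::runif(nm, l[1], l[2])
  if (nl) d[band == 3L] <- l[2] + .sample_long_offset(nl, dispersal$k_disp,
                                                      l[3] - l[2])
  d
}

# Core dispersal draw for one group: returns the in-bounds landing cell index
# (1-based) of every seed, one entry per seed, plus the emitting cell.
.disperse_group <- function(ls, g) {
  p <- ls$params[[g]]
  if (p$fecundity == 0L) return(list(src = integer(0), target = integer(0)))
  mc <- .mat_cols(p, ncol(ls$ab[[g]]))
  if (!length(mc)) return(list(src = integer(0), target = integer(0)))
  src_cells <- which(rowSums(ls$ab[[g]][, mc, drop = FALSE]) > 0)
  if (!length(src_cells)) return(list(src = integer(0), target = integer(0)))
  src <- rep(src_cells, each = p$fecundity)
  n <- length(src)
  d <- sample_dispersal_distances(n, p$dispersal)
  if (!length(d)) return(list(src = integer(0), target = integer(0)))
  theta <- stats::runif(n, 0, 2 * pi)
  cell0 <- src - 1L
  # seeds leave from a uniform point within the source cell: mother plants
  # are spread over the cell, not stacked at its centre
  x <- (cell0 %% ls$width + stats::runif(n)) * ls$cell_size + d * cos(theta)
  y <- (cell0 %/% ls$width + stats::runif(n)) * ls$cell_size + d * sin(theta)
  col <- floor(x / ls$cell_size)
  row <- floor(y / ls$cell_size)
  ok <- col >= 0 & col < ls$width & row >= 0 & row < ls$height
  list(src = src[ok], target = as.integer(row[ok] * ls$width + col[ok] + 1L))
}

#' Produce and disperse one year's seed rain for a group
#'
#' Every cell holding mature plants of the group releases \code{fecundity}
#' seeds. Returns the surviving (in-grid) seed events.
#'
#' @param ls A \code{steppe_landscape}.
#' @param group Group id (informal names accepted).
#' @return data.frame with columns src_row, src_col, row, col (0-based), one
#'   row per seed that landed inside the grid. Uses the current RNG state.
#' @export
seed_events <- function(ls, group) {
  g <- .normalize_group(group)
  if (!g %in% ls$groups) stop(sprintf("unknown group '%s'", group), call. = FALSE)
  ev <- .disperse_group(ls, g)
  s0 <- ev$src - 1L; t0 <- ev$target - 1L
  data.frame(src_row = s0 %/% ls$width, src_col = s0 %% ls$width,
             row = t0 %/% ls$width, col = t0 %% ls$width)
}
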