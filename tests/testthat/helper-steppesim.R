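# Shared fixtures and independent oracles for the test suite.

PARAMS <- fg_defaults()

# A small landscape with one cohort placed by hand.
one_cohort_landscape <- function(group, age, abundance = 1, dims = c(5, 5),
                                 row = 2, col = 2) {
  ls <- empty_landscape(dims, cell_size = 10, params = PARAMS)
  place_cohort(ls, row, col, group, age, abundance)
}

# Independent brute-force oracle for the age-class partition: the smallest i
# with age < breakpoints[i] (0-based), else the number of breakpoints.
age_class_bruteforce <- function(age, breakpoints) {
  for (i in seq_along(breakpoints)) {
    if (age < breakpoints[i]) return(i - 1L)
  }
  length(breakpoints)
}

# Independent rejection sampler of the dispersal distance kernel: uniform
# proposals over [0, d_max] accepted proportionally to the piecewise density
# (uniform within the short and medium bands, two-rate exponential tail).
dispersal_rejection_oracle <- function(n, dispersal) {
  lv <- c(dispersal$s_rate, dispersal$m_rate, dispersal$h_rate)
  w <- ifelse(lv == 0, 0, 2^(lv - 3))  # 4-level capacity scale, doubling
  pr <- w / sum(w)
  l <- dispersal$limits
  k1 <- dispersal$k_disp[1]; k2 <- dispersal$k_disp[2]
  W <- l[3] - l[2]
  dens <- function(d) {
    out <- numeric(length(d))
    s <- d < l[1]
    m <- d >= l[1] & d < l[2]
    t1 <- d >= l[2] & d < l[3]
    t2 <- d >= l[3]
    out[s] <- pr[1] / l[1]
    out[m] <- pr[2] / (l[2] - l[1])
    # long band normalisation: mass W(1-exp(-k1))/k1 + W exp(-k1)/k2
    zl <- W * (1 - exp(-k1)) / k1 + W * exp(-k1) / k2
    out[t1] <- pr[3] * exp(-k1 * (d[t1] - l[2]) / W) / zl
    out[t2] <- pr[3] * exp(-k1) * exp(-k2 * (d[t2] - l[3]) / W) / zl
    out
  }
  d_max <- l[3] + W * (20 / k2)     # tail mass beyond is < 1e-8
  grid <- seq(0, d_max, length.out = 20000)
  M <- max(dens(grid)) * 1.05
  out <- numeric(0)
  while (length(out) < n) {
    prop <- stats::runif(2 * n, 0, d_max)
    keep <- stats::runif(2 * n) < dens(prop) / M
    out <- c(out, prop[keep])
  }
  out[seq_len(n)]
}

# Parameter set with a single modification applied to one group (for
# closed-population and reseeding experiments).
modify_group <- function(params, group, field, value) {
  params[[group]][[field]] <- value
  params
}
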