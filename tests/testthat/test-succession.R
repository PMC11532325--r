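# Annual demographic step: strata competition, survival, aging, germination.

test_that("resource levels follow the stratum shading rule", {
  ls <- empty_landscape(c(5, 5))
  expect_equal(compute_resource(ls, 2, 2, 1), "high")   # nothing shades
  expect_error(compute_resource(ls, 2, 2, 6), "1..5")

  # one mature tree cohort (stratum 3) at abundance 1 shades stratum 1 fully
  ls <- place_cohort(ls, 2, 2, "tree", 12, 1)
  expect_equal(compute_resource(ls, 2, 2, 1), "low")
  expect_equal(compute_resource(ls, 2, 2, 2), "low")
  expect_equal(compute_resource(ls, 2, 2, 3), "high")   # own stratum: no self-shade
  expect_equal(compute_resource(ls, 2, 2, 5), "high")   # nothing above stratum 5
  expect_equal(compute_resource(ls, 0, 0, 1), "high")   # other cells unaffected

  # intermediate cover -> medium
  ls2 <- one_cohort_landscape("tree", 12, 0.5)
  expect_equal(compute_resource(ls2, 2, 2, 1), "medium")
})

test_that("immatures shade lower strata by their relative size", {
  # immature subshrub (size 1 -> weight 1/4) in stratum 1 shades nothing below
  ls <- one_cohort_landscape("non-spiny subshrub", 1, 1)
  expect_equal(compute_resource(ls, 2, 2, 1), "high")
  # mature subshrub occupies stratum 2 and shades stratum 1
  ls <- one_cohort_landscape("non-spiny subshrub", 4, 1)
  expect_equal(compute_resource(ls, 2, 2, 1), "low")
})

test_that("survival pass removes cohorts whose stage/resource entry is false", {
  # annual mature under a full tree canopy (low resource at stratum 1) dies
  ls <- one_cohort_landscape("tree", 12, 1)
  ls <- place_cohort(ls, 2, 2, "annuals", 1, 0.5)
  ls <- place_cohort(ls, 2, 2, "gramineae", 1, 0.5)  # immature, survives at low
  out <- annual_step(ls)
  expect_equal(landscape_abundance(out, "annuals"), 0)
  expect_gt(landscape_abundance(out, "gramineae"), 0)
})

test_that("aging promotes germinants, matures plants and retires the old", {
  # annual at max_age 2 is removed by the next step
  ls <- one_cohort_landscape("annuals", 2, 0.8)
  out <- annual_step(ls)
  expect_equal(landscape_abundance(out, "annuals"), 0)

  # tree germinant becomes an immature of age 1
  ls <- one_cohort_landscape("tree", 0, 0.4)
  out <- annual_step(ls)
  cc <- cohorts(out)
  expect_equal(cc$age, 1)
  expect_equal(cc$stage, "immature")
  expect_equal(cc$abundance, 0.4)

  # forb matures at age 1: a germinant is mature after one step (and, being
  # mature, already seeds a new germinant generation the same year)
  ls <- one_cohort_landscape("forb", 0, 0.4)
  cc <- cohorts(annual_step(ls))
  expect_equal(cc$stage[cc$age == 1], "mature")
  expect_equal(cc$abundance[cc$age == 1], 0.4)
})

test_that("germination needs seeds, a positive rate and germinant survival", {
  nss <- PARAMS$non_spiny_subshrub
  expect_equal(germination_abundance(nss, "low", 5), 0)      # rate none at low
  expect_equal(germination_abundance(nss, "medium", 5), 0)   # germinants die
  expect_equal(germination_abundance(nss, "high", 3), 0.5)   # level 2, saturated
  tree <- PARAMS$resprouter_tree
  expect_equal(germination_abundance(tree, "high", 2), 0.75)
  expect_equal(germination_abundance(tree, "high", 1), 0.375) # half saturation
  expect_gt(germination_abundance(tree, "high", 2),
            germination_abundance(tree, "medium", 2))
  expect_equal(germination_abundance(tree, "high", 0), 0)    # no seed events
})

test_that("seed rain lands on the grid and respects fecundity", {
  # no mature cohorts -> no seeds
  ls <- one_cohort_landscape("tree", 5, 1, dims = c(21, 21), row = 10, col = 10)
  expect_equal(nrow(seed_events(ls, "tree")), 0L)

  # a single mature tree cohort far from the border emits exactly 2 events
  set.seed(1)
  ls <- one_cohort_landscape("tree", 12, 1, dims = c(41, 41), row = 20, col = 20)
  ev <- seed_events(ls, "tree")
  expect_equal(nrow(ev), 2L)
  expect_true(all(ev$row >= 0 & ev$row < 41 & ev$col >= 0 & ev$col < 41))
  expect_true(all(ev$src_row == 20 & ev$src_col == 20))

  # off-grid seeds are discarded: a corner source loses part of its rain
  set.seed(2)
  lost <- replicate(200, nrow(seed_events(
    one_cohort_landscape("tree", 12, 1, dims = c(5, 5), row = 0, col = 0),
    "tree")))
  expect_lt(mean(lost), 2)
})

test_that("band choice frequencies match the normalised capacity fractions", {
  # forb: high/med/low -> (1, .5, .25)/1.75 over the 5/30/100 m limits
  set.seed(99)
  d <- sample_dispersal_distances(1e5, PARAMS$perennial_forb$dispersal)
  p_hat <- c(mean(d < 5), mean(d >= 5 & d < 30), mean(d >= 30))
  p_exp <- c(1, 0.5, 0.25) / 1.75
  se <- sqrt(p_exp * (1 - p_exp) / 1e5)
  expect_true(all(abs(p_hat - p_exp) < 3 * se))
})

test_that("dispersal distances match an independent rejection-sampling oracle", {
  set.seed(7)
  d_impl <- sample_dispersal_distances(1e5, PARAMS$resprouter_tree$dispersal)
  d_orac <- dispersal_rejection_oracle(1e5, PARAMS$resprouter_tree$dispersal)
  ks <- suppressWarnings(stats::ks.test(d_impl, d_orac))
  expect_gt(ks$p.value, 0.01)
})

test_that("a closed population only loses abundance through senescence", {
  params <- modify_group(PARAMS, "spiny_subshrub", "fecundity", 0L)
  params$spiny_subshrub$survival[] <- TRUE
  set.seed(5)
  ls <- init_landscape(archetype_profile(c(spiny_subshrub = 40)), c(20, 20),
                       params = params)
  tot <- landscape_abundance(ls, "spiny_subshrub")
  for (y in 1:35) {
    ls <- annual_step(ls)
    now <- landscape_abundance(ls, "spiny_subshrub")
    expect_lte(now, tot + 1e-9)
    tot <- now
  }
  expect_equal(tot, 0)  # all initial cohorts are past max_age 30 by now
})

test_that("annual herbs persist beyond three years only via reseeding", {
  params <- modify_group(PARAMS, "annual", "fecundity", 0L)
  ls <- empty_landscape(c(5, 5), params = params)
  ls <- place_cohort(ls, 1, 1, "annual", 1, 0.9)
  ls <- place_cohort(ls, 3, 3, "annual", 2, 0.9)
  for (y in 1:3) ls <- annual_step(ls)
  expect_equal(landscape_abundance(ls, "annual"), 0)

  # with seeds the population renews itself
  set.seed(8)
  ls2 <- empty_landscape(c(5, 5))
  ls2 <- place_cohort(ls2, 2, 2, "annual", 1, 0.9)
  ls2$seeds[13, "annual"] <- 5
  for (y in 1:3) ls2 <- annual_step(ls2)
  expect_gt(landscape_abundance(ls2, "annual"), 0)
})

test_that("abundances stay within [0, 1] and ages within lifespan", {
  set.seed(21)
  ls <- init_landscape(2, dims = c(25, 25))
  sc <- grazing_scenario("moderate")
  for (y in 1:12) {
    ls <- annual_step(ls, sc)
    for (g in ls$groups) {
      m <- ls$ab[[g]]
      expect_true(all(m >= 0 & m <= 1), info = g)
      expect_lte(max(rowSums(m)), 1 + 1e-9)
      expect_lte(ncol(m), PARAMS[[g]]$max_age + 1L)
    }
  }
})

test_that("identical seeds replay to bit-identical landscapes", {
  run <- function() {
    set.seed(31)
    ls <- init_landscape(3, dims = c(30, 30))
    sc <- grazing_scenario("moderate")
    for (y in 1:8) ls <- annual_step(ls, sc)
    ls
  }
  a <- run(); b <- run()
  expect_identical(a$ab, b$ab)
  expect_identical(a$seeds, b$seeds)
})
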