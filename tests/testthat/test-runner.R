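# Scenario orchestration: configs, replay determinism, outputs, and the
# relative no-grazing vs moderate endpoints that hold for woodland steppes.

test_that("a zero-year run returns the initial state only", {
  cfg <- run_config(1, "none", years = 0, grid = c(10, 10), seed = 3)
  out <- run_scenario(cfg)
  expect_equal(unique(out$series$year), 0)
  expect_identical(out$final$ab, out$initial$ab)
  expect_equal(out$series$abundance,
               unname(landscape_abundance(out$initial)[out$series$group]))
})

test_that("unknown archetypes and invalid configs are rejected", {
  expect_error(run_config(1, years = -1), ">= 0")
  expect_error(run_scenario(run_config("landscape9", years = 0)), "unknown archetype")
})

test_that("the full experiment plan is 5 landscapes x 3 regimes", {
  plan <- experiment_plan()
  expect_equal(nrow(plan), 15L)
  expect_setequal(unique(plan$regime), c("none", "moderate", "overgrazing"))
  expect_setequal(unique(plan$landscape), 1:5)
  # default simulation horizon is 50 years
  expect_equal(run_config(1)$years, 50L)
})

test_that("identical configurations replay to identical outputs", {
  cfg <- run_config(2, "moderate", years = 6, grid = c(25, 25), seed = 11)
  a <- run_scenario(cfg)
  b <- run_scenario(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$final$ab, b$final$ab)
})

test_that("run outputs are written as documented files", {
  dir <- withr::local_tempdir()
  cfg <- run_config(3, "overgrazing", years = 2, grid = c(12, 12), seed = 5,
                    out_dir = dir)
  run_scenario(cfg)
  expect_true(file.exists(file.path(dir, "landscape3_overgrazing_series.tsv")))
  expect_true(file.exists(file.path(dir, "landscape3_overgrazing_final.tsv")))
  expect_true(file.exists(file.path(dir, "landscape3_overgrazing_initial_map.tsv")))
  expect_true(file.exists(file.path(dir, "landscape3_overgrazing_final_map.png")))
  expect_true(file.exists(file.path(dir, "landscape3_overgrazing_meta.txt")))
  ser <- read.delim(file.path(dir, "landscape3_overgrazing_series.tsv"))
  expect_equal(nrow(ser), 3 * 6)
  expect_true(all(ser$abundance >= 0 & ser$abundance <= 100))
  map <- as.matrix(read.delim(file.path(dir, "landscape3_overgrazing_final_map.tsv"),
                              header = FALSE))
  expect_equal(dim(map), c(12L, 12L))
})

test_that("run_experiment aggregates a tidy long table across all runs", {
  ex <- run_experiment(landscapes = c(3, 4), regimes = c("none", "overgrazing"),
                       years = 3, grid = c(15, 15), seed = 2)
  expect_equal(nrow(ex$plan), 4L)
  expect_equal(names(ex$summary),
               c("landscape", "regime", "group", "year", "abundance"))
  expect_equal(nrow(ex$summary), 4 * 6 * 4)  # runs x groups x years 0..3
  expect_equal(nrow(ex$final), 4 * 6)
  expect_true(all(ex$summary$abundance >= 0 & ex$summary$abundance <= 100))
})

test_that("year-0 abundances equal the initialised landscape's abundances", {
  cfg <- run_config(4, "moderate", years = 2, grid = c(20, 20), seed = 9)
  out <- run_scenario(cfg)
  y0 <- out$series[out$series$year == 0, ]
  expect_equal(y0$abundance,
               unname(landscape_abundance(out$initial)[y0$group]))
})

# Woodland-steppe comparisons that the grazing-regime contrast supports:
# under grazing exclusion trees advance monotonically and suppress the
# palatable herb layer relative to moderate grazing. (Run at a reduced grid
# to keep the unit suite fast; the acceptance suite re-runs the full design.)
test_that("grazing exclusion suppresses forbs and spiny subshrubs below their moderate endpoints", {
  none <- run_scenario(run_config(1, "none", years = 50, grid = c(40, 40),
                                  seed = 0))
  mod <- run_scenario(run_config(1, "moderate", years = 50, grid = c(40, 40),
                                 seed = 0))
  tree <- none$series$abundance[none$series$group == "resprouter_tree"]
  expect_true(all(diff(tree) >= -1e-9))
  expect_gt(tree[51], tree[1])
  for (g in c("perennial_forb", "spiny_subshrub")) {
    n50 <- none$series$abundance[none$series$group == g & none$series$year == 50]
    m50 <- mod$series$abundance[mod$series$group == g & mod$series$year == 50]
    expect_lt(n50, m50, label = g)
  }
})

test_that("grazing exclusion lets both subshrub groups expand in treeless steppe", {
  out <- run_scenario(run_config(5, "none", years = 50, grid = c(40, 40),
                                 seed = 0))
  for (g in c("non_spiny_subshrub", "spiny_subshrub")) {
    s <- out$series$abundance[out$series$group == g]
    expect_gt(s[51], s[1], label = g)
  }
})
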