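# Functional-group parameter loading, ordinal scales and age classes.

test_that("packaged defaults reproduce the published trait tables", {
  p <- PARAMS
  expect_setequal(names(p), fg_groups())

  tree <- fg_group(p, "resprouter tree")
  expect_equal(tree$mature_age, 10)
  expect_equal(tree$max_age, 300)
  expect_equal(tree$fecundity, 2)
  expect_equal(tree$stratum_mature, 3)
  expect_equal(tree$dispersal$limits, c(10, 50, 100))
  expect_equal(tree$dispersal$k_disp, c(2, 10))
  expect_equal(tree$disturbance$kill, c(3, 2, 0))
  expect_equal(tree$disturbance$resprout, c(0, 1, 0))
  expect_equal(tree$disturbance$respage, c(1, 5, 10))

  ann <- fg_group(p, "annuals")
  expect_equal(ann$disturbance$respage, c(-1, -1))
  expect_equal(ann$max_age, 2)
  expect_equal(ann$fecundity, 5)
  expect_equal(ann$disturbance$kill, c(1, 3))

  expect_equal(fg_group(p, "perennial forb")$mature_age, 1)
  expect_equal(fg_group(p, "perennial forb")$max_age, 5)
  expect_equal(fg_group(p, "gramineae")$disturbance$kill, c(3, 0))
  expect_equal(fg_group(p, "gramineae")$disturbance$resprout, c(0, 3))
  for (g in p) expect_equal(g$maxab, 1)

  # disturbance tuple lengths match the printed age limits
  n_classes <- vapply(p, function(g) length(g$disturbance$kill), integer(1))
  expect_equal(unname(n_classes[c("non_spiny_subshrub", "spiny_subshrub",
                                  "perennial_forb", "perennial_gramineae",
                                  "annual", "resprouter_tree")]),
               c(3L, 3L, 2L, 2L, 2L, 3L))
})

test_that("survival matrices and germination levels match the published table", {
  surv <- list(
    non_spiny_subshrub = rbind(c(F, F, T), c(F, T, T), c(T, T, T)),
    spiny_subshrub     = rbind(c(F, F, T), c(F, T, T), c(T, T, T)),
    perennial_forb     = rbind(c(F, T, T), c(T, T, T), c(T, T, T)),
    perennial_gramineae = rbind(c(F, T, T), c(T, T, T), c(T, T, T)),
    annual             = rbind(c(F, F, T), c(F, F, T), c(F, T, T)),
    resprouter_tree    = rbind(c(F, T, T), c(T, T, T), c(T, T, T))
  )
  germ <- list(
    non_spiny_subshrub = c(0, 1, 2), spiny_subshrub = c(0, 1, 2),
    perennial_forb = c(1, 1, 1), perennial_gramineae = c(1, 1, 1),
    annual = c(1, 1, 1), resprouter_tree = c(1, 2, 3)
  )
  for (g in fg_groups()) {
    expect_equal(unname(PARAMS[[g]]$survival), surv[[g]], info = g)
    expect_equal(unname(PARAMS[[g]]$germination_rate), germ[[g]], info = g)
  }
  # survival lookup helper agrees entry-for-entry
  expect_false(survival_entry(PARAMS$annual, "immature", "medium"))
  expect_true(survival_entry(PARAMS$perennial_gramineae, "immature", "low"))
  expect_true(survival_entry(PARAMS$non_spiny_subshrub, "mature", "low"))
})

test_that("survival and germination are non-decreasing in resource level", {
  for (g in PARAMS) {
    expect_false(is.unsorted(g$germination_rate), info = g$name)
    for (stg in rownames(g$survival)) {
      expect_false(is.unsorted(as.integer(g$survival[stg, ])),
                   info = paste(g$name, stg))
    }
  }
})

test_that("parameter sets round-trip through serialisation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fg_params(PARAMS, path)
  again <- load_fg_params(path)
  expect_equal(again, PARAMS)
})

test_that("validation errors name the group and field", {
  path <- withr::local_tempfile(fileext = ".yaml")
  doc <- yaml::read_yaml(system.file("extdata", "functional_groups.yaml",
                                     package = "steppesim"))
  doc$groups$perennial_forb$disturbance$kill <- c(3, 1, 2)  # 2 classes expected
  yaml::write_yaml(doc, path)
  expect_error(load_fg_params(path), "perennial_forb.*kill|kill.*perennial_forb")

  doc <- yaml::read_yaml(system.file("extdata", "functional_groups.yaml",
                                     package = "steppesim"))
  doc$groups$annual$fecundity <- NULL
  yaml::write_yaml(doc, path)
  expect_error(load_fg_params(path), "annual.*fecundity")

  doc <- yaml::read_yaml(system.file("extdata", "functional_groups.yaml",
                                     package = "steppesim"))
  doc$groups$spiny_subshrub$germination$low <- 7
  yaml::write_yaml(doc, path)
  expect_error(load_fg_params(path), "ordinal")
})

test_that("age classes are half-open on the right and match a brute-force scan", {
  expect_equal(age_class_of(1, c(2, 5)), 0L)
  expect_equal(age_class_of(0, c(2, 5)), 0L)
  expect_equal(age_class_of(2, c(2, 5)), 1L)
  expect_equal(age_class_of(5, c(2, 5)), 2L)
  expect_error(age_class_of(-1, c(2, 5)), "non-negative")
  for (g in PARAMS) {
    bp <- g$disturbance$age_breakpoints
    got <- age_class_of(0:300, bp)
    want <- vapply(0:300, age_class_bruteforce, integer(1), breakpoints = bp)
    expect_equal(got, want, info = g$name)
  }
})

test_that("ordinal levels map linearly onto fractions", {
  expect_equal(level_to_fraction(0), 0)
  expect_equal(level_to_fraction(4), 1)
  expect_equal(level_to_fraction(2), 0.5)   # "Half"
  expect_equal(level_to_fraction(0:4), c(0, 0.25, 0.5, 0.75, 1))
  expect_error(level_to_fraction(5), "0..4")
})

test_that("abundance classes use the fixed thresholds and absent means zero", {
  x <- c(0, 0.1, 0.33, 0.34, 0.66, 0.67, 1)
  expect_equal(as.character(abundance_class(x)),
               c("absent", "low", "low", "medium", "medium", "high", "high"))
  expect_error(abundance_class(1.2), "0, 1|\\[0, 1\\]")
})
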