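## Functional-group parameterisation: ordinal scales, validation, config I/O.

#' Canonical functional-group identifiers
#'
#' The six growth forms simulated by the package, in canonical order
#' (used for tie-breaking in dominance maps and for column order in
#' growth-form abundance matrices).
#'
#' @return Character vector of the six group identifiers.
#' @export
fg_groups <- function() {
  c("non_spiny_subshrub", "spiny_subshrub", "perennial_forb",
    "perennial_gramineae", "annual", "resprouter_tree")
}

# Verbal labels of the 5-level ordinal scale. Two dialects are in use:
# rate-like parameters read No-Low-Med-High-All, kill/propagule parameters
# read No-Few-Half-Most-All. Both map onto the same 0..4 coding.
.level_labels <- list(
  rate = c("no", "low", "med", "high", "all"),
  kill = c("no", "few", "half", "most", "all")
)

#' Convert a 5-level ordinal to a fraction
#'
#' Ordinal levels 0..4 (No / Low or Few / Med or Half / High or Most / All)
#' map linearly onto fractions: 0, 0.25, 0.5, 0.75, 1. "Half" anchors 0.5
#' and the scale is symmetric around it.
#'
#' @param level Integer vector with values in 0..4.
#' @return Numeric vector of fractions in [0, 1].
#' @export
level_to_fraction <- function(level) {
  level <- as.integer(level)
  if (any(is.na(level)) || any(level < 0L) || any(level > 4L)) {
    stop("ordinal level must be an integer in 0..4", call. = FALSE)
  }
  level / 4
}

# Parse an ordinal that may be given as integer 0..4 or as a verbal label
# in either dialect ("Med", "Half", ...). Synonyms: medium/med, none/no.
.parse_level <- function(x, what = "level") {
  if (is.numeric(x)) {
    v <- as.integer(x)
  } else {
    key <- tolower(trimws(as.character(x)))
    key[key == "none"] <- "no"
    key[key == "medium"] <- "med"
    v <- vapply(key, function(k) {
      i <- match(k, .level_labels$rate)
      if (is.na(i)) i <- match(k, .level_labels$kill)
      if (is.na(i)) NA_integer_ else i - 1L
    }, integer(1))
  }
  if (any(is.na(v)) || any(v < 0L) || any(v > 4L)) {
    stop(sprintf("invalid ordinal value for %s", what), call. = FALSE)
  }
  unname(v)
}

.resource_levels <- c("low", "medium", "high")
.stages <- c("propagule", "germinant", "immature", "mature")

#' Age class of an age given class breakpoints
#'
#' Age classes are half-open on the right: breakpoints (b1, ..., bk) define
#' classes [0, b1), [b1, b2), ..., [bk, Inf). Returns the 0-based class
#' index: the smallest i with age < breakpoints[i + 1], or k when the age is
#' at or beyond the last breakpoint.
#'
#' @param age Numeric vector of ages in years (>= 0).
#' @param breakpoints Strictly increasing numeric vector of ages.
#' @return Integer vector of 0-based class indices.
#' @export
age_class_of <- function(age, breakpoints) {
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  if (length(breakpoints) == 0 || is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be non-empty and strictly increasing", call. = FALSE)
  }
  findInterval(age, breakpoints)
}

#' @rdname abundance_class
#' @export
abundance_thresholds <- function() c(low = 0.33, medium = 0.66)

#' Ordinal abundance class of a continuous abundance
#'
#' Internal abundance is continuous in [0, 1]; the reporting classes are
#' absent (= 0), low ((0, 0.33]), medium ((0.33, 0.66]) and high ((0.66, 1]).
#'
#' @param x Numeric vector of abundances in [0, 1].
#' @return Factor with levels absent, low, medium, high.
#' @export
abundance_class <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("abundance must lie in [0, 1]", call. = FALSE)
  }
  th <- abundance_thresholds()
  cls <- ifelse(x == 0, "absent",
         ifelse(x <= th[["low"]], "low",
         ifelse(x <= th[["medium"]], "medium", "high")))
  factor(cls, levels = c("absent", "low", "medium", "high"))
}

.fail <- function(group, field, msg) {
  stop(sprintf("functional group '%s', field '%s': %s", group, field, msg),
       call. = FALSE)
}

.need <- function(block, field, group) {
  if (is.null(block[[field]])) .fail(group, field, "missing field")
  block[[field]]
}

# Build one validated fg_params object from a parsed config block.
.build_group <- function(name, block) {
  g <- list(name = name, label = if (!is.null(block$label)) block$label else name)

  g$maxab <- as.integer(.need(block, "maxab", name))
  if (g$maxab < 1L || g$maxab > 3L) .fail(name, "maxab", "must be in 1..3")
  g$mature_age <- as.integer(.need(block, "mature_age", name))
  g$max_age <- as.integer(.need(block, "max_age", name))
  if (g$mature_age < 1L) .fail(name, "mature_age", "must be >= 1")
  if (g$mature_age >= g$max_age) .fail(name, "mature_age", "must be < max_age")
  g$size_class <- as.integer(.need(block, "size", name))
  if (g$size_class < 1L || g$size_class > 4L) .fail(name, "size", "must be in 1..4")

  st <- as.integer(.need(block, "stratum", name))
  if (length(st) != 2L || any(st < 1L | st > 5L)) {
    .fail(name, "stratum", "needs two values in 1..5 (immature, mature)")
  }
  if (st[1] > st[2]) .fail(name, "stratum", "immature stratum must be <= mature stratum")
  g$stratum_immature <- st[1]
  g$stratum_mature <- st[2]

  dsp <- .need(block, "dispersal", name)
  g$dispersal <- list(
    s_rate = .parse_level(.need(dsp, "s_rate", name), "dispersal s_rate"),
    m_rate = .parse_level(.need(dsp, "m_rate", name), "dispersal m_rate"),
    h_rate = .parse_level(.need(dsp, "h_rate", name), "dispersal h_rate"),
    k_disp = as.numeric(.need(dsp, "k_disp", name)),
    limits = as.numeric(.need(dsp, "limits", name))
  )
  with(g$dispersal, {
    if (any(c(s_rate, m_rate, h_rate) > 3L)) {
      .fail(name, "dispersal", "band rates use levels 0..3 only")
    }
    if (length(k_disp) != 2L || any(k_disp <= 0)) {
      .fail(name, "dispersal.k_disp", "needs two positive constants")
    }
    if (length(limits) != 3L || is.unsorted(limits, strictly = TRUE) ||
        limits[1] <= 0) {
      .fail(name, "dispersal.limits", "needs three strictly increasing distances")
    }
  })

  g$fecundity <- as.integer(.need(block, "fecundity", name))
  if (g$fecundity < 0L) .fail(name, "fecundity", "must be >= 0")

  germ <- .need(block, "germination", name)
  g$germination_rate <- vapply(.resource_levels, function(r) {
    .parse_level(.need(germ, r, name), paste0("germination.", r))
  }, integer(1))

  sv <- .need(block, "survival", name)
  g$survival <- do.call(rbind, lapply(c("germinant", "immature", "mature"),
    function(stg) {
      row <- .need(sv, stg, name)
      if (length(row) != 3L) .fail(name, paste0("survival.", stg), "needs 3 entries")
      as.logical(row)
    }))
  dimnames(g$survival) <- list(c("germinant", "immature", "mature"),
                               .resource_levels)
  if (any(is.na(g$survival))) .fail(name, "survival", "entries must be logical")

  db <- .need(block, "disturbance", name)
  bp <- as.numeric(.need(db, "age_breakpoints", name))
  if (length(bp) < 1L || length(bp) > 2L || is.unsorted(bp, strictly = TRUE)) {
    .fail(name, "disturbance.age_breakpoints",
          "needs 1-2 strictly increasing ages")
  }
  nclass <- length(bp) + 1L
  tup <- function(field) {
    v <- as.integer(.need(db, field, name))
    if (length(v) != nclass) {
      .fail(name, paste0("disturbance.", field),
            sprintf("length %d does not match %d age classes", length(v), nclass))
    }
    v
  }
  g$disturbance <- list(
    age_breakpoints = bp,
    seed_broken = .parse_level(.need(db, "seed_broken", name), "seed_broken"),
    propkill = .parse_level(.need(db, "propkill", name), "propkill"),
    kill = tup("kill"),
    resprout = tup("resprout"),
    respage = tup("respage")
  )
  with(g$disturbance, {
    if (any(kill < 0L | kill > 4L)) .fail(name, "disturbance.kill", "levels 0..4")
    if (any(resprout < 0L | resprout > 4L)) {
      .fail(name, "disturbance.resprout", "levels 0..4")
    }
    # kill and resprout are fractions of the same cohort; they cannot
    # jointly exceed the whole.
    if (any(kill + resprout > 4L)) {
      .fail(name, "disturbance", "kill + resprout exceeds the whole cohort")
    }
    if (any(respage < -1L) || any(respage >= g$max_age)) {
      .fail(name, "disturbance.respage", "must be -1 or an age below max_age")
    }
  })

  structure(g, class = "fg_params")
}

#' @export
print.fg_params <- function(x, ...) {
  cat(sprintf("<fg_params> %s (maxab %d, mature %d y, lifespan %d y, strata %d/%d, fecundity %d)\n",
              x$name, x$maxab, x$mature_age, x$max_age,
              x$stratum_immature, x$stratum_mature, x$fecundity))
  invisible(x)
}

# Normalise free-form group names ("Resprouter tree", "annuals") to canonical ids.
.normalize_group <- function(x) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(x)))
  key <- gsub("^_|_$", "", key)
  aliases <- c(
    annuals = "annual", annual_herb = "annual", annual_herbs = "annual",
    tree = "resprouter_tree", forb = "perennial_forb",
    gramineae = "perennial_gramineae", grass = "perennial_gramineae",
    subshrub = "non_spiny_subshrub", nonspiny_subshrub = "non_spiny_subshrub"
  )
  out <- ifelse(key %in% names(aliases), aliases[key], key)
  unname(out)
}

#' Load functional-group parameters from a YAML config
#'
#' Reads a structured text document with one block per functional group (see
#' the packaged default under \code{system.file("extdata",
#' "functional_groups.yaml", package = "steppesim")} for the schema) and
#' returns a validated list of parameter bundles. Validation errors name the
#' offending group and field.
#'
#' @param path Path to a YAML parameter file; the packaged default when NULL.
#' @return Named list of \code{fg_params} objects, class \code{fg_params_set}.
#' @export
load_fg_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_groups.yaml", package = "steppesim")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$groups)) stop("config has no 'groups' section", call. = FALSE)
  out <- lapply(names(doc$groups), function(nm) {
    .build_group(.normalize_group(nm), doc$groups[[nm]])
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  structure(out, class = "fg_params_set")
}

#' Default functional-group parameter set
#'
#' The packaged parameterisation of the six Central Anatolian steppe growth
#' forms (non-spiny subshrub, spiny subshrub, perennial forb, perennial
#' gramineae, annual herb, resprouter tree).
#'
#' @return Named list of \code{fg_params} objects.
#' @export
fg_defaults <- function() load_fg_params(NULL)

#' Fetch one group's parameters by (possibly informal) name
#'
#' @param params An \code{fg_params_set}.
#' @param group Group name; informal variants such as "annuals" or
#'   "resprouter tree" are accepted.
#' @return An \code{fg_params} object.
#' @export
fg_group <- function(params, group) {
  id <- .normalize_group(group)
  if (!id %in% names(params)) {
    stop(sprintf("unknown functional group '%s'", group), call. = FALSE)
  }
  params[[id]]
}

#' Serialise a parameter set back to YAML
#'
#' Writing then re-reading a loaded parameter set yields identical
#' parameters (round-trip property).
#'
#' @param params An \code{fg_params_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fg_params <- function(params, path) {
  blocks <- lapply(params, function(g) {
    list(
      label = g$label,
      maxab = g$maxab,
      mature_age = g$mature_age,
      max_age = g$max_age,
      size = g$size_class,
      stratum = c(g$stratum_immature, g$stratum_mature),
      dispersal = list(
        s_rate = g$dispersal$s_rate, m_rate = g$dispersal$m_rate,
        h_rate = g$dispersal$h_rate, k_disp = g$dispersal$k_disp,
        limits = g$dispersal$limits
      ),
      fecundity = g$fecundity,
      germination = as.list(g$germination_rate),
      survival = list(
        germinant = unname(g$survival["germinant", ]),
        immature = unname(g$survival["immature", ]),
        mature = unname(g$survival["mature", ])
      ),
      disturbance = g$disturbance
    )
  })
  yaml::write_yaml(list(groups = blocks), path)
  invisible(path)
}

# Life stage implied by cohort age: germinants are age 0, plants are mature
# from mature_age on, immature in between.
stage_of_age <- function(params, age) {
  ifelse(age == 0, "germinant",
         ifelse(age >= params$mature_age, "mature", "immature"))
}

#' Survival-matrix lookup
#'
#' @param params An \code{fg_params} object.
#' @param stage One of "germinant", "immature", "mature".
#' @param resource One of "low", "medium", "high".
#' @return Logical: does a cohort of this stage survive at this resource level?
#' @export
survival_entry <- function(params, stage, resource) {
  stage <- match.arg(stage, c("germinant", "immature", "mature"))
  resource <- match.arg(resource, .resource_levels)
  params$survival[stage, resource]
}
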