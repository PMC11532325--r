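## Synthetic phytosociological datasets with the statistical structure the
## archetype-derivation pipeline assumes: alliances drawn around archetype
## mean covers, releves realised as species x Braun-Blanquet records.

#' Specify a synthetic releve dataset
#'
#' Defaults emulate the scale of the compiled Central Anatolian dataset:
#' 58 alliances spread over the five shipped landscape archetypes, with
#' releve counts per alliance chosen to total 668 releves.
#'
#' @param archetypes List of \code{\link{archetype_profile}}s (default: the
#'   five shipped landscape profiles).
#' @param n_alliances_per_archetype Integer vector (recycled) of alliances
#'   per archetype; default c(12, 12, 12, 11, 11).
#' @param n_releves_per_alliance Integer vector (recycled over alliances) of
#'   releves per alliance; the default fills 668 releves as evenly as
#'   possible.
#' @param species_pool_size Species available per growth form (default 30).
#' @param noise Within-alliance standard deviation of group cover on the
#'   percent scale (Gaussian, truncated to [0, 100]); default 5.
#' @return A \code{releve_spec}.
#' @export
releve_spec <- function(archetypes = archetype_profiles(),
                        n_alliances_per_archetype = c(12, 12, 12, 11, 11),
                        n_releves_per_alliance = NULL,
                        species_pool_size = 30, noise = 5) {
  n_arch <- length(archetypes)
  n_all <- rep_len(as.integer(n_alliances_per_archetype), n_arch)
  total_alliances <- sum(n_all)
  if (is.null(n_releves_per_alliance)) {
    base <- 668 %/% total_alliances
    extra <- 668 %% total_alliances
    n_rel <- rep(base, total_alliances)
    if (extra > 0) n_rel[seq_len(extra)] <- base + 1L
  } else {
    n_rel <- rep_len(as.integer(n_releves_per_alliance), total_alliances)
  }
  stopifnot(all(n_all >= 1L), all(n_rel >= 1L), species_pool_size >= 1,
            noise >= 0)
  structure(list(archetypes = archetypes, n_alliances = n_all,
                 n_releves = n_rel,
                 species_pool_size = as.integer(species_pool_size),
                 noise = noise),
            class = "releve_spec")
}

#' Generate a synthetic releve table
#'
#' For each alliance, per-group target covers are the archetype means plus
#' truncated Gaussian noise. Each releve realises the targets as species
#' records: one species carries the target cover (so the per-group maximum
#' equals the target) and up to two further species of the group's pool carry
#' uniformly smaller covers; percents are coded back to Braun-Blanquet
#' classes. Species names are synthetic tokens (group prefix + index).
#'
#' @param spec A \code{\link{releve_spec}}.
#' @return List with \code{releves} (the standard releve table: releve_id,
#'   alliance_id, species, growth_form, bb_code) and \code{truth}
#'   (data.frame alliance_id, archetype — the generating archetype per
#'   alliance). Uses the current RNG state.
#' @export
generate_releves <- function(spec) {
  stopifnot(inherits(spec, "releve_spec"))
  groups <- fg_groups()
  arch_of_alliance <- rep(seq_along(spec$archetypes), spec$n_alliances)
  n_alliances <- length(arch_of_alliance)
  alliance_ids <- sprintf("A%02d", seq_len(n_alliances))
  rows <- vector("list", n_alliances)
  rel_counter <- 0L
  for (a in seq_len(n_alliances)) {
    prof <- spec$archetypes[[arch_of_alliance[a]]]
    mu <- stats::setNames(numeric(length(groups)), groups)
    mu[names(prof$targets)] <- prof$targets
    recs <- vector("list", spec$n_releves[a])
    for (j in seq_len(spec$n_releves[a])) {
      rel_counter <- rel_counter + 1L
      rid <- sprintf("R%04d", rel_counter)
      # within-alliance noise: each releve realises the archetype mean with
      # its own Gaussian deviation (truncated to [0, 100]); groups absent
      # from the archetype stay absent throughout the alliance
      target <- mu + stats::rnorm(length(mu), 0, spec$noise)
      target[target < 0] <- 0
      target[target > 100] <- 100
      target[mu == 0] <- 0
      gr <- list()
      for (g in groups) {
        t <- target[[g]]
        if (t <= 0) next
        n_extra <- sample.int(3L, 1L) - 1L
        picks <- sample.int(spec$species_pool_size, min(1L + n_extra,
                                                        spec$species_pool_size))
        covers <- c(t, stats::runif(length(picks) - 1L, 0, t))
        code <- percent_to_bb(covers)
        keep <- !is.na(code)
        if (!any(keep)) next
        gr[[g]] <- data.frame(
          releve_id = rid, alliance_id = alliance_ids[a],
          species = sprintf("%s_sp%02d", g, picks[keep]),
          growth_form = g, bb_code = code[keep], stringsAsFactors = FALSE)
      }
      recs[[j]] <- if (length(gr)) do.call(rbind, gr) else NULL
    }
    rows[[a]] <- do.call(rbind, recs)
  }
  releves <- do.call(rbind, rows)
  rownames(releves) <- NULL
  list(releves = releves,
       truth = data.frame(alliance_id = alliance_ids,
                          archetype = arch_of_alliance,
                          stringsAsFactors = FALSE))
}

#' Write a synthetic releve table (and its ground truth) to disk
#'
#' @param sim Result of \code{\link{generate_releves}}.
#' @param path Output path for the releve table (tab-separated).
#' @param truth_path Optional path for the alliance-to-archetype sidecar.
#' @return \code{path}, invisibly.
#' @export
write_releves <- function(sim, path, truth_path = NULL) {
  utils::write.table(sim$releves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Cluster purity against a known archetype assignment
#'
#' Fraction of alliances whose cluster's majority archetype matches their
#' own generating archetype.
#'
#' @param assignments Named integer vector (from
#'   \code{\link{cluster_alliances}}).
#' @param truth data.frame alliance_id, archetype.
#' @return Purity in [0, 1].
#' @export
cluster_purity <- function(assignments, truth) {
  arch <- truth$archetype[match(names(assignments), truth$alliance_id)]
  sum(vapply(split(arch, assignments), function(v) max(table(v)),
             numeric(1))) / length(arch)
}
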