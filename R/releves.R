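## Phytosociological releve processing: Braun-Blanquet conversion, growth-form
## aggregation and consolidation of alliances into landscape archetypes by
## k-means clustering with elbow selection.

# Classic 7-token Braun-Blanquet cover-abundance scale with conventional
# class-midpoint percentages. Overridable in the converting functions.
.bb_midpoints <- c(r = 0.1, "+" = 0.5, "1" = 2.5, "2" = 15,
                   "3" = 37.5, "4" = 62.5, "5" = 87.5)

#' Convert Braun-Blanquet cover codes to percent cover
#'
#' Uses the conventional class midpoints: r = 0.1, + = 0.5, 1 = 2.5, 2 = 15,
#' 3 = 37.5, 4 = 62.5, 5 = 87.5.
#'
#' @param code Character vector of codes in \{r, +, 1, 2, 3, 4, 5\}.
#' @param table Optional named numeric replacing the default midpoint table.
#' @return Numeric vector of percent covers.
#' @export
bb_to_percent <- function(code, table = NULL) {
  tab <- if (is.null(table)) .bb_midpoints else table
  out <- tab[as.character(code)]
  if (any(is.na(out))) {
    bad <- unique(as.character(code)[is.na(out)])
    stop(sprintf("unknown Braun-Blanquet code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  unname(out)
}

#' Convert percent cover to a Braun-Blanquet code
#'
#' Inverse class assignment of \code{\link{bb_to_percent}}: > 75 is 5,
#' (50, 75] is 4, (25, 50] is 3, (5, 25] is 2, (1, 5] is 1, (0.25, 1] is +,
#' (0, 0.25] is r. Zero cover returns NA (no record).
#'
#' @param percent Numeric vector of covers in [0, 100].
#' @return Character vector of codes (NA for zero cover).
#' @export
percent_to_bb <- function(percent) {
  if (any(percent < 0 | percent > 100)) {
    stop("percent cover must lie in [0, 100]", call. = FALSE)
  }
  breaks <- c(0, 0.25, 1, 5, 25, 50, 75, 100)
  codes <- c("r", "+", "1", "2", "3", "4", "5")
  out <- codes[findInterval(percent, breaks, left.open = TRUE,
                            rightmost.closed = TRUE)]
  out[percent == 0] <- NA_character_
  out
}

.check_releves <- function(df) {
  need <- c("releve_id", "alliance_id", "species", "growth_form", "bb_code")
  if (!all(need %in% names(df))) {
    stop(sprintf("releve table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  df$growth_form <- .normalize_group(df$growth_form)
  bad <- setdiff(unique(df$growth_form), fg_groups())
  if (length(bad)) {
    stop(sprintf("unknown growth form(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  bb_to_percent(df$bb_code)  # validates codes
  df
}

#' Read a releve table
#'
#' Headered delimited text with columns releve_id, alliance_id, species,
#' growth_form, bb_code — the schema \code{\link{generate_releves}} emits.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return data.frame of validated releve records.
#' @export
read_releves <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c(bb_code = "character"))
  .check_releves(df)
}

#' Aggregate one releve's records to growth-form percent covers
#'
#' Per growth form, the maximum converted percent cover across its member
#' species; growth forms without records get 0. Permutation-invariant in
#' record order and idempotent under record duplication.
#'
#' @param records data.frame of releve records (one releve).
#' @return Named numeric over the six growth forms.
#' @export
aggregate_growth_forms <- function(records) {
  records <- .check_releves(records)
  pct <- bb_to_percent(records$bb_code)
  out <- stats::setNames(numeric(length(fg_groups())), fg_groups())
  if (nrow(records)) {
    mx <- tapply(pct, records$growth_form, max)
    out[names(mx)] <- mx
  }
  out
}

#' Growth-form abundance matrix of a releve table
#'
#' Aggregates every releve with \code{\link{aggregate_growth_forms}} and,
#' when \code{by = "alliance"}, averages releves within alliances.
#'
#' @param df A releve table.
#' @param by "alliance" (default: rows are alliance means) or "releve".
#' @return Numeric matrix, rows alliances (or releves), columns the six
#'   growth forms, entries percent cover.
#' @export
growth_form_matrix <- function(df, by = c("alliance", "releve")) {
  by <- match.arg(by)
  df <- .check_releves(df)
  df$pct <- bb_to_percent(df$bb_code)
  per_rel <- tapply(seq_len(nrow(df)), df$releve_id, function(i) {
    v <- tapply(df$pct[i], df$growth_form[i], max)
    out <- stats::setNames(numeric(length(fg_groups())), fg_groups())
    out[names(v)] <- v
    out
  })
  rel_mat <- do.call(rbind, per_rel)
  if (by == "releve") return(rel_mat)
  alliance <- df$alliance_id[match(rownames(rel_mat), df$releve_id)]
  agg <- rowsum(rel_mat, alliance) / as.vector(table(alliance)[sort(unique(alliance))])
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Consolidate alliances into vegetation types by k-means with elbow selection
#'
#' Runs k-means for k = 1..k_max (multiple restarts) and selects k at the
#' elbow of the within-cluster sum-of-squares curve, operationalised as the
#' maximiser of the second difference of log(WSS) over k. The log scale makes
#' the curvature statistic scale-invariant: on a raw WSS curve the second
#' difference is dominated by the first (largest) drops and selects k = 2 for
#' any hierarchically structured data, even when WSS collapses to zero at the
#' true k. A degenerate matrix whose rows are all identical yields k = 1.
#'
#' @param mat Growth-form abundance matrix (rows alliances).
#' @param k_max Largest k to consider (>= 2); default 10.
#' @param nstart Random restarts per k (default 25).
#' @return List with elements \code{k}, \code{assignments} (named integer),
#'   \code{centroids} (k x 6 matrix), \code{wss} (length k_max), and
#'   \code{profiles} (centroids as \code{\link{archetype_profile}}s).
#'   Reproducible under a fixed RNG seed.
#' @export
cluster_alliances <- function(mat, k_max = 10, nstart = 25) {
  mat <- as.matrix(mat)
  if (k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  if (nrow(mat) < k_max) stop("need at least k_max rows", call. = FALSE)
  if (all(apply(mat, 2, function(x) max(x) - min(x)) < 1e-12)) {
    cent <- mat[1, , drop = FALSE]
    return(list(k = 1L,
                assignments = stats::setNames(rep(1L, nrow(mat)), rownames(mat)),
                centroids = cent, wss = NULL,
                profiles = list(archetype_profile(cent[1, ], name = "type1"))))
  }
  n_distinct <- nrow(unique(mat))
  k_fit <- min(k_max, n_distinct)
  fits <- lapply(seq_len(k_fit), function(k) {
    stats::kmeans(mat, centers = k, nstart = nstart, iter.max = 100)
  })
  wss <- vapply(fits, function(f) sum(f$withinss), numeric(1))
  if (k_fit < k_max) wss <- c(wss, rep(wss[k_fit], k_max - k_fit))
  if (k_max >= 3) {
    lw <- log(pmax(wss, wss[1] * 1e-9))  # floor exact-zero WSS for the log
    d2 <- lw[1:(k_max - 2)] - 2 * lw[2:(k_max - 1)] + lw[3:k_max]
    k <- min(which.max(d2) + 1L, k_fit)
  } else {
    k <- min(2L, k_fit)
  }
  fit <- fits[[k]]
  profiles <- lapply(seq_len(k), function(i) {
    archetype_profile(pmin(100, pmax(0, fit$centers[i, ])),
                      name = sprintf("type%d", i))
  })
  list(k = k,
       assignments = stats::setNames(fit$cluster, rownames(mat)),
       centroids = fit$centers, wss = wss, profiles = profiles)
}
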