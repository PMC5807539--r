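#' Configuration for percent-identity species delimitation
#'
#' The delimitation criterion is the barcode-divergence rule used for the
#' *Bemisia tabaci* complex: queries more than 3.5--4.0% divergent from
#' every named reference belong to a different (possibly new) putative
#' species. The default threshold is the conservative 3.5% end of that
#' band, so a query at exactly 96.5% identity to its closest reference is
#' still assigned to that reference's species; only strictly greater
#' divergence creates a new cluster.
#'
#' @param threshold_divergence divergence fraction separating species
#'   (default 0.035; 0.040 selects the liberal end of the band).
#' @param linkage linkage used when clustering unassignable queries into
#'   new putative species: `"single"` (transitive membership under the
#'   same criterion, the default) or `"complete"`.
#' @param new_species_prefix label prefix for new clusters (default
#'   `"NEW"`).
#' @param naming_start first ordinal used when naming new clusters.
#' @return a list of class `delimit_config`.
#' @export
delimit_config <- function(threshold_divergence = 0.035,
                           linkage = c("single", "complete"),
                           new_species_prefix = "NEW",
                           naming_start = 1L) {
  stopifnot(threshold_divergence > 0, threshold_divergence < 1)
  structure(list(threshold_divergence = threshold_divergence,
                 linkage = match.arg(linkage),
                 new_species_prefix = new_species_prefix,
                 naming_start = as.integer(naming_start)),
            class = "delimit_config")
}

#' Assign queries to reference species by closest-match identity
#'
#' Each query is compared to every panel reference; the reference at
#' minimum divergence decides the verdict. Divergence at or below the
#' threshold assigns the query to that reference's species; otherwise the
#' query is marked `new_cluster`. Ties between equally close references
#' are broken by lexicographic accession and flagged.
#'
#' @param queries a record tibble of query sequences.
#' @param panel a reference panel ([read_panel()]/[make_panel()]).
#' @param cfg a [delimit_config()].
#' @param dm optional precomputed `div_matrix` over `rbind(queries, panel)`
#'   ids; if `NULL` one is computed (prealigned p-distance).
#' @return a tibble with one row per query: `query_id`, `status`
#'   (`assigned`/`new_cluster`), `species` (NA for new), `closest_reference`,
#'   `divergence`, `identity_pct`, `tie` (ambiguous closest reference),
#'   `runner_up_species`, `runner_up_identity_pct`.
#' @export
assign_species <- function(queries, panel, cfg = delimit_config(), dm = NULL) {
  stopifnot(is.data.frame(queries), is.data.frame(panel))
  if (nrow(panel) == 0) stop("reference panel is empty", call. = FALSE)
  if (nrow(queries) == 0) {
    return(tibble::tibble(query_id = character(), status = character(),
                          species = character(), closest_reference = character(),
                          divergence = numeric(), identity_pct = numeric(),
                          tie = logical(), runner_up_species = character(),
                          runner_up_identity_pct = numeric()))
  }
  if (is.null(dm)) {
    combined <- dplyr::bind_rows(
      queries[, c("id", "description", "residues", "length")],
      panel[, c("id", "description", "residues", "length")]
    )
    dm <- pairwise_matrix(combined, model = "p", mode = "prealigned")
  }
  thr <- cfg$threshold_divergence
  ref_ids <- panel$id
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    qid <- queries$id[i]
    dvec <- dm$d[qid, ref_ids]
    ord <- order(dvec, ref_ids)   # min divergence, lexicographic accession
    best <- ord[1]
    tie <- sum(dvec == dvec[best]) > 1
    best_ref <- ref_ids[best]
    best_species <- panel$species[best]
    ## runner-up: closest reference belonging to a different species
    other <- which(panel$species != best_species)
    if (length(other) > 0) {
      ro <- other[order(dvec[other], ref_ids[other])][1]
      ru_species <- panel$species[ro]
      ru_ident <- 100 * (1 - dvec[ro])
    } else {
      ru_species <- NA_character_; ru_ident <- NA_real_
    }
    assigned <- dvec[best] <= thr
    tibble::tibble(
      query_id = qid,
      status = if (assigned) "assigned" else "new_cluster",
      species = if (assigned) best_species else NA_character_,
      closest_reference = best_ref,
      divergence = unname(dvec[best]),
      identity_pct = 100 * (1 - unname(dvec[best])),
      tie = tie,
      runner_up_species = ru_species,
      runner_up_identity_pct = ru_ident
    )
  })
  dplyr::bind_rows(rows)
}

#' Cluster unassignable queries into new putative species
#'
#' Queries too divergent from every reference are grouped by linkage
#' clustering on their pairwise divergences, cut at the same threshold
#' used for assignment, so new putative species obey the criterion that
#' delimits known ones. Clusters are named `prefix + ordinal` in order of
#' first occurrence in the input; singletons form their own clusters.
#'
#' @param unassigned a record tibble of `new_cluster`-status queries.
#' @param cfg a [delimit_config()].
#' @param dm optional precomputed `div_matrix` covering the unassigned ids.
#' @return a tibble: `query_id`, `cluster` (name).
#' @export
cluster_new_species <- function(unassigned, cfg = delimit_config(), dm = NULL) {
  n <- nrow(unassigned)
  name_for <- function(k) paste0(cfg$new_species_prefix, cfg$naming_start + k - 1L)
  if (n == 0) return(tibble::tibble(query_id = character(), cluster = character()))
  if (n == 1) {
    return(tibble::tibble(query_id = unassigned$id, cluster = name_for(1L)))
  }
  if (is.null(dm)) {
    dm <- pairwise_matrix(unassigned, model = "p", mode = "prealigned")
  }
  dmat <- dm$d[unassigned$id, unassigned$id]
  hc <- stats::hclust(stats::as.dist(dmat),
                      method = if (cfg$linkage == "single") "single" else "complete")
  memb <- stats::cutree(hc, h = cfg$threshold_divergence)
  ## rename clusters by order of first occurrence
  first_seen <- unique(memb)
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  tibble::tibble(query_id = unassigned$id,
                 cluster = name_for(relabel[as.character(memb)]))
}

#' Delimitation summary table
#'
#' Aggregates assignments and new clusters into one row per species or
#' putative new species: number of sequences, closest reference
#' accession(s) observed, and the min--max percent identity to the closest
#' relative, formatted to 0.1%. Known species sort first, new clusters
#' after, each block alphabetically.
#'
#' @param assignments output of [assign_species()].
#' @param clusters output of [cluster_new_species()] (may be empty).
#' @return a tibble: `species`, `is_new`, `n_sequences`,
#'   `closest_references`, `identity_min`, `identity_max`,
#'   `identity_range` (formatted string).
#' @export
species_report <- function(assignments,
                           clusters = tibble::tibble(query_id = character(),
                                                     cluster = character())) {
  if (nrow(assignments) == 0) {
    return(tibble::tibble(species = character(), is_new = logical(),
                          n_sequences = integer(), closest_references = character(),
                          identity_min = numeric(), identity_max = numeric(),
                          identity_range = character()))
  }
  lab <- assignments
  lab$group <- lab$species
  lab$is_new <- lab$status == "new_cluster"
  if (any(lab$is_new)) {
    m <- match(lab$query_id, clusters$query_id)
    lab$group[lab$is_new] <- clusters$cluster[m[lab$is_new]]
    if (anyNA(lab$group)) {
      stop("every new_cluster query must appear in `clusters`", call. = FALSE)
    }
  }
  out <- lab |>
    dplyr::group_by(.data$group, .data$is_new) |>
    dplyr::summarise(
      n_sequences = dplyr::n(),
      closest_references = paste(sort(unique(.data$closest_reference)),
                                 collapse = ","),
      identity_min = round(min(.data$identity_pct), 1),
      identity_max = round(max(.data$identity_pct), 1),
      .groups = "drop"
    ) |>
    dplyr::rename(species = "group") |>
    dplyr::arrange(.data$is_new, .data$species)
  out$identity_range <- ifelse(
    out$identity_min == out$identity_max,
    sprintf("%.1f%%", out$identity_min),
    sprintf("%.1f‒%.1f%%", out$identity_min, out$identity_max)
  )
  out
}

#' Count new putative species in a delimitation report
#'
#' A species row counts as new when even its best match is too far from
#' any named reference: maximum identity strictly below
#' `100 * (1 - threshold)`.
#'
#' @param report a tibble carrying `identity_max` per species row (e.g.
#'   [species_report()] output or the packaged survey identity table).
#' @param threshold divergence threshold (default 0.035).
#' @return integer count of new putative species.
#' @export
count_new_species <- function(report, threshold = 0.035) {
  sum(report$identity_max < 100 * (1 - threshold))
}
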