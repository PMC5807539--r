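#' Run the full delimitation stage: distances, assignment, new-species
#' clustering, report
#'
#' Computes the query-vs-panel divergence matrix, assigns every query to
#' its closest reference species under the divergence threshold, clusters
#' the unassignable remainder into new putative species, and renders the
#' survey-style summary table. With `out_dir` set, writes
#' `assignments.tsv` and `species_report.tsv`.
#'
#' @param queries record tibble of query barcodes (pre-aligned with the
#'   panel, i.e. equal lengths; use `mode = "align-pairs"` otherwise).
#' @param panel reference panel tibble.
#' @param cfg a [delimit_config()].
#' @param mode distance mode, see [pairwise_matrix()].
#' @param out_dir optional output directory.
#' @return a list with `assignments`, `clusters`, `report`, `dm`, and a
#'   one-line `summary` string.
#' @export
run_delimit <- function(queries, panel, cfg = delimit_config(),
                        mode = "prealigned", out_dir = NULL) {
  if (nrow(queries) == 0) {
    warning("no query sequences; returning an empty report", call. = FALSE)
  }
  combined <- dplyr::bind_rows(
    queries[, c("id", "description", "residues", "length")],
    panel[, c("id", "description", "residues", "length")]
  )
  dm <- pairwise_matrix(combined, model = "p", mode = mode)
  assignments <- assign_species(queries, panel, cfg, dm = dm)
  unassigned <- queries[queries$id %in%
                          assignments$query_id[assignments$status == "new_cluster"], ]
  clusters <- cluster_new_species(unassigned, cfg, dm = dm)
  report <- species_report(assignments, clusters)
  summary_line <- sprintf(
    "%d queries: %d assigned to %d known species; %d in %d new putative species",
    nrow(queries), sum(assignments$status == "assigned"),
    length(unique(stats::na.omit(assignments$species))),
    sum(assignments$status == "new_cluster"),
    length(unique(clusters$cluster))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(assignments[, setdiff(names(assignments), "tie")],
                     file.path(out_dir, "assignments.tsv"))
    readr::write_tsv(report, file.path(out_dir, "species_report.tsv"))
  }
  list(assignments = assignments, clusters = clusters, report = report,
       dm = dm, summary = summary_line)
}

#' Screen primer pairs against a batch of templates
#'
#' The in-silico analogue of running both primer sets on a gel: for each
#' template and each named primer pair, did an amplicon form at the given
#' mismatch tolerance, and how long was it?
#'
#' @param primer_sets named list of `list(fwd = , rev = )` primer pairs.
#' @param templates record tibble of templates.
#' @param max_mismatches mismatch tolerance per binding site (default 3).
#' @param max_product maximum product length (default 2000).
#' @param out_dir optional output directory (writes `primer_screen.tsv`).
#' @return a tibble: `template_id`, `primer_set`, `amplified`,
#'   `product_length` (NA when no product), `n_amplicons`.
#' @export
run_primer_screen <- function(primer_sets, templates, max_mismatches = 3,
                              max_product = 2000, out_dir = NULL) {
  stopifnot(is.list(primer_sets), !is.null(names(primer_sets)))
  rows <- list()
  for (set_name in names(primer_sets)) {
    ps <- primer_sets[[set_name]]
    for (i in seq_len(nrow(templates))) {
      amp <- in_silico_pcr(ps$fwd, ps$rev, templates[i, ],
                           max_mismatches = max_mismatches,
                           max_product = max_product)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        template_id = templates$id[i],
        primer_set = set_name,
        amplified = nrow(amp) > 0,
        product_length = if (nrow(amp) > 0) amp$product_length[1] else NA_integer_,
        n_amplicons = nrow(amp)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out, file.path(out_dir, "primer_screen.tsv"))
  }
  out
}

#' Run the tree-and-dating stage
#'
#' Builds the divergence matrix, an ultrametric UPGMA tree calibrated to
#' the fossil root age, and bootstrap intervals for focal clade ages; an
#' NJ tree (outgroup-rooted when an outgroup is given) is built alongside
#' for topology, with its clock adequacy reported. A clock-test flag is a
#' warning, not an error: the dated tree is still produced, flagged.
#'
#' @param records pre-aligned record tibble.
#' @param focal_clades named list of tip-id vectors to date.
#' @param cfg a [calibration_config()].
#' @param outgroup optional outgroup tip ids for rooting the NJ tree.
#' @param model distance model (`"p"` or `"k2p"`).
#' @param clock_limit flag limit for [clock_test()] (default 0.1).
#' @param out_dir optional output directory (writes `dated_tree.nwk` and
#'   `clade_ages.tsv`).
#' @return a list with `dated_tree`, `ages`, `nj`, `clock`, `dm`.
#' @export
run_dating <- function(records, focal_clades, cfg = calibration_config(),
                       outgroup = NULL, model = "p", clock_limit = 0.1,
                       out_dir = NULL) {
  dm <- pairwise_matrix(records, model = model)
  nj <- if (nrow(records) >= 3) nj_tree(dm) else NULL
  clock <- NULL
  if (!is.null(nj) && !is.null(outgroup)) {
    rooted_nj <- root_with_outgroup(nj, outgroup)
    clock <- clock_test(rooted_nj, limit = clock_limit)
    if (clock$flagged) {
      warning(sprintf(
        "clock test flagged: root-to-tip CV %.3f exceeds %.2f; dates assume a strict clock",
        clock$cv, clock_limit), call. = FALSE)
    }
    nj <- rooted_nj
  }
  dated <- calibrate_ages(upgma_tree(dm), cfg)
  ages <- bootstrap_ages(records, focal_clades, cfg, model = model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dated_tree(dated, ages, file.path(out_dir, "dated_tree.nwk"),
                     file.path(out_dir, "clade_ages.tsv"))
  }
  list(dated_tree = dated, ages = ages, nj = nj, clock = clock, dm = dm)
}
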