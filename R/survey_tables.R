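#' Host-plant by species specimen counts from the Ugandan whitefly survey
#'
#' Numbers of adult whiteflies, by putative species, collected from
#' cassava and five weed species in the 2013 Ugandan survey that this
#' package's pipeline re-analyses. One row per host plant; the thirteen
#' species columns cover twelve *Bemisia tabaci* putative species plus the
#' non-*tabaci* *B.* Uganda1. The `total_printed` column is the row total
#' as published; note that in the Pavonia urens row the published cells
#' sum to one more than the published total (28 vs 27), an inconsistency
#' in the source tabulation, so totals here always use `total_printed`.
#'
#' @return a tibble with columns `host_plant`, `common_name`, one column
#'   per species, and `total_printed`.
#' @export
host_plant_counts <- function() {
  readr::read_tsv(system.file("extdata", "host_plant_counts.tsv",
                              package = "whiteflydelim", mustWork = TRUE),
                  show_col_types = FALSE)
}

#' Closest-relative identity table from the Ugandan whitefly survey
#'
#' For each species recovered in the survey: the number of sequences, the
#' GenBank accession of the closest reference relative, and the min--max
#' percent nucleotide identity of the survey's sequences to that
#' relative. `is_new` flags the five putative species first described by
#' the survey (SSA9--SSA13); `is_tabaci` is `FALSE` only for
#' *B.* Uganda1.
#'
#' @return a tibble with columns `species`, `is_tabaci`, `is_new`,
#'   `n_sequences`, `closest_accession`, `identity_min`, `identity_max`.
#' @export
closest_relative_identity <- function() {
  readr::read_tsv(system.file("extdata", "closest_relative_identity.tsv",
                              package = "whiteflydelim", mustWork = TRUE),
                  show_col_types = FALSE)
}

.SPECIES_COLS <- c("SSA1", "SSA2", "SSA6", "SSA9", "SSA10", "SSA11", "SSA12",
                   "SSA13", "MEAM1", "MEAM2", "MED", "IO", "B_Uganda1")

#' Total specimens in the survey count table
#'
#' Sums the published per-host totals (see [host_plant_counts()] for why
#' the printed totals, not the cells, are authoritative).
#'
#' @param counts a host-count tibble (default the packaged survey table).
#' @return integer total.
#' @export
count_total_specimens <- function(counts = host_plant_counts()) {
  sum(counts$total_printed)
}

#' Number of *B. tabaci* species observed in the survey counts
#'
#' Counts species columns with a nonzero column total, excluding the
#' non-*tabaci* *B.* Uganda1.
#'
#' @param counts a host-count tibble (default the packaged survey table).
#' @return integer count of *B. tabaci* species.
#' @export
count_species_identified <- function(counts = host_plant_counts()) {
  cols <- setdiff(intersect(.SPECIES_COLS, names(counts)), "B_Uganda1")
  sum(colSums(counts[, cols]) > 0)
}

#' Minimum identity linking the SSA10/SSA11 clade to the New World panel
#'
#' SSA10 and SSA11 both match a New World reference (FN821787) as closest
#' relative; the minimum of their identity ranges quantifies the deepest
#' point of the African/American link.
#'
#' @param identity a closest-relative tibble (default the packaged survey
#'   table).
#' @return minimum identity percent.
#' @export
new_world_link_identity <- function(identity = closest_relative_identity()) {
  rows <- identity[identity$species %in% c("SSA10", "SSA11"), ]
  min(rows$identity_min)
}
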