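#' Build a table of validated sequence records
#'
#' The package's working representation of barcode (or mitogenome) sequences
#' is a tibble with one row per record and columns `id`, `description`,
#' `residues` and `length`. Residues are normalised on construction:
#' lowercase is uppercased and `U` is mapped to `T` (GenBank dumps vary in
#' both respects). Any character outside the IUPAC nucleotide alphabet
#' (including `-` for gaps in pre-aligned input) is a validation error that
#' names the offending record and position.
#'
#' @param id character vector of record identifiers (accessions/sample ids).
#' @param residues character vector of nucleotide strings.
#' @param description optional character vector of free-text descriptions.
#' @return a tibble with columns `id`, `description`, `residues`, `length`.
#' @examples
#' seq_records("s1", "acgu")   # normalised to ACGT
#' @export
seq_records <- function(id, residues, description = "") {
  stopifnot(is.character(id), is.character(residues))
  n <- length(id)
  if (length(residues) != n) stop("id and residues lengths differ", call. = FALSE)
  description <- rep_len(as.character(description), n)
  residues <- normalize_residues(residues)
  for (i in seq_len(n)) .validate_residues(residues[i], id[i])
  tibble::tibble(id = as.character(id), description = description,
                 residues = residues, length = nchar(residues))
}

#' Normalise nucleotide strings
#'
#' Uppercases and maps `U` to `T`. Idempotent: applying it twice gives the
#' same result as applying it once.
#'
#' @param x character vector of nucleotide strings.
#' @return normalised character vector.
#' @export
normalize_residues <- function(x) {
  chartr("U", "T", toupper(x))
}

.validate_residues <- function(res, id) {
  if (is.na(res) || nchar(res) == 0) {
    stop("record ", dQuote(id), ": empty sequence", call. = FALSE)
  }
  chars <- .seq_chars(res)
  bad <- which(!chars %in% .IUPAC_ALPHABET)
  if (length(bad) > 0) {
    stop("record ", dQuote(id), ": illegal character ", dQuote(chars[bad[1]]),
         " at position ", bad[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file into a record table
#'
#' Accepts wrapped or single-line FASTA. The FASTA header's first
#' whitespace-delimited token becomes `id`; the remainder (if any) becomes
#' `description`. Residues are normalised (uppercase, U to T) and validated
#' against the IUPAC nucleotide alphabet; gaps are accepted so pre-aligned
#' files can be read.
#'
#' @param path path to a FASTA file.
#' @return a tibble as produced by [seq_records()], entries in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ", conditionMessage(e),
                         call. = FALSE)
                  })
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id = ids, residues = unname(as.character(set)),
              description = desc)
}

#' Write a record table as FASTA
#'
#' Output is wrapped at 70 columns. Round-trips with [read_fasta()]:
#' ids, descriptions and residues are preserved exactly.
#'
#' @param records a record tibble ([seq_records()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 70L)
  invisible(path)
}

#' Read a labelled reference panel (FASTA + TSV metadata)
#'
#' The metadata file is tab-delimited with a header row and columns `id`,
#' `species`, `clade` and `is_tabaci`; each metadata id must be present in
#' the FASTA. FASTA entries without metadata are dropped with a warning
#' (they are not part of the panel).
#'
#' @param fasta path to the reference FASTA.
#' @param metadata path to the TSV metadata.
#' @return a tibble with columns `id`, `species`, `clade`, `is_tabaci`,
#'   `description`, `residues`, `length`.
#' @export
read_panel <- function(fasta, metadata) {
  recs <- read_fasta(fasta)
  meta <- readr::read_tsv(metadata, show_col_types = FALSE,
                          col_types = readr::cols(
                            id = readr::col_character(),
                            species = readr::col_character(),
                            clade = readr::col_character(),
                            is_tabaci = readr::col_logical()
                          ))
  required <- c("id", "species", "clade", "is_tabaci")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    stop("panel metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  make_panel(recs, meta)
}

#' Assemble a reference panel from in-memory objects
#'
#' @param records a record tibble.
#' @param meta a data frame with columns `id`, `species`, `clade`,
#'   `is_tabaci`.
#' @return the joined panel tibble (see [read_panel()]).
#' @export
make_panel <- function(records, meta) {
  if (anyDuplicated(meta$id)) {
    stop("duplicate id(s) in panel metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate id(s) in panel sequences", call. = FALSE)
  }
  absent <- setdiff(meta$id, records$id)
  if (length(absent) > 0) {
    stop("panel metadata id(s) missing from sequences: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(meta$species) | is.na(meta$species))) {
    stop("panel species names must be non-empty", call. = FALSE)
  }
  unmatched <- setdiff(records$id, meta$id)
  if (length(unmatched) > 0) {
    warning("sequence(s) without panel metadata dropped: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  dplyr::inner_join(
    tibble::as_tibble(meta)[, c("id", "species", "clade", "is_tabaci")],
    records, by = "id"
  )
}
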