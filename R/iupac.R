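#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## IUPAC nucleotide ambiguity codes. Expansions are the sets of unambiguous
## bases each code stands for; "-" is a gap, never a base.
.IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_CODES <- names(.IUPAC_EXPANSION)
.IUPAC_ALPHABET <- c(.IUPAC_CODES, "-")

## set-of-bases -> minimal covering code, keyed by sorted concatenation
.IUPAC_FROM_SET <- local({
  keys <- vapply(.IUPAC_EXPANSION, function(x) paste(sort(x), collapse = ""),
                 character(1))
  stats::setNames(names(keys), keys)
})

## 16x16 logical lookup: do the expansions of two codes intersect?
.IUPAC_MATCH <- local({
  m <- matrix(FALSE, length(.IUPAC_CODES), length(.IUPAC_CODES),
              dimnames = list(.IUPAC_CODES, .IUPAC_CODES))
  for (a in .IUPAC_CODES) for (b in .IUPAC_CODES) {
    m[a, b] <- length(intersect(.IUPAC_EXPANSION[[a]], .IUPAC_EXPANSION[[b]])) > 0
  }
  m
})

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

#' Test whether two IUPAC nucleotide codes can pair
#'
#' Two degenerate codes are compatible when the sets of unambiguous bases
#' they stand for intersect (e.g. `R` = \{A,G\} matches `A` but not `C`).
#' The relation is symmetric and `N` matches every base.
#'
#' @param a,b Single IUPAC nucleotide codes (characters). Gaps are not
#'   accepted: compatibility is an annealing notion and gaps do not anneal.
#' @return `TRUE` if the expansion sets intersect, else `FALSE`. Vectorised
#'   over `a` and `b` (recycled).
#' @examples
#' iupac_match("R", "A")  # TRUE
#' iupac_match("R", "C")  # FALSE
#' @export
iupac_match <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  bad <- unique(c(a, b)[!c(a, b) %in% .IUPAC_CODES])
  if (length(bad) > 0) {
    stop("not a valid non-gap IUPAC nucleotide code: ",
         paste(dQuote(bad), collapse = ", "), call. = FALSE)
  }
  .IUPAC_MATCH[cbind(a, b)]
}

#' Number of template sequences a degenerate string stands for
#'
#' The degeneracy of an IUPAC string is the product over positions of the
#' expansion-set sizes (1 for A/C/G/T, 2 for R/Y/S/W/K/M, 3 for B/D/H/V,
#' 4 for N).
#'
#' @param x an IUPAC string without gaps.
#' @return integer degeneracy (>= 1).
#' @export
iupac_degeneracy <- function(x) {
  chars <- .seq_chars(toupper(x))
  if (any(!chars %in% .IUPAC_CODES)) {
    stop("degeneracy undefined: string contains gaps or non-IUPAC characters",
         call. = FALSE)
  }
  prod(lengths(.IUPAC_EXPANSION[chars]))
}

#' Reverse complement of an IUPAC string
#'
#' Ambiguity codes map to their complementary ambiguity (R<->Y, K<->M, ...);
#' gaps are preserved.
#'
#' @param x an IUPAC string.
#' @return the reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  chars <- .seq_chars(toupper(x))
  if (any(!chars %in% .IUPAC_ALPHABET)) {
    stop("cannot complement non-IUPAC characters", call. = FALSE)
  }
  paste(rev(unname(.COMPLEMENT[chars])), collapse = "")
}

## split a string into single characters
.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## minimal IUPAC code covering exactly a set of unambiguous bases
.code_for_set <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .IUPAC_FROM_SET[key]
  if (is.na(code)) {
    stop("no IUPAC code for base set {", paste(bases, collapse = ","), "}",
         call. = FALSE)
  }
  unname(code)
}
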