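#' Needleman-Wunsch global alignment of two sequences
#'
#' Optimal global alignment under simple linear scoring (default match +1,
#' mismatch -1, gap -2), computed with `Biostrings::pairwiseAlignment`.
#' Inputs must be gap-free; the result is a pair of equal-length gapped
#' strings plus the alignment score.
#'
#' @param a,b single-row record tibbles or plain strings.
#' @param match,mismatch,gap scores (gap is the per-residue gap penalty,
#'   negative).
#' @return a list with `a`, `b` (aligned strings) and `score`.
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  sa <- if (is.character(a)) a else a$residues[[1]]
  sb <- if (is.character(b)) b else b$residues[[1]]
  sa <- normalize_residues(sa); sb <- normalize_residues(sb)
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("cannot align an empty sequence",
                                             call. = FALSE)
  if (grepl("-", paste0(sa, sb), fixed = TRUE)) {
    stop("inputs to global_align must be gap-free", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = -gap)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

## columns where both residues are unambiguous A/C/G/T
.comparable_columns <- function(ca, cb) {
  bases <- c("A", "C", "G", "T")
  ca %in% bases & cb %in% bases
}

#' Uncorrected p-distance under pairwise deletion
#'
#' The proportion of differing sites among aligned columns where both
#' residues are unambiguous A/C/G/T; columns with a gap or ambiguity code
#' in either sequence are excluded from numerator and denominator.
#' Percent identity is `100 * (1 - divergence)`.
#'
#' @param a,b aligned strings of equal length (or single-row record
#'   tibbles).
#' @return a list with `divergence`, `sites_compared`, `identity_pct`.
#' @export
p_distance <- function(a, b) {
  sa <- if (is.character(a)) a else a$residues[[1]]
  sb <- if (is.character(b)) b else b$residues[[1]]
  ca <- .seq_chars(normalize_residues(sa))
  cb <- .seq_chars(normalize_residues(sb))
  if (length(ca) != length(cb)) {
    stop("aligned lengths differ (", length(ca), " vs ", length(cb), ")",
         call. = FALSE)
  }
  keep <- .comparable_columns(ca, cb)
  n <- sum(keep)
  if (n == 0) stop("no comparable sites between the two sequences", call. = FALSE)
  d <- sum(ca[keep] != cb[keep]) / n
  list(divergence = d, sites_compared = n, identity_pct = 100 * (1 - d))
}

#' Kimura two-parameter distance
#'
#' Model-corrected divergence \eqn{-\frac{1}{2}\ln((1-2P-Q)\sqrt{1-2Q})}
#' where `P` and `Q` are the transition and transversion proportions over
#' comparable sites (pairwise deletion, as in [p_distance()]). When the
#' logarithm's argument is non-positive the distance is saturated and
#' returned as `NA` with `defined = FALSE`.
#'
#' @param a,b aligned strings of equal length (or single-row record
#'   tibbles).
#' @return a list with `divergence`, `sites_compared`, `P`, `Q`, `defined`.
#' @export
k2p_distance <- function(a, b) {
  sa <- if (is.character(a)) a else a$residues[[1]]
  sb <- if (is.character(b)) b else b$residues[[1]]
  ca <- .seq_chars(normalize_residues(sa))
  cb <- .seq_chars(normalize_residues(sb))
  if (length(ca) != length(cb)) stop("aligned lengths differ", call. = FALSE)
  keep <- .comparable_columns(ca, cb)
  n <- sum(keep)
  if (n == 0) stop("no comparable sites between the two sequences", call. = FALSE)
  ca <- ca[keep]; cb <- cb[keep]
  diff <- ca != cb
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(list(divergence = NA_real_, sites_compared = n, P = P, Q = Q,
                defined = FALSE))
  }
  d <- -0.5 * log(arg1 * sqrt(arg2))
  list(divergence = d, sites_compared = n, P = P, Q = Q, defined = TRUE)
}

#' All-pairs divergence matrix
#'
#' Computes a symmetric divergence matrix over a set of records, either on
#' a pre-aligned set (equal lengths assumed; gap/ambiguity columns handled
#' per pair by pairwise deletion) or by globally aligning each pair first.
#'
#' @param records a record tibble with >= 2 rows and unique ids.
#' @param model `"p"` (uncorrected) or `"k2p"`.
#' @param mode `"prealigned"` or `"align-pairs"`.
#' @return an object of class `div_matrix`: list with `ids`, `d`
#'   (divergence matrix), `sites` (sites-compared matrix), `model`.
#' @export
pairwise_matrix <- function(records, model = c("p", "k2p"),
                            mode = c("prealigned", "align-pairs")) {
  model <- match.arg(model); mode <- match.arg(mode)
  stopifnot(is.data.frame(records), nrow(records) >= 2)
  if (anyDuplicated(records$id)) stop("record ids must be unique", call. = FALSE)
  n <- nrow(records)
  if (mode == "prealigned" && length(unique(records$length)) != 1) {
    stop("prealigned mode needs equal-length sequences", call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  sites <- matrix(0L, n, n, dimnames = list(records$id, records$id))
  diag(sites) <- records$length
  dist_fun <- if (model == "p") p_distance else k2p_distance
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mode == "align-pairs") {
        aln <- global_align(records$residues[i], records$residues[j])
        res <- dist_fun(aln$a, aln$b)
      } else {
        res <- dist_fun(records$residues[i], records$residues[j])
      }
      if (is.na(res$divergence)) {
        undefined <- c(undefined, paste0(records$id[i], " ~ ", records$id[j]))
      }
      d[i, j] <- d[j, i] <- res$divergence
      sites[i, j] <- sites[j, i] <- res$sites_compared
    }
  }
  if (length(undefined) > 0) {
    stop("undefined (saturated) distance for pair(s): ",
         paste(undefined, collapse = "; "), call. = FALSE)
  }
  structure(list(ids = records$id, d = d, sites = sites, model = model),
            class = "div_matrix")
}

#' @export
print.div_matrix <- function(x, ...) {
  cat(sprintf("<div_matrix> %d taxa, model %s, mean divergence %.4f\n",
              length(x$ids), x$model, mean(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' Look up one pairwise divergence
#'
#' @param dm a `div_matrix`.
#' @param a,b record ids.
#' @return divergence fraction.
#' @export
divergence <- function(dm, a, b) {
  stopifnot(inherits(dm, "div_matrix"))
  dm$d[a, b]
}

#' Serialise a divergence matrix
#'
#' Writes both a square PHYLIP-style matrix and (optionally) a tidy
#' long-format TSV with identity percentages.
#'
#' @param dm a `div_matrix`.
#' @param path output path for the PHYLIP matrix.
#' @param tidy_path optional output path for the tidy TSV (`id_a`, `id_b`,
#'   `divergence`, `identity_pct`, `sites`).
#' @return `path`, invisibly.
#' @export
write_div_matrix <- function(dm, path, tidy_path = NULL) {
  stopifnot(inherits(dm, "div_matrix"))
  n <- length(dm$ids)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste(formatC(dm$ids[i], width = -12),
                     paste(sprintf("%.8f", dm$d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  if (!is.null(tidy_path)) {
    idx <- which(upper.tri(dm$d), arr.ind = TRUE)
    readr::write_tsv(tibble::tibble(
      id_a = dm$ids[idx[, 1]], id_b = dm$ids[idx[, 2]],
      divergence = dm$d[idx], identity_pct = 100 * (1 - dm$d[idx]),
      sites = dm$sites[idx]
    ), tidy_path)
  }
  invisible(path)
}

#' Convert a divergence matrix to a `stats::dist` object
#'
#' @param dm a `div_matrix`.
#' @return a `dist` object (lower triangle), taxa in input order.
#' @export
as_dist <- function(dm) {
  stopifnot(inherits(dm, "div_matrix"))
  stats::as.dist(dm$d)
}
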