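#' Construct a PCR primer
#'
#' A primer is an IUPAC string written 5' to 3' with an orientation:
#' `forward` primers anneal to the minus strand and read along the plus
#' strand; `reverse` primers anneal to the plus strand, so their binding
#' sites appear on the template as the primer's reverse complement.
#'
#' @param name primer name.
#' @param residues IUPAC string, 5' to 3'; gaps are not allowed.
#' @param orientation `"forward"` or `"reverse"`.
#' @return an object of class `primer` (a named list with `name`,
#'   `residues`, `orientation`, `length`, `degeneracy`).
#' @examples
#' primer("2195Bt", "TGRTTTTTTGGTCATCCRGAAGT", "forward")
#' @export
primer <- function(name, residues, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  residues <- normalize_residues(residues)
  if (nchar(residues) == 0) stop("primer sequence is empty", call. = FALSE)
  chars <- .seq_chars(residues)
  if (any(!chars %in% .IUPAC_CODES)) {
    stop("primer ", dQuote(name), " contains gaps or non-IUPAC characters",
         call. = FALSE)
  }
  structure(
    list(name = name, residues = residues, orientation = orientation,
         length = nchar(residues), degeneracy = iupac_degeneracy(residues)),
    class = "primer"
  )
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s (%s, %d nt, degeneracy %d)\n  5'-%s-3'\n",
              x$name, x$orientation, x$length, x$degeneracy, x$residues))
  invisible(x)
}

#' The study's mtCO1 primer sets
#'
#' Returns the two primer pairs compared throughout the analyses: the
#' widely used general-insect pair (MT10/C1-J-2195 with MT12/TL2-N-3014)
#' and the degenerate pair redesigned to match *Bemisia tabaci* and
#' *B. afer* mitogenomes (2195Bt with C012/Bt-sh2), which targets the same
#' region so amplicons stay comparable across studies.
#'
#' @param set `"old"` for MT10/MT12, `"new"` for 2195Bt/C012.
#' @return a list with elements `fwd` and `rev`, each a [primer()].
#' @export
whitefly_primers <- function(set = c("new", "old")) {
  set <- match.arg(set)
  switch(set,
    old = list(
      fwd = primer("MT10/C1-J-2195", "TTGATTTTTTGGTCATCCAGAAGT", "forward"),
      rev = primer("MT12/TL2-N-3014", "TCCAATGCACTAATCTGCCATATTA", "reverse")
    ),
    new = list(
      fwd = primer("2195Bt", "TGRTTTTTTGGTCATCCRGAAGT", "forward"),
      rev = primer("C012/Bt-sh2", "TTTACTGCACTTTCTGCC", "reverse")
    )
  )
}

#' Count primer/template mismatches over one annealing window
#'
#' Positions are compared with the degenerate-compatibility rule
#' ([iupac_match()]); a gap in the window counts as a mismatch (there is no
#' indel-tolerant annealing model). Mismatch positions are reported
#' relative to the primer's 5' end (1-based).
#'
#' @param primer a [primer()].
#' @param window a string of exactly the primer's length, as read in the
#'   primer's own 5'->3' frame.
#' @return a list with `mismatches` (count) and `positions` (integer
#'   vector, primer-relative).
#' @export
count_mismatches <- function(primer, window) {
  stopifnot(inherits(primer, "primer"))
  window <- normalize_residues(window)
  if (nchar(window) != primer$length) {
    stop("window length ", nchar(window), " != primer length ", primer$length,
         call. = FALSE)
  }
  pc <- .seq_chars(primer$residues)
  wc <- .seq_chars(window)
  ok <- wc %in% .IUPAC_CODES
  hit <- logical(length(pc))
  hit[ok] <- .IUPAC_MATCH[cbind(pc[ok], wc[ok])]
  pos <- which(!hit)
  list(mismatches = length(pos), positions = pos)
}

## mismatch counts of `pat` (character vector of codes) against every window
## of `tmpl_chars`; returns integer vector over 1-based start offsets
.window_mismatches <- function(pat, tmpl_chars) {
  m <- length(pat)
  n <- length(tmpl_chars)
  n_win <- n - m + 1L
  if (n_win < 1L) return(integer(0))
  ok <- tmpl_chars %in% .IUPAC_CODES
  mm <- integer(n_win)
  idx <- seq_len(n_win)
  for (j in seq_len(m)) {
    tc <- tmpl_chars[idx + j - 1L]
    okj <- ok[idx + j - 1L]
    hit <- logical(n_win)
    hit[okj] <- .IUPAC_MATCH[cbind(pat[j], tc[okj])]
    mm <- mm + !hit
  }
  mm
}

#' Scan a template for primer binding sites
#'
#' Both strands are scanned: plus-strand windows are matched against the
#' primer directly (strand `+`), and windows whose reverse complement the
#' primer matches are reported on strand `-`. All coordinates are 0-based,
#' half-open, on the plus strand. Templates shorter than the primer yield
#' an empty result.
#'
#' @param primer a [primer()].
#' @param template a single-row record tibble or a list/row with `id` and
#'   `residues`.
#' @param max_mismatches maximum mismatches tolerated (default 3).
#' @return a tibble of binding sites with columns `template_id`, `start`,
#'   `end`, `strand`, `mismatches`, `mismatch_positions` (list column,
#'   primer-5'-relative), sorted by (mismatches, start).
#' @export
scan_template <- function(primer, template, max_mismatches = 3) {
  stopifnot(inherits(primer, "primer"), max_mismatches >= 0)
  tid <- template$id[[1]]
  tmpl <- normalize_residues(template$residues[[1]])
  if (grepl("-", tmpl, fixed = TRUE)) {
    stop("template ", dQuote(tid), " contains gaps; scan needs an ungapped sequence",
         call. = FALSE)
  }
  tmpl_chars <- .seq_chars(tmpl)
  m <- primer$length
  pc <- .seq_chars(primer$residues)
  ## a site on the minus strand is a plus-strand window equal to the
  ## primer's reverse complement
  pc_rc <- .seq_chars(reverse_complement(primer$residues))

  collect <- function(pat, strand) {
    mm <- .window_mismatches(pat, tmpl_chars)
    keep <- which(mm <= max_mismatches)
    if (length(keep) == 0) return(NULL)
    pos_list <- lapply(keep, function(s) {
      wc <- tmpl_chars[s + seq_len(m) - 1L]
      hit <- wc %in% .IUPAC_CODES & .IUPAC_MATCH[cbind(pat, wc)]
      bad <- which(!hit)
      ## report primer-5'-relative positions: on the minus strand the
      ## primer's 5' end sits at the window's right edge
      if (strand == "-") sort(m - bad + 1L) else bad
    })
    tibble::tibble(template_id = tid, start = keep - 1L,
                   end = keep - 1L + m, strand = strand,
                   mismatches = mm[keep], mismatch_positions = pos_list)
  }

  out <- dplyr::bind_rows(collect(pc, "+"), collect(pc_rc, "-"))
  if (nrow(out) == 0) {
    return(tibble::tibble(template_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer(),
                          mismatch_positions = list()))
  }
  dplyr::arrange(out, .data$mismatches, .data$start)
}

#' Predict PCR products on a template
#'
#' Every pairing of a plus-strand forward-primer site with a downstream
#' minus-strand reverse-primer site yields a candidate amplicon; the
#' product length spans both primer footprints (reverse site end minus
#' forward site start).
#'
#' @param fwd forward [primer()] (orientation must be `forward`).
#' @param rev reverse [primer()] (orientation must be `reverse`).
#' @param template a record row (see [scan_template()]).
#' @param max_mismatches mismatch tolerance applied to each site (default 3).
#' @param max_product maximum product length in nt (default 2000).
#' @return a tibble of amplicons: `template_id`, `fwd_start`, `fwd_end`,
#'   `fwd_mismatches`, `rev_start`, `rev_end`, `rev_mismatches`,
#'   `product_length`, sorted by `product_length`.
#' @export
in_silico_pcr <- function(fwd, rev, template, max_mismatches = 3,
                          max_product = 2000) {
  stopifnot(fwd$orientation == "forward", rev$orientation == "reverse")
  fsites <- scan_template(fwd, template, max_mismatches)
  fsites <- fsites[fsites$strand == "+", ]
  rsites <- scan_template(rev, template, max_mismatches)
  rsites <- rsites[rsites$strand == "-", ]
  empty <- tibble::tibble(template_id = character(), fwd_start = integer(),
                          fwd_end = integer(), fwd_mismatches = integer(),
                          rev_start = integer(), rev_end = integer(),
                          rev_mismatches = integer(), product_length = integer())
  if (nrow(fsites) == 0 || nrow(rsites) == 0) return(empty)
  pairs <- tidyr::expand_grid(f = seq_len(nrow(fsites)), r = seq_len(nrow(rsites)))
  out <- tibble::tibble(
    template_id = fsites$template_id[pairs$f],
    fwd_start = fsites$start[pairs$f], fwd_end = fsites$end[pairs$f],
    fwd_mismatches = fsites$mismatches[pairs$f],
    rev_start = rsites$start[pairs$r], rev_end = rsites$end[pairs$r],
    rev_mismatches = rsites$mismatches[pairs$r]
  )
  out$product_length <- out$rev_end - out$fwd_start
  out <- out[out$fwd_start < out$rev_start & out$product_length <= max_product, ]
  dplyr::arrange(out, .data$product_length)
}

#' Mismatch profile of a primer against an aligned block of windows
#'
#' The workhorse behind primer-redesign diagnostics: given annealing-region
#' windows extracted from several sequences (all in the primer's 5'->3'
#' frame, gaps allowed and counted as mismatches), it tabulates where each
#' sequence disagrees with the primer and summarises, per primer position,
#' how many sequences mismatch there.
#'
#' @param primer a [primer()].
#' @param block a record tibble whose residues all have the primer's length.
#' @return a list with `per_sequence` (tibble: `id`, `mismatches`,
#'   `positions` list column), `per_position` (tibble: `position`,
#'   `n_mismatching`), and `union_positions` (positions where at least one
#'   sequence mismatches).
#' @export
mismatch_profile <- function(primer, block) {
  stopifnot(inherits(primer, "primer"), is.data.frame(block))
  if (any(nchar(block$residues) != primer$length)) {
    stop("ragged block: every window must have the primer length (",
         primer$length, ")", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(block)), function(i) {
    count_mismatches(primer, block$residues[i])
  })
  per_seq <- tibble::tibble(
    id = block$id,
    mismatches = vapply(rows, `[[`, integer(1), "mismatches"),
    positions = lapply(rows, `[[`, "positions")
  )
  all_pos <- unlist(per_seq$positions)
  per_pos <- tibble::tibble(
    position = seq_len(primer$length),
    n_mismatching = vapply(seq_len(primer$length),
                           function(p) sum(all_pos == p), numeric(1))
  )
  list(per_sequence = per_seq, per_position = per_pos,
       union_positions = sort(unique(all_pos)))
}

#' Design a minimally degenerate primer over an aligned region
#'
#' For each column of the region the minimal IUPAC code covering exactly
#' the set of observed bases is chosen, so the resulting primer matches
#' every input sequence with zero mismatches and its degeneracy equals the
#' product of the per-column observed-set sizes. Columns containing gaps
#' or `N` are refused: the caller must pre-filter the alignment.
#'
#' @param block a record tibble of aligned sequences (equal lengths).
#' @param region integer vector `c(start, end)`, 1-based inclusive columns;
#'   defaults to the whole alignment.
#' @param name name for the designed primer.
#' @param orientation orientation of the designed primer.
#' @return a [primer()].
#' @export
design_degenerate <- function(block, region = NULL, name = "designed",
                              orientation = "forward") {
  stopifnot(is.data.frame(block), nrow(block) >= 2)
  lens <- unique(nchar(block$residues))
  if (length(lens) != 1) stop("block sequences must be aligned (equal length)",
                              call. = FALSE)
  if (is.null(region)) region <- c(1L, lens)
  stopifnot(length(region) == 2, region[1] >= 1, region[2] <= lens,
            region[1] <= region[2])
  mat <- do.call(rbind, lapply(block$residues,
                               function(s) .seq_chars(normalize_residues(s))))
  mat <- mat[, region[1]:region[2], drop = FALSE]
  codes <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(col %in% c("-", "N"))) {
      stop("column ", region[1] + j - 1L,
           " contains a gap or N; pre-filter the region", call. = FALSE)
    }
    bases <- unique(unlist(.IUPAC_EXPANSION[col]))
    .code_for_set(bases)
  }, character(1))
  primer(name, paste(codes, collapse = ""), orientation)
}
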