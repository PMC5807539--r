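## shared fixture builders; everything is generated in code, seeded

random_records <- function(n, len, seed = NULL, prefix = "r") {
  if (!is.null(seed)) set.seed(seed)
  seq_records(
    id = paste0(prefix, seq_len(n)),
    residues = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  )
}

## string with exactly k substitutions relative to x, at random positions
mutate_string <- function(x, k) {
  chars <- strsplit(x, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

## a synthetic stand-in for the annealing-region block of the reverse
## primer MT12/TL2-N-3014 against whitefly mitogenomes: four windows
## derived from the primer with substitutions planted so that six primer
## positions mismatch in at least one sequence (union of 6)
synthetic_mt12_block <- function() {
  mt12 <- whitefly_primers("old")$rev
  pc <- strsplit(mt12$residues, "")[[1]]
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
  union_pos <- c(3L, 6L, 9L, 12L, 18L, 24L)   # planted mismatching positions
  per_seq <- list(
    mg1 = union_pos[c(1, 2, 3, 4, 5, 6)],
    mg2 = union_pos[c(1, 3, 5)],
    mg3 = union_pos[c(2, 4, 6)],
    mg4 = union_pos[c(1, 4, 5, 6)]
  )
  rows <- vapply(per_seq, function(pos) {
    w <- pc
    w[pos] <- vapply(w[pos], flip, character(1))
    paste(w, collapse = "")
  }, character(1))
  list(block = seq_records(id = names(rows), residues = unname(rows)),
       union_positions = union_pos, per_seq = per_seq)
}

## standard small species plan used by delimitation recovery tests:
## three known species and one novel one, 2% within / 6% between
standard_plan <- function() {
  data.frame(
    species = c("SP1", "SP2", "SP3", "NOV1"),
    n_members = c(4, 3, 3, 3),
    max_within = 0.02, min_between = 0.06,
    novel = c(FALSE, FALSE, FALSE, TRUE)
  )
}
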