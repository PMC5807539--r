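test_that("degenerate code compatibility follows the IUPAC expansions", {
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("N", "G"))
  # symmetry, self-match, N-matches-all (property over the full alphabet)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  for (a in codes) {
    expect_true(iupac_match(a, a))
    expect_true(iupac_match("N", a))
    for (b in codes) {
      expect_identical(iupac_match(a, b), iupac_match(b, a))
    }
  }
  expect_error(iupac_match("-", "A"), "IUPAC")
})

test_that("primer construction computes degeneracy and rejects gaps", {
  p <- primer("2195Bt", "TGRTTTTTTGGTCATCCRGAAGT", "forward")
  expect_equal(p$degeneracy, 4L)   # two R positions
  expect_equal(p$length, 23L)
  expect_error(primer("bad", "AC-GT"), "gaps")
  expect_equal(iupac_degeneracy("NRA"), 8L)
})

test_that("mismatch counting is position-exact against a brute-force oracle", {
  new_fwd <- whitefly_primers("new")$fwd
  # the degenerate forward primer accepts both published template variants
  expect_equal(count_mismatches(new_fwd, "TGGTTTTTTGGTCATCCAGAAGT")$mismatches, 0)
  expect_equal(count_mismatches(new_fwd, "TGATTTTTTGGTCATCCGGAAGT")$mismatches, 0)
  expect_equal(count_mismatches(new_fwd, new_fwd$residues)$mismatches, 0)

  set.seed(5)
  for (rep in 1:10) {
    win <- paste(sample(c("A", "C", "G", "T"), 23, replace = TRUE), collapse = "")
    p <- primer("x", win)
    k <- sample(0:4, 1)
    mut <- strsplit(win, "")[[1]]
    pos <- sort(sample(23, k))
    for (j in pos) mut[j] <- setdiff(c("A", "C", "G", "T"), mut[j])[1]
    got <- count_mismatches(p, paste(mut, collapse = ""))
    # oracle: position-wise comparison
    oracle <- which(strsplit(win, "")[[1]] != mut)
    expect_equal(got$positions, oracle)
    expect_equal(got$mismatches, k)
  }
  expect_error(count_mismatches(new_fwd, "ACGT"), "length")
})

test_that("template scanning agrees with an exhaustive window oracle", {
  set.seed(11)
  tpl <- random_records(1, 1000, prefix = "tpl")
  p <- primer("probe", substr(tpl$residues, 101, 123))   # planted at 0-based 100
  sites <- scan_template(p, tpl, max_mismatches = 0)
  plus <- sites[sites$strand == "+", ]
  expect_true(100 %in% plus$start)
  expect_equal(plus$mismatches[plus$start == 100], 0L)

  # brute-force oracle over every window and both strands, max_mm = 2
  brute <- function(primer, tmpl, max_mm) {
    tc <- strsplit(tmpl, "")[[1]]
    pc <- strsplit(primer$residues, "")[[1]]
    rc <- strsplit(reverse_complement(primer$residues), "")[[1]]
    hits <- list()
    for (s in 0:(length(tc) - length(pc))) {
      w <- tc[s + seq_along(pc)]
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") pc else rc
        mm <- sum(!mapply(iupac_match, pat, w))
        if (mm <= max_mm) hits[[length(hits) + 1]] <-
            data.frame(start = s, strand = strand, mismatches = mm)
      }
    }
    do.call(rbind, hits)
  }
  short <- random_records(1, 300, seed = 12)
  probe <- primer("probe2", substr(short$residues, 51, 66))
  got <- scan_template(probe, short, max_mismatches = 2)
  want <- brute(probe, short$residues, 2)
  got_o <- got[order(got$start, got$strand), c("start", "strand", "mismatches")]
  want_o <- want[order(want$start, want$strand), ]
  expect_equal(as.data.frame(got_o), want_o, ignore_attr = TRUE)

  # a primer absent from the template yields nothing at 0 mismatches
  absent <- primer("none", paste(rep("A", 30), collapse = ""))
  expect_equal(nrow(scan_template(absent,
                                  seq_records("t", paste(rep("C", 200), collapse = "")),
                                  max_mismatches = 0)), 0L)
  # template shorter than primer: empty, not an error
  expect_equal(nrow(scan_template(absent, seq_records("s", "ACGT"), 0)), 0L)
})

test_that("reverse-orientation sites are reported in plus-strand coordinates", {
  set.seed(13)
  rev_p <- whitefly_primers("old")$rev    # 25-mer
  tpl_chars <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  rc <- strsplit(reverse_complement(rev_p$residues), "")[[1]]
  tpl_chars[941:965] <- rc                 # 0-based [940, 965)
  tpl <- seq_records("t", paste(tpl_chars, collapse = ""))
  sites <- scan_template(rev_p, tpl, max_mismatches = 0)
  minus <- sites[sites$strand == "-", ]
  expect_true(nrow(minus) >= 1)
  expect_true(all(c(940L) %in% minus$start))
  expect_equal(minus$end[minus$start == 940], 965L)
})

test_that("in-silico PCR pairs sites into products of the planted length", {
  sets <- whitefly_primers("new")
  pl <- plant_primer_template(sets$fwd, sets$rev, 867, 0, 0, seed = 3)
  amp <- in_silico_pcr(sets$fwd, sets$rev, pl$template, max_mismatches = 0)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_length, 867L)
  expect_equal(amp$fwd_start, pl$fwd_site$start)
  expect_equal(amp$rev_end, pl$rev_site$end)

  # property: product length equals planted spacing over random plantings
  for (seed in 1:8) {
    set.seed(seed)
    len <- sample(200:1500, 1)
    pl2 <- plant_primer_template(sets$fwd, sets$rev, len, 0, 0, seed = seed)
    amp2 <- in_silico_pcr(sets$fwd, sets$rev, pl2$template, max_mismatches = 0)
    expect_true(len %in% amp2$product_length)
  }

  # no reverse site within max_product -> empty
  amp3 <- in_silico_pcr(sets$fwd, sets$rev, pl$template,
                        max_mismatches = 0, max_product = 500)
  expect_equal(nrow(amp3), 0L)
})

test_that("two forward sites with one reverse site give two sorted amplicons", {
  set.seed(17)
  fwd <- primer("f", "ACGTACGTACGTACGT", "forward")
  rev <- primer("r", "TTGGCCAATTGGCCAA", "reverse")
  chars <- sample(c("A", "C", "G", "T"), 1200, replace = TRUE)
  fc <- strsplit(fwd$residues, "")[[1]]
  rc <- strsplit(reverse_complement(rev$residues), "")[[1]]
  chars[101:116] <- fc
  chars[301:316] <- fc
  chars[901:916] <- rc
  tpl <- seq_records("t", paste(chars, collapse = ""))
  amp <- in_silico_pcr(fwd, rev, tpl, max_mismatches = 0)
  # oracle: exhaustive pairing of the planted sites
  expect_equal(amp$product_length, sort(c(916 - 300, 916 - 100)))
  expect_false(is.unsorted(amp$product_length))
})

test_that("mismatch profiling summarises per sequence and per position", {
  new_fwd <- whitefly_primers("new")$fwd
  perfect <- seq_records(paste0("s", 1:4),
                         rep("TGGTTTTTTGGTCATCCAGAAGT", 4))
  prof <- mismatch_profile(new_fwd, perfect)
  expect_equal(prof$per_sequence$mismatches, rep(0L, 4))
  expect_equal(sum(prof$per_position$n_mismatching), 0)

  # a gap inside the window counts as a mismatch at that position
  gapped <- seq_records("g", "TGGT-TTTTGGTCATCCAGAAGT")
  prof_g <- mismatch_profile(new_fwd, gapped)
  expect_equal(prof_g$per_sequence$mismatches, 1L)
  expect_equal(prof_g$union_positions, 5L)

  expect_error(mismatch_profile(new_fwd, seq_records("x", "ACGT")), "ragged")
})

test_that("the old reverse primer shows six union mismatch positions on the synthetic mitogenome block", {
  fx <- synthetic_mt12_block()
  prof <- mismatch_profile(whitefly_primers("old")$rev, fx$block)
  expect_equal(prof$union_positions, fx$union_positions)
  expect_equal(length(prof$union_positions), 6L)
  # oracle: per-row counts equal the planted per-sequence sets
  expect_equal(prof$per_sequence$mismatches,
               lengths(fx$per_seq), ignore_attr = TRUE)
})

test_that("degenerate design covers exactly the observed bases", {
  blk <- seq_records(c("a", "b"), c("AACG", "GACG"))
  p <- design_degenerate(blk, name = "d")
  expect_equal(p$residues, "RACG")
  expect_equal(p$degeneracy, 2L)

  # invariant columns give a degeneracy-1 consensus
  same <- seq_records(c("a", "b", "c"), rep("ACGTACGT", 3))
  expect_equal(design_degenerate(same)$degeneracy, 1L)

  # property: zero mismatches against every design input (random blocks)
  for (seed in 1:10) {
    blk2 <- random_records(4, 20, seed = seed)
    des <- design_degenerate(blk2)
    for (i in 1:4) {
      expect_equal(count_mismatches(des, blk2$residues[i])$mismatches, 0)
    }
    expect_equal(des$degeneracy, {
      m <- do.call(rbind, strsplit(blk2$residues, ""))
      prod(apply(m, 2, function(col) length(unique(col))))
    })
  }

  gap_blk <- seq_records(c("a", "b"), c("AC-G", "ACTG"))
  expect_error(design_degenerate(gap_blk), "gap")
})
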