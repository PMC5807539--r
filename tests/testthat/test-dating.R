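test_that("calibration scales node heights linearly to the root age", {
  # root height 0.40, one interior node at 0.10, root age 130 -> 32.5 mya
  tr <- read_newick("((A:0.1,B:0.1):0.3,(C:0.3,D:0.3):0.1);")
  dated <- calibrate_ages(tr, calibration_config(root_age_mean = 130))
  ages <- dated$node_age
  n_tip <- ape::Ntip(dated)
  expect_equal(unname(ages[seq_len(n_tip)]), rep(0, 4))       # tips at 0 mya
  root_age <- ages[n_tip + 1L]
  expect_equal(unname(root_age), 130)
  mrca_ab <- ape::getMRCA(dated, c("A", "B"))
  expect_equal(unname(ages[mrca_ab]), 0.1 / 0.4 * 130)        # 32.5 mya
  expect_equal(clade_age(dated, c("A", "B")), 32.5)

  # scale invariance: doubling all branch lengths changes no age
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 2
  dated2 <- calibrate_ages(tr2, calibration_config(root_age_mean = 130))
  expect_equal(dated2$node_age, dated$node_age)

  # calibration linearity: scaling the root age scales every age exactly
  dated3 <- calibrate_ages(tr, calibration_config(root_age_mean = 65))
  expect_equal(dated3$node_age, dated$node_age / 2)

  # ages decrease from root to tips along every edge
  for (e in seq_len(nrow(dated$edge))) {
    expect_gte(dated$node_age[dated$edge[e, 1]],
               dated$node_age[dated$edge[e, 2]])
  }

  # non-ultrametric input is refused with advice
  bad <- read_newick("((A:0.1,B:0.4):0.3,C:0.4);")
  expect_error(calibrate_ages(bad), "not ultrametric")
})

test_that("the clock statistic is zero on ultrametric trees and flags rate shifts", {
  tr <- read_newick("((A:0.1,B:0.1):0.3,(C:0.3,D:0.3):0.1);")
  ct <- clock_test(tr)
  expect_equal(ct$cv, 0)
  expect_false(ct$flagged)

  # doubling one terminal branch breaks the clock
  tr2 <- tr
  tip_a <- which(tr2$edge[, 2] == which(tr2$tip.label == "A"))
  tr2$edge.length[tip_a] <- tr2$edge.length[tip_a] * 2
  ct2 <- clock_test(tr2)
  expect_gt(ct2$cv, 0)

  # clock-simulated trees stay below the limit in >= 90% of replicates:
  # sequences evolve on a fixed balanced clock tree, the NJ estimate is
  # rooted on one side of the true root split (whose midpoint is the true
  # root on a balanced tree), and only sampling noise remains
  sim_tree <- read_newick(paste0(
    "(((a:5,b:5):5,(c:5,d:5):5):5,((e:5,f:5):5,(g:5,h:5):5):5);"))
  below <- 0
  for (seed in 1:50) {
    recs <- evolve_sequences(sim_tree, 2000, 0.005, "JC69", seed = seed + 1000)
    nj <- root_with_outgroup(nj_tree(pairwise_matrix(recs, model = "k2p")),
                             c("e", "f", "g", "h"))
    if (!clock_test(nj)$flagged) below <- below + 1
  }
  expect_gte(below, 45)
})

test_that("strict-clock dating recovers true node ages on clock simulations", {
  # simulate under a known clock, calibrate the root to its true age, and
  # compare every recovered interior-node age to the generating tree
  set.seed(2024)
  rel_errors <- c()
  for (rep in 1:20) {
    tr <- simulate_yule(8, 0.1, seed = 3000 + rep)
    true_root <- max(tr$node_age)
    recs <- evolve_sequences(tr, 5000, 0.005, "JC69", seed = 4000 + rep)
    dm <- pairwise_matrix(recs, model = "k2p")
    dated <- calibrate_ages(upgma_tree(dm),
                            calibration_config(root_age_mean = true_root))
    for (node in (ape::Ntip(tr) + 2L):(ape::Ntip(tr) + tr$Nnode)) {
      tips <- ape::extract.clade(tr, node)$tip.label
      if (!ape::is.monophyletic(dated, tips)) next
      est <- clade_age(dated, tips)
      truth <- tr$node_age[node]
      rel_errors <- c(rel_errors, abs(est - truth) / truth)
    }
  }
  expect_gt(length(rel_errors), 50)          # most clades recovered
  expect_lte(mean(rel_errors), 0.15)
})

test_that("bootstrap intervals are seeded, cover truth, and shrink with signal", {
  tr <- simulate_yule(8, 0.1, seed = 71)
  recs <- evolve_sequences(tr, 2000, 0.005, "JC69", seed = 72)
  clade <- ape::extract.clade(tr, ape::Ntip(tr) + 2L)$tip.label
  cfg <- calibration_config(root_age_mean = max(tr$node_age),
                            bootstrap_reps = 20, seed = 9)
  b1 <- bootstrap_ages(recs, list(focal = clade), cfg, model = "k2p")
  b2 <- bootstrap_ages(recs, list(focal = clade), cfg, model = "k2p")
  expect_equal(b1, b2)                       # fixed seed, identical intervals
  expect_lte(b1$age_lo95, b1$age_hi95)
  expect_equal(b1$n_replicates_present, 20L)

  # reps = 0 -> point estimates only
  b0 <- bootstrap_ages(recs, list(focal = clade),
                       calibration_config(bootstrap_reps = 0), model = "k2p")
  expect_equal(b0$n_replicates_present, 0L)
  expect_true(is.na(b0$age_lo95))

  # coverage: true clade ages inside the 95% interval for >= 80% of cases
  hits <- 0; total <- 0
  for (rep in 1:10) {
    tr2 <- simulate_yule(8, 0.1, seed = 500 + rep)
    recs2 <- evolve_sequences(tr2, 2000, 0.005, "JC69", seed = 600 + rep)
    cfg2 <- calibration_config(root_age_mean = max(tr2$node_age),
                               bootstrap_reps = 20, seed = rep)
    nodes <- (ape::Ntip(tr2) + 2L):(ape::Ntip(tr2) + tr2$Nnode)
    clades <- lapply(nodes, function(nd) ape::extract.clade(tr2, nd)$tip.label)
    names(clades) <- paste0("c", nodes)
    bb <- bootstrap_ages(recs2, clades, cfg2, model = "k2p")
    for (k in seq_along(nodes)) {
      if (bb$n_replicates_present[k] < 10) next
      total <- total + 1
      truth <- tr2$node_age[nodes[k]]
      if (truth >= bb$age_lo95[k] && truth <= bb$age_hi95[k]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("a zero-noise alignment gives a degenerate interval", {
  # very long sequences at tiny rate: bootstrap spread collapses
  tr <- simulate_yule(4, 0.2, seed = 31)
  recs <- evolve_sequences(tr, 20000, 0.002, "JC69", seed = 32)
  clade <- ape::extract.clade(tr, ape::Ntip(tr) + 2L)$tip.label
  cfg <- calibration_config(root_age_mean = max(tr$node_age),
                            bootstrap_reps = 20, seed = 3)
  bb <- bootstrap_ages(recs, list(f = clade), cfg, model = "k2p")
  width <- bb$age_hi95 - bb$age_lo95
  expect_lt(width / bb$age_mya, 0.35)        # narrow relative to the age
})

test_that("dated trees serialise with age annotations", {
  tr <- read_newick("((A:0.1,B:0.1):0.3,(C:0.3,D:0.3):0.1);")
  dated <- calibrate_ages(tr, calibration_config())
  nwk <- withr::local_tempfile(fileext = ".nwk")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  ages <- tibble::tibble(clade = "AB", age_mya = 32.5)
  write_dated_tree(dated, ages, nwk, tsv)
  line <- readLines(nwk)
  expect_match(line, "age=130")
  expect_equal(readr::read_tsv(tsv, show_col_types = FALSE)$age_mya, 32.5)
})
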