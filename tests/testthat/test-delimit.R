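## small hand-built panel/query set on exact planted divergences:
## 1000-nt sequences so divergence fractions are round numbers
build_fixture <- function(seed = 101) {
  set.seed(seed)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  refs <- seq_records(
    c("REFA", "REFB"),
    c(base, mutate_string(base, 120))        # references 12% apart
  )
  panel <- make_panel(refs, tibble::tibble(
    id = refs$id, species = c("SpA", "SpB"), clade = "x", is_tabaci = TRUE
  ))
  list(base = base, panel = panel)
}

test_that("queries assign to the closest reference at or under the threshold", {
  fx <- build_fixture()
  queries <- seq_records(
    c("q_same", "q_near", "q_boundary", "q_far"),
    c(fx$base,                       # identical: identity 100
      mutate_string(fx$base, 10),    # 1% off SpA
      mutate_string(fx$base, 35),    # exactly at the 3.5% boundary
      mutate_string(fx$base, 60))    # 6% off everything
  )
  asn <- assign_species(queries, fx$panel)
  expect_equal(asn$status, c("assigned", "assigned", "assigned", "new_cluster"))
  expect_equal(asn$species[1:3], rep("SpA", 3))
  expect_equal(asn$identity_pct[1], 100)
  # boundary: equality keeps the known species (only strictly greater
  # divergence creates a new cluster)
  expect_equal(asn$divergence[3], 0.035)
  expect_true(is.na(asn$species[4]))
  expect_equal(asn$closest_reference[1], "REFA")
  # runner-up species reported with its identity
  expect_equal(asn$runner_up_species[1], "SpB")
  expect_error(assign_species(queries, fx$panel[0, ]), "empty")
})

test_that("unassignable queries cluster at the threshold with stable names", {
  set.seed(55)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  g1 <- mutate_string(base, 100)
  g2 <- mutate_string(base, 200)
  queries <- seq_records(
    paste0("u", 1:5),
    c(g1, mutate_string(g1, 8), mutate_string(g1, 9),   # tight group of 3
      g2, mutate_string(g2, 10))                        # group of 2
  )
  cl <- cluster_new_species(queries, delimit_config())
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(cl$cluster[1:3], rep("NEW1", 3))   # first-occurrence naming
  expect_equal(cl$cluster[4:5], rep("NEW2", 2))

  # oracle: brute-force single-linkage components over all pairs
  dm <- pairwise_matrix(queries, model = "p")
  adj <- dm$d <= 0.035
  comp <- seq_len(5)
  for (it in 1:5) {
    for (i in 1:5) for (j in 1:5) if (adj[i, j]) comp[comp == comp[j]] <- comp[i]
  }
  expect_equal(length(unique(comp)), length(unique(cl$cluster)))
  expect_equal(as.integer(factor(comp, levels = unique(comp))),
               as.integer(factor(cl$cluster, levels = unique(cl$cluster))))

  # singleton
  one <- cluster_new_species(queries[1, ], delimit_config())
  expect_equal(one$cluster, "NEW1")
  # all mutually close -> one cluster under either linkage
  near <- seq_records(paste0("n", 1:3),
                      c(g1, mutate_string(g1, 3), mutate_string(g1, 3)))
  for (linkage in c("single", "complete")) {
    cl2 <- cluster_new_species(near, delimit_config(linkage = linkage))
    expect_equal(length(unique(cl2$cluster)), 1L)
  }
})

test_that("the species report aggregates counts, accessions and ranges", {
  fx <- build_fixture(103)
  queries <- seq_records(
    c(paste0("a", 1:3), "b1", "x1", "x2"),
    c(fx$base, mutate_string(fx$base, 5), mutate_string(fx$base, 16),
      mutate_string(fx$panel$residues[2], 4),
      mutate_string(fx$base, 70), mutate_string(fx$base, 72))
  )
  out <- run_delimit(queries, fx$panel)
  rep <- out$report
  expect_equal(sum(rep$n_sequences), nrow(queries))     # counts conserved
  expect_equal(rep$species[!rep$is_new], c("SpA", "SpB"))
  spa <- rep[rep$species == "SpA", ]
  expect_equal(spa$n_sequences, 3L)
  expect_equal(spa$identity_max, 100)
  expect_equal(spa$identity_min, round(100 * (1 - 16 / 1000), 1))
  expect_true(all(rep$is_new == grepl("^NEW", rep$species)))
  expect_match(spa$identity_range, "^98.4")

  # empty input gives an empty report
  expect_equal(nrow(species_report(queries[0, ] |>
                                     assign_species(fx$panel))), 0L)
})

test_that("new-species counting applies the strict 96.5% identity rule", {
  survey <- closest_relative_identity()
  tab <- survey[survey$is_tabaci, ]
  expect_equal(count_new_species(tab, threshold = 0.035), 5L)
  # the flagged rows are exactly the survey's five new putative species
  flagged <- tab$species[tab$identity_max < 96.5]
  expect_setequal(flagged, c("SSA9", "SSA10", "SSA11", "SSA12", "SSA13"))

  all_perfect <- tibble::tibble(identity_max = rep(100, 4))
  expect_equal(count_new_species(all_perfect), 0L)
  # exactly 96.5% is not counted (strict inequality)
  expect_equal(count_new_species(tibble::tibble(identity_max = 96.5)), 0L)
})

test_that("delimitation partitions queries exactly once and is idempotent", {
  sim <- make_panel_and_queries(standard_plan(), seq_length = 600, seed = 77)
  out <- run_delimit(sim$queries, sim$panel)
  ids_seen <- c(out$assignments$query_id[out$assignments$status == "assigned"],
                out$clusters$query_id)
  expect_setequal(ids_seen, sim$queries$id)
  expect_equal(length(ids_seen), nrow(sim$queries))

  # idempotence: adopt the new cluster members as references (under
  # reference accessions of their own) and re-run on the original queries
  new_ids <- out$clusters$query_id
  adopted <- sim$queries[sim$queries$id %in% new_ids,
                         c("id", "description", "residues", "length")]
  adopted_species <- out$clusters$cluster[match(adopted$id,
                                                out$clusters$query_id)]
  adopted$id <- paste0("REFN_", adopted$id)
  aug_records <- dplyr::bind_rows(
    sim$panel[, c("id", "description", "residues", "length")], adopted
  )
  aug_meta <- tibble::tibble(
    id = aug_records$id,
    species = c(sim$panel$species, adopted_species),
    clade = "x", is_tabaci = TRUE
  )
  aug_panel <- make_panel(aug_records, aug_meta)
  back <- assign_species(sim$queries[sim$queries$id %in% new_ids, ], aug_panel)
  expect_true(all(back$status == "assigned"))
  expect_equal(back$species,
               out$clusters$cluster[match(back$query_id, out$clusters$query_id)])
})

test_that("lowering the threshold never decreases the number of new clusters", {
  sim <- make_panel_and_queries(standard_plan(), seq_length = 600, seed = 78)
  thresholds <- c(0.06, 0.04, 0.035, 0.02, 0.01)
  n_new <- vapply(thresholds, function(th) {
    out <- run_delimit(sim$queries, sim$panel, delimit_config(th))
    length(unique(out$clusters$cluster))
  }, numeric(1))
  expect_false(is.unsorted(n_new))   # monotone non-decreasing as th drops
})
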