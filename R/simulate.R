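#' Simulate a Yule (pure-birth) tree with known node ages
#'
#' Lineage count grows from the root outward; construction draws the
#' epoch durations backward from the tips: with `k` extant lineages the
#' epoch lasts Exp(`k * birth_rate`), and two uniformly chosen lineages
#' join, down to the root. The expected root age is therefore
#' `sum(1/(k*birth_rate))` for `k = 2..n_taxa`. Branch lengths are in
#' million years (my); true node ages are returned in `node_age`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate in events/my/lineage.
#' @param tip_prefix tip label prefix (labels `t1..tn`).
#' @param seed optional integer seed (uses the session RNG when `NULL`).
#' @return a rooted binary `ape::phylo` tree with `node_age` (my, indexed
#'   by node number; tips 0).
#' @export
simulate_yule <- function(n_taxa, birth_rate = 0.1, tip_prefix = "t",
                          seed = NULL) {
  stopifnot(n_taxa >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_taxa)
  n_nodes <- 2L * n - 1L
  ## active lineages are node numbers; internal nodes numbered n+1 .. 2n-1
  ## with the root first (ape convention: root = n+1)
  active <- seq_len(n)
  age <- numeric(n_nodes)
  parent <- integer(n_nodes)
  next_internal <- n_nodes   # fill internal node slots from last to n+1
  t_now <- 0
  for (k in seq(n, 2L)) {
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    pick <- sample(seq_along(active), 2L)
    node <- next_internal
    next_internal <- next_internal - 1L
    age[node] <- t_now
    parent[active[pick]] <- node
    active <- c(active[-pick], node)
  }
  edge <- cbind(parent[-(n + 1L)], seq_len(n_nodes)[-(n + 1L)])
  keep <- edge[, 1] != 0
  edge <- edge[keep, , drop = FALSE]
  tr <- list(edge = edge,
             edge.length = age[edge[, 1]] - age[edge[, 2]],
             tip.label = paste0(tip_prefix, seq_len(n)),
             Nnode = n - 1L)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr$node_age <- age
  tr
}

## K80 transition-probability matrix for branch length d (expected
## substitutions/site) and transition/transversion rate ratio kappa.
## JC69 is kappa = 1. Rows/cols ordered A, C, G, T.
.k80_pmatrix <- function(d, kappa) {
  bt <- d / (kappa + 2)          # beta * t (each transversion rate)
  at <- kappa * bt               # alpha * t (transition rate)
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  bases <- c("A", "C", "G", "T")
  P <- matrix(p_tv, 4, 4, dimnames = list(bases, bases))
  diag(P) <- p_same
  P["A", "G"] <- P["G", "A"] <- p_ts
  P["C", "T"] <- P["T", "C"] <- p_ts
  P
}

#' Evolve sequences along a tree under JC69 or K2P
#'
#' The root sequence is uniform random over A/C/G/T; each branch applies
#' the closed-form K80 transition-probability matrix for its expected
#' substitutions/site (`rate * branch length`). With `kappa = 1` this is
#' Jukes--Cantor. The per-branch substitution events are tallied in the
#' `substitution_log` attribute (transitions vs transversions), which is
#' how a large `kappa` can be seen to favour transitions.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths in my.
#' @param seq_length sites to simulate (>= 1).
#' @param rate substitution rate in substitutions/site/my.
#' @param model `"JC69"` or `"K2P"`.
#' @param kappa transition/transversion rate ratio for `"K2P"`
#'   (default 4).
#' @param seed optional integer seed.
#' @return a record tibble (one row per tip, ids = tip labels) with a
#'   `substitution_log` attribute (tibble: `branch_child`, `transitions`,
#'   `transversions`).
#' @export
evolve_sequences <- function(tree, seq_length, rate, model = c("JC69", "K2P"),
                             kappa = 4, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(tree, "phylo"), seq_length >= 1, rate >= 0)
  if (model == "JC69") kappa <- 1
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  seqs <- vector("list", n_nodes)
  seqs[[root]] <- sample(bases, seq_length, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")$edge  # parents before children
  log_rows <- vector("list", nrow(ord))
  for (e in seq_len(nrow(ord))) {
    par <- ord[e, 1]; child <- ord[e, 2]
    len <- tree$edge.length[which(tree$edge[, 1] == par &
                                    tree$edge[, 2] == child)]
    d <- rate * len
    parent_seq <- seqs[[par]]
    if (d == 0) {
      child_seq <- parent_seq
    } else {
      P <- .k80_pmatrix(d, kappa)
      child_seq <- parent_seq
      for (b in bases) {
        idx <- which(parent_seq == b)
        if (length(idx) > 0) {
          child_seq[idx] <- sample(bases, length(idx), replace = TRUE,
                                   prob = P[b, ])
        }
      }
    }
    changed <- which(child_seq != parent_seq)
    purine <- parent_seq[changed] %in% c("A", "G")
    purine_child <- child_seq[changed] %in% c("A", "G")
    log_rows[[e]] <- tibble::tibble(
      branch_child = child,
      transitions = sum(purine == purine_child),
      transversions = sum(purine != purine_child)
    )
    seqs[[child]] <- child_seq
  }
  out <- seq_records(
    id = tree$tip.label,
    residues = vapply(seqs[seq_len(n_tip)], paste, character(1), collapse = "")
  )
  attr(out, "substitution_log") <- dplyr::bind_rows(log_rows)
  out
}

## apply `k` substitutions to a base-character vector at distinct random
## positions; each substituted base becomes one of the 3 alternatives
.mutate_seq <- function(chars, k) {
  if (k == 0) return(chars)
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  chars
}

#' Generate a reference panel plus queries with known species structure
#'
#' Emulates a barcode survey: each planned species gets a reference
#' sequence and member queries within `max_within` divergence of it;
#' species marked `novel = TRUE` get members but no reference, placed at
#' least `min_between` divergence from every reference, so delimitation
#' should recover them as new putative species. The realised structure is
#' verified with the distance module and regenerated (up to `max_attempts`
#' rejections) until the plan holds.
#'
#' @param species_plan a data frame with columns `species`, `n_members`,
#'   `max_within` (divergence fraction), `min_between` (divergence
#'   fraction), and optionally `novel` (logical, default `FALSE`).
#' @param seq_length sequence length in nt (default 867, the survey's
#'   partial-barcode length).
#' @param seed integer seed.
#' @param max_attempts rejection-sampling cap (default 1000).
#' @return a list with `panel` (reference panel tibble), `queries` (record
#'   tibble) and `truth` (tibble: `query_id`, `species`, `novel`).
#' @export
make_panel_and_queries <- function(species_plan, seq_length = 867, seed = 1L,
                                   max_attempts = 1000L) {
  stopifnot(is.data.frame(species_plan),
            all(c("species", "n_members", "max_within", "min_between") %in%
                  names(species_plan)))
  if (is.null(species_plan$novel)) species_plan$novel <- FALSE
  if (any(species_plan$max_within >= species_plan$min_between)) {
    stop("infeasible plan: max_within must be < min_between", call. = FALSE)
  }
  stopifnot(seq_length >= 100)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_sp <- nrow(species_plan)
  ## substitutions seeding each species centroid: enough that two
  ## centroids' mostly-disjoint mutation sets exceed min_between
  k_centroid <- ceiling(0.75 * max(species_plan$min_between) * seq_length)

  for (attempt in seq_len(max_attempts)) {
    root <- sample(bases, seq_length, replace = TRUE)
    centroids <- lapply(seq_len(n_sp), function(i) .mutate_seq(root, k_centroid))
    refs <- queries <- truth <- list()
    for (i in seq_len(n_sp)) {
      sp <- species_plan$species[i]
      ## members within max_within of the centroid AND of each other:
      ## each member at most half the within budget from the centroid
      k_member_max <- max(0L, floor(species_plan$max_within[i] * seq_length / 2))
      members <- lapply(seq_len(species_plan$n_members[i]), function(j) {
        .mutate_seq(centroids[[i]], sample.int(k_member_max + 1L, 1) - 1L)
      })
      if (!species_plan$novel[i]) {
        refs[[sp]] <- paste(centroids[[i]], collapse = "")
      }
      queries[[sp]] <- vapply(members, paste, character(1), collapse = "")
      truth[[sp]] <- tibble::tibble(
        query_id = sprintf("%s_q%02d", sp, seq_along(members)),
        species = sp, novel = species_plan$novel[i]
      )
    }
    truth_tbl <- dplyr::bind_rows(truth)
    query_tbl <- seq_records(id = truth_tbl$query_id,
                             residues = unlist(queries, use.names = FALSE))
    ref_ids <- paste0("REF_", names(refs))
    panel_recs <- seq_records(id = ref_ids,
                              residues = unlist(refs, use.names = FALSE))
    panel <- make_panel(panel_recs, tibble::tibble(
      id = ref_ids, species = names(refs), clade = "sim", is_tabaci = TRUE
    ))
    if (.plan_holds(species_plan, panel, query_tbl, truth_tbl)) {
      return(list(panel = panel, queries = query_tbl, truth = truth_tbl,
                  seed = seed, attempts = attempt))
    }
  }
  stop("could not realise the species plan in ", max_attempts,
       " attempts; relax within/between divergences", call. = FALSE)
}

## post-hoc verification that generated data satisfy the species plan
.plan_holds <- function(plan, panel, queries, truth) {
  all_rec <- dplyr::bind_rows(
    queries[, c("id", "description", "residues", "length")],
    panel[, c("id", "description", "residues", "length")]
  )
  dm <- pairwise_matrix(all_rec, model = "p")
  for (i in seq_len(nrow(plan))) {
    sp <- plan$species[i]
    member_ids <- truth$query_id[truth$species == sp]
    own_ids <- c(member_ids,
                 if (!plan$novel[i]) panel$id[panel$species == sp])
    if (length(own_ids) > 1) {
      sub <- dm$d[own_ids, own_ids]
      if (max(sub) > plan$max_within[i]) return(FALSE)
    }
    other_refs <- panel$id[panel$species != sp]
    if (length(other_refs) > 0 &&
        min(dm$d[member_ids, other_refs]) < plan$min_between[i]) return(FALSE)
    if (plan$novel[i] && nrow(panel) > 0 &&
        min(dm$d[member_ids, panel$id]) < plan$min_between[i]) return(FALSE)
  }
  TRUE
}

#' Build a template carrying planted primer binding sites
#'
#' A random template is generated with the forward primer's site planted
#' on the plus strand and the reverse primer's reverse complement planted
#' downstream so the product spans exactly `product_length` nt. A chosen
#' number of non-matching substitutions is planted inside each site, which
#' makes amplification succeed or fail at a given mismatch tolerance by
#' construction.
#'
#' @param fwd,rev forward and reverse [primer()]s.
#' @param product_length desired product length in nt (must exceed the
#'   combined primer lengths).
#' @param fwd_mismatches,rev_mismatches planted mismatch counts.
#' @param flank extra random sequence on each side (default 50 nt).
#' @param seed optional integer seed.
#' @param id template id.
#' @return a list with `template` (record tibble), `fwd_site` and
#'   `rev_site` (truth tibbles: `start`, `end`, `strand`,
#'   `mismatch_positions` primer-relative).
#' @export
plant_primer_template <- function(fwd, rev, product_length,
                                  fwd_mismatches = 0, rev_mismatches = 0,
                                  flank = 50L, seed = NULL, id = "template") {
  stopifnot(inherits(fwd, "primer"), inherits(rev, "primer"))
  if (product_length <= fwd$length + rev$length) {
    stop("product_length must exceed the combined primer lengths", call. = FALSE)
  }
  if (fwd_mismatches > fwd$length || rev_mismatches > rev$length) {
    stop("cannot plant more mismatches than the primer has positions",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  total <- 2L * flank + product_length
  chars <- sample(bases, total, replace = TRUE)

  ## realise a primer as concrete bases, then corrupt chosen positions
  plant <- function(p, n_mm) {
    pc <- .seq_chars(p$residues)
    site <- vapply(pc, function(code) sample(.IUPAC_EXPANSION[[code]], 1),
                   character(1))
    mm_pos <- sort(sample.int(p$length, n_mm))
    for (j in mm_pos) {
      off <- setdiff(bases, .IUPAC_EXPANSION[[pc[j]]])
      site[j] <- sample(off, 1)
    }
    list(site = unname(site), mm_pos = mm_pos)
  }

  fp <- plant(fwd, fwd_mismatches)
  rp <- plant(rev, rev_mismatches)
  fwd_start <- flank                       # 0-based
  rev_end <- flank + product_length
  rev_start <- rev_end - rev$length
  chars[fwd_start + seq_len(fwd$length)] <- fp$site
  ## the reverse primer reads 5'->3' on the minus strand: plant its
  ## reverse complement on the plus strand
  rc <- rev(unname(.COMPLEMENT[rp$site]))
  chars[rev_start + seq_len(rev$length)] <- rc
  template <- seq_records(id = id, residues = paste(chars, collapse = ""))
  list(
    template = template,
    fwd_site = tibble::tibble(start = fwd_start, end = fwd_start + fwd$length,
                              strand = "+", mismatch_positions = list(fp$mm_pos)),
    rev_site = tibble::tibble(start = rev_start, end = rev_end,
                              strand = "-", mismatch_positions = list(rp$mm_pos))
  )
}
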