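#' Configuration for fossil-calibrated strict-clock dating
#'
#' The root of the tree is anchored to the age of the oldest whitefly
#' fossil relevant to the group, c. 130 million years (mya); node heights
#' in substitutions/site are rescaled linearly to absolute time. The
#' standard deviation describes the calibration uncertainty and is used
#' only to jitter the root age across bootstrap replicates when
#' `jitter_calibration` is on (off by default, so the fossil mean acts as
#' a fixed point calibration). The constant 123 mya is carried as
#' provenance (a conventional starting value associated with this
#' calibration) and plays no role in the arithmetic.
#'
#' @param root_age_mean calibration mean in mya (default 130).
#' @param root_age_sd calibration standard deviation in mya (default 20).
#' @param prior_initial documented starting value in mya (default 123;
#'   unused by the strict-clock math).
#' @param bootstrap_reps number of bootstrap replicates for age intervals
#'   (default 100).
#' @param jitter_calibration if `TRUE`, each bootstrap replicate draws its
#'   root age from Normal(root_age_mean, root_age_sd).
#' @param seed integer seed for bootstrap resampling.
#' @return a list of class `calibration_config`.
#' @export
calibration_config <- function(root_age_mean = 130, root_age_sd = 20,
                               prior_initial = 123, bootstrap_reps = 100L,
                               jitter_calibration = FALSE, seed = 1L) {
  stopifnot(root_age_mean > 0, root_age_sd >= 0, bootstrap_reps >= 0)
  structure(list(root_age_mean = root_age_mean, root_age_sd = root_age_sd,
                 prior_initial = prior_initial,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 jitter_calibration = isTRUE(jitter_calibration),
                 seed = as.integer(seed)),
            class = "calibration_config")
}

#' Calibrate node ages on an ultrametric tree
#'
#' Under a strict molecular clock, node heights (substitutions/site above
#' the tips) are proportional to elapsed time, so fixing the root to the
#' fossil age converts every height linearly:
#' `age(node) = height(node) / height(root) * root_age_mean`. Tips get age
#' 0 and the root gets exactly the calibration age; rescaling all branch
#' lengths by a common factor leaves the ages unchanged.
#'
#' @param tree a rooted ultrametric `ape::phylo` tree.
#' @param cfg a [calibration_config()].
#' @param tol ultrametricity tolerance on root-to-tip spread (default
#'   1e-6, in the tree's branch-length units).
#' @return the tree with an added numeric vector `node_age` (mya, indexed
#'   by node number) and attribute `root_age`.
#' @export
calibrate_ages <- function(tree, cfg = calibration_config(), tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_ultrametric(tree, tol)) {
    stop("tree is not ultrametric (root-to-tip spread exceeds ", tol,
         "); build it with upgma_tree() or check the clock with clock_test()",
         call. = FALSE)
  }
  h <- node_heights(tree)
  root_h <- h[ape::Ntip(tree) + 1L]
  ages <- if (root_h == 0) rep(0, length(h)) else h / root_h * cfg$root_age_mean
  ages[seq_len(ape::Ntip(tree))] <- 0
  tree$node_age <- ages
  attr(tree, "root_age") <- cfg$root_age_mean
  tree
}

#' Age of the most recent common ancestor of a set of tips
#'
#' @param dated a tree returned by [calibrate_ages()].
#' @param tips character vector of tip labels (>= 2).
#' @return age in mya.
#' @export
clade_age <- function(dated, tips) {
  stopifnot(!is.null(dated$node_age), length(tips) >= 2)
  node <- ape::getMRCA(dated, tips)
  dated$node_age[node]
}

#' Strict-clock adequacy statistic
#'
#' Coefficient of variation of root-to-tip path lengths on a rooted tree:
#' 0 for a perfectly clock-like (ultrametric) tree, growing as lineages
#' depart from rate constancy. Trees above the limit are flagged; the
#' caller decides whether to proceed.
#'
#' @param tree a rooted `ape::phylo` tree with branch lengths.
#' @param limit flag threshold on the coefficient of variation
#'   (default 0.1).
#' @return a list with `cv`, `flagged`, `root_to_tip` (named vector).
#' @export
clock_test <- function(tree, limit = 0.1) {
  rtt <- root_to_tip(tree)
  m <- mean(rtt)
  cv <- if (m == 0) 0 else stats::sd(rtt) / m
  list(cv = cv, flagged = cv > limit, root_to_tip = rtt)
}

#' Bootstrap confidence intervals for calibrated clade ages
#'
#' Alignment columns are resampled with replacement; each replicate
#' recomputes the divergence matrix, rebuilds the UPGMA tree, recalibrates
#' the root to the fossil age and records the age of each focal clade's
#' most recent common ancestor. A clade contributes to a replicate only
#' when it is monophyletic there; replicates where it is absent are
#' counted and excluded from its interval.
#'
#' @param records a pre-aligned record tibble (equal lengths).
#' @param focal_clades named list of character vectors of tip ids.
#' @param cfg a [calibration_config()] (reps, seed, optional calibration
#'   jitter).
#' @param model distance model passed to [pairwise_matrix()].
#' @return a tibble: `clade`, `age_mya` (point estimate from the full
#'   alignment), `age_mean`, `age_lo95`, `age_hi95`,
#'   `n_replicates_present`.
#' @export
bootstrap_ages <- function(records, focal_clades, cfg = calibration_config(),
                           model = "p") {
  stopifnot(is.data.frame(records), length(unique(records$length)) == 1)
  if (is.null(names(focal_clades)) || any(!nzchar(names(focal_clades)))) {
    stop("focal_clades must be a named list", call. = FALSE)
  }
  point_tree <- calibrate_ages(
    upgma_tree(pairwise_matrix(records, model = model)), cfg)
  for (cl in focal_clades) {
    if (length(setdiff(cl, point_tree$tip.label)) > 0) {
      stop("focal clade tips missing from data", call. = FALSE)
    }
  }
  point <- vapply(focal_clades, function(cl) clade_age(point_tree, cl),
                  numeric(1))
  reps <- cfg$bootstrap_reps
  if (reps == 0) {
    return(tibble::tibble(clade = names(focal_clades), age_mya = unname(point),
                          age_mean = NA_real_, age_lo95 = NA_real_,
                          age_hi95 = NA_real_, n_replicates_present = 0L))
  }
  L <- records$length[1]
  chars <- do.call(rbind, lapply(records$residues, .seq_chars))
  set.seed(cfg$seed)
  draws <- matrix(NA_real_, nrow = reps, ncol = length(focal_clades))
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    boot <- records
    boot$residues <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    boot$length <- L
    cfg_r <- cfg
    if (cfg$jitter_calibration) {
      cfg_r$root_age_mean <- max(1e-6, stats::rnorm(1, cfg$root_age_mean,
                                                    cfg$root_age_sd))
    }
    tr <- calibrate_ages(upgma_tree(pairwise_matrix(boot, model = model)),
                         cfg_r)
    for (k in seq_along(focal_clades)) {
      cl <- focal_clades[[k]]
      if (ape::is.monophyletic(tr, cl)) {
        draws[r, k] <- clade_age(tr, cl)
      }
    }
  }
  tibble::tibble(
    clade = names(focal_clades),
    age_mya = unname(point),
    age_mean = apply(draws, 2, mean, na.rm = TRUE),
    age_lo95 = apply(draws, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
    age_hi95 = apply(draws, 2, stats::quantile, probs = 0.975, na.rm = TRUE),
    n_replicates_present = apply(draws, 2, function(x) sum(!is.na(x)))
  )
}

#' Write a dated tree and its age table
#'
#' The newick output annotates each internal node with its calibrated age
#' in a comment-style label (`age=<mya>`); the TSV carries one row per
#' focal clade.
#'
#' @param dated a tree from [calibrate_ages()].
#' @param ages a tibble from [bootstrap_ages()] (optional).
#' @param newick_path,table_path output paths (either may be `NULL`).
#' @return `invisible(NULL)`.
#' @export
write_dated_tree <- function(dated, ages = NULL, newick_path = NULL,
                             table_path = NULL) {
  if (!is.null(newick_path)) {
    lab <- dated
    n_int <- lab$Nnode
    int_ages <- lab$node_age[ape::Ntip(lab) + seq_len(n_int)]
    lab$node.label <- sprintf("age=%.3f", int_ages)
    writeLines(ape::write.tree(lab, digits = 12), newick_path)
  }
  if (!is.null(table_path) && !is.null(ages)) {
    readr::write_tsv(ages, table_path)
  }
  invisible(NULL)
}
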