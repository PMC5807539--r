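#' Neighbor-joining tree from a divergence matrix
#'
#' Canonical Saitou--Nei agglomeration (via `ape::nj`). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero; the total clamped deficit is recorded in the `clamped_deficit`
#' attribute.
#'
#' @param dm a `div_matrix` or symmetric numeric matrix with dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "div_matrix")) dm$d else dm
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 taxa", call. = FALSE)
  if (any(!is.finite(d))) stop("distances must be finite", call. = FALSE)
  tr <- ape::nj(stats::as.dist(d))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_deficit") <- deficit
  tr
}

#' UPGMA (average-linkage) ultrametric tree
#'
#' Average-linkage agglomeration on the divergence matrix; each internal
#' node's height is half its merge distance, so tip-to-tip path lengths on
#' an ultrametric input reproduce the input distances exactly.
#'
#' @param dm a `div_matrix` or symmetric numeric matrix with dimnames.
#' @return a rooted ultrametric `ape::phylo` tree.
#' @export
upgma_tree <- function(dm) {
  d <- if (inherits(dm, "div_matrix")) dm$d else dm
  if (nrow(d) < 2) stop("UPGMA needs at least 2 taxa", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Root a tree on the branch separating an outgroup
#'
#' The root is placed at the midpoint of the branch that separates the
#' outgroup tips from the ingroup. The outgroup must form one side of a
#' split in the unrooted tree; otherwise an error names the offending set.
#'
#' @param tree an `ape::phylo` tree.
#' @param outgroup character vector of outgroup tip labels.
#' @return a rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing) > 0) {
    stop("outgroup tip(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(outgroup) >= length(tree$tip.label)) {
    stop("outgroup cannot contain every tip", call. = FALSE)
  }
  ut <- ape::unroot(tree)
  ntip <- ape::Ntip(ut)
  og <- match(outgroup, ut$tip.label)
  ig <- setdiff(seq_len(ntip), og)
  ## tip set below each node in the current (arbitrary) representation
  desc <- vector("list", ntip + ut$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  post <- ape::reorder.phylo(ut, "postorder")$edge
  for (e in seq_len(nrow(post))) {
    desc[[post[e, 1]]] <- c(desc[[post[e, 1]]], desc[[post[e, 2]]])
  }
  ## the separating branch has exactly the outgroup (or exactly the
  ## ingroup) below it
  target <- NA_integer_
  for (e in seq_len(nrow(ut$edge))) {
    below <- desc[[ut$edge[e, 2]]]
    if (setequal(below, og) || setequal(below, ig)) { target <- e; break }
  }
  if (is.na(target)) {
    stop("outgroup {", paste(outgroup, collapse = ","),
         "} does not form one side of a split in the tree", call. = FALSE)
  }
  phytools::reroot(ut, node.number = ut$edge[target, 2],
                   position = ut$edge.length[target] / 2)
}

#' Read a newick tree
#'
#' @param x a newick string or a path to a newick file.
#' @return an `ape::phylo` tree; duplicate tip labels are an error.
#' @export
read_newick <- function(x) {
  tr <- if (file.exists(x) && !grepl("\\(", x)) {
    ape::read.tree(file = x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(tr)) stop("could not parse newick input", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' Write a tree as newick
#'
#' @param tree an `ape::phylo` tree.
#' @param path optional file path; if `NULL` the newick string is returned.
#' @return the newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Root-to-node depths and node heights
#'
#' Heights are measured from the tips upward (substitutions/site on
#' divergence-scaled trees): `height(node) = max root-to-tip depth -
#' root-to-node depth`.
#'
#' @param tree a rooted `ape::phylo` tree.
#' @return a numeric vector of heights indexed by node number
#'   (tips `1..Ntip`, then internal nodes).
#' @export
node_heights <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Root-to-tip path lengths
#'
#' @param tree a rooted `ape::phylo` tree.
#' @return named numeric vector, one entry per tip.
#' @export
root_to_tip <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  stats::setNames(depths[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Is a rooted tree ultrametric?
#'
#' @param tree a rooted `ape::phylo` tree.
#' @param tol absolute tolerance on root-to-tip spread.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  rtt <- root_to_tip(tree)
  diff(range(rtt)) <= tol
}
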