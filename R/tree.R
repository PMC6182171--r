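#' Read a species tree with branch lengths
#'
#' Parses a rooted newick tree whose branch lengths are in substitutions per
#' site. Every edge must carry a branch length and all lengths must be
#' non-negative; tip labels must be unique. These are the assumptions under
#' which per-base conservation scores and branch-length (BBL) conservation
#' scores are well defined.
#'
#' @param x A newick string, or the path of a file containing one.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
#' @examples
#' tr <- read_species_tree("((A:0.1,B:0.2):0.3,C:0.4);")
#' total_branch_length(tr)
read_species_tree <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (!grepl("(", x, fixed = TRUE) && file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    x
  }
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0)) {
    stop("malformed newick: unbalanced ')' at offset ",
         which(depth < 0)[1] - 1L)
  }
  if (depth[length(depth)] != 0) {
    stop("malformed newick: ", depth[length(depth)], " unclosed '(' ")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("malformed newick: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick: not a parseable tree")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("tree is missing branch lengths on one or more edges")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tree$tip.label)) stop("duplicate species labels in tree")
  tree
}

#' Total branch length of a phylogeny
#'
#' The sum of all branch lengths (substitutions/site); used to normalise
#' per-base conservation so that percent-identity scores lie in \[0, 1\].
#'
#' @param tree A `phylo` object.
#' @return Total branch length (numeric scalar).
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  sum(tree$edge.length)
}

# Precompute, for each edge, the set of leaves below it, as an
# edge-by-species logical incidence matrix. An edge belongs to the minimal
# subtree spanning a leaf set S iff S has members both below and not below
# the edge, so induced lengths reduce to one matrix product over columns.
tree_branch_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  post <- ape::reorder.phylo(tree, "postorder")
  # leafset per node, accumulated bottom-up in postorder edge order
  nodesets <- vector("list", max(edges))
  for (i in seq_len(ntip)) nodesets[[i]] <- i
  ord <- match(
    paste(post$edge[, 1], post$edge[, 2]),
    paste(edges[, 1], edges[, 2])
  )
  below <- matrix(FALSE, nrow = nrow(edges), ncol = ntip,
                  dimnames = list(NULL, tree$tip.label))
  for (j in seq_len(nrow(edges))) {
    e <- ord[j]
    child <- edges[e, 2]
    leaves <- nodesets[[child]]
    below[e, leaves] <- TRUE
    parent <- edges[e, 1]
    nodesets[[parent]] <- c(nodesets[[parent]], leaves)
  }
  list(
    below = below,
    lengths = tree$edge.length,
    species = tree$tip.label,
    total = sum(tree$edge.length)
  )
}

# Induced subtree lengths for many leaf sets at once. `member` is a
# species-by-set logical matrix (rownames = species). Returns one length
# per column; sets of size <= 1 get 0.
induced_lengths <- function(index, member) {
  stopifnot(is.matrix(member), !is.null(rownames(member)))
  if (!all(rownames(member) %in% index$species)) {
    stop("unknown species: ",
         paste(setdiff(rownames(member), index$species), collapse = ", "))
  }
  m <- matrix(FALSE, nrow = length(index$species), ncol = ncol(member),
              dimnames = list(index$species, NULL))
  m[rownames(member), ] <- member
  counts <- index$below %*% m                # edges x sets
  sizes <- colSums(m)
  inside <- counts > 0 & sweep(counts, 2, sizes, "<")
  as.numeric(crossprod(inside, index$lengths))
}

#' Branch length of the subtree induced by a set of species
#'
#' Length of the minimal spanning subtree of the phylogeny connecting the
#' given leaves (the Steiner subtree over the tree). Returns 0 for sets of
#' size one or zero. This quantity is the "branch length over which a base
#' is conserved" in per-base conservation scoring and the BBL score of a
#' binding-site prediction.
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of species names (must be tree tips).
#' @param index Optional precomputed [tree_branch_index] result (internal
#'   speed-up when calling repeatedly).
#' @return Branch length (substitutions/site).
#' @export
#' @examples
#' tr <- read_species_tree("((A:0.1,B:0.2):0.3,C:0.4);")
#' induced_subtree_length(tr, c("A", "C"))  # 0.8
induced_subtree_length <- function(tree, leaves, index = NULL) {
  stopifnot(is.character(leaves) || length(leaves) == 0L)
  leaves <- unique(leaves)
  if (is.null(index)) index <- tree_branch_index(tree)
  if (!all(leaves %in% index$species)) {
    stop("unknown species: ",
         paste(setdiff(leaves, index$species), collapse = ", "))
  }
  if (length(leaves) <= 1L) return(0)
  member <- matrix(index$species %in% leaves, ncol = 1,
                   dimnames = list(index$species, NULL))
  induced_lengths(index, member)
}
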