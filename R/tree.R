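#' Phylogeny with branch tags
#'
#' A `tagged_tree` couples an `ape::phylo` tree (branch lengths in expected
#' codon substitutions per site) with one tag per branch. Tags partition the
#' branches into a test (foreground) set and a reference (background) set:
#' two-ratio branch models estimate omega separately on the two sets, and
#' relaxation models apply the selection-intensity exponent k on the test
#' set only. Branches are identified by their child node: tip branches by
#' the tip label, internal branches by `"node<N>"` with N the ape node
#' number.
#'
#' @param phy an `ape::phylo` object with branch lengths.
#' @param tags character vector of per-branch tags in `phy$edge` order, or a
#'   named vector keyed by branch id; missing branches default to
#'   `"reference"`. `NULL` means all-reference.
#' @return object of class `tagged_tree`: list with elements `phy` and
#'   `tags` (character, one per edge, named by branch id).
#' @seealso [tag_clade()], [read_tagged_newick()]
#' @export
tagged_tree <- function(phy, tags = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("duplicate taxon names in tree")
  ids <- branch_ids(phy)
  full <- rep("reference", nrow(phy$edge))
  names(full) <- ids
  if (!is.null(tags)) {
    if (!is.null(names(tags))) {
      unknown <- setdiff(names(tags), ids)
      if (length(unknown)) {
        stop("unknown branch id(s): ", paste(unknown, collapse = ", "))
      }
      full[names(tags)] <- unname(tags)
    } else {
      if (length(tags) != nrow(phy$edge)) {
        stop("tags must have one entry per edge")
      }
      full[] <- tags
    }
  }
  structure(list(phy = phy, tags = full), class = "tagged_tree")
}

#' Branch identifiers of a tree
#'
#' @param phy an `ape::phylo` (or [tagged_tree]).
#' @return character vector of branch ids in `phy$edge` order.
#' @export
branch_ids <- function(phy) {
  if (inherits(phy, "tagged_tree")) phy <- phy$phy
  child <- phy$edge[, 2]
  ntip <- length(phy$tip.label)
  ifelse(child <= ntip, phy$tip.label[child], paste0("node", child))
}

#' Tag the branches of a clade
#'
#' Marks as test (or any other tag) all branches inside the smallest clade
#' containing `tips`, optionally including the stem branch leading to it.
#' With a single tip, only that terminal branch is tagged.
#'
#' @param tree a [tagged_tree].
#' @param tips character vector of tip labels spanning the focal clade.
#' @param tag tag to assign (default `"test"`).
#' @param stem include the branch subtending the clade's MRCA?
#' @return the modified [tagged_tree].
#' @export
tag_clade <- function(tree, tips, tag = "test", stem = TRUE) {
  stopifnot(inherits(tree, "tagged_tree"))
  phy <- tree$phy
  missing <- setdiff(tips, phy$tip.label)
  if (length(missing)) {
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  tipn <- match(tips, phy$tip.label)
  if (length(tipn) == 1L) {
    sel <- phy$edge[, 2] == tipn
  } else {
    mrca <- ape::getMRCA(phy, tipn)
    desc <- descendant_nodes(phy, mrca)
    sel <- phy$edge[, 1] %in% c(mrca, desc)
    if (stem) sel <- sel | phy$edge[, 2] == mrca
  }
  tree$tags[sel] <- tag
  tree
}

descendant_nodes <- function(phy, node) {
  out <- integer(0)
  stack <- phy$edge[phy$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- phy$edge[phy$edge[, 1] %in% stack, 2]
  }
  out
}

#' Branches carrying a given tag
#'
#' @param tree a [tagged_tree].
#' @param tag tag value to select (default `"test"`).
#' @return character vector of branch ids.
#' @export
tagged_branches <- function(tree, tag = "test") {
  stopifnot(inherits(tree, "tagged_tree"))
  names(tree$tags)[tree$tags == tag]
}

#' Swap test and reference tags
#'
#' @param tree a [tagged_tree] tagged with `"test"`/`"reference"`.
#' @return the tree with the two tag sets exchanged.
#' @export
swap_tags <- function(tree) {
  stopifnot(inherits(tree, "tagged_tree"))
  tags <- tree$tags
  tree$tags[tags == "test"] <- "reference"
  tree$tags[tags == "reference"] <- "test"
  tree
}

#' @export
print.tagged_tree <- function(x, ...) {
  cat("Tagged tree:", length(x$phy$tip.label), "tips,",
      nrow(x$phy$edge), "branches\n")
  tab <- table(x$tags)
  cat("  tags:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Postorder traversal data shared by the likelihood and the simulator:
# edges reordered so every child is visited before its parent.
tree_traversal <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  idx <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  list(edge = po$edge, lengths = po$edge.length,
       orig_index = idx,
       ntip = length(phy$tip.label),
       nnode = length(phy$tip.label) + phy$Nnode,
       root = po$edge[nrow(po$edge), 1])
}
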