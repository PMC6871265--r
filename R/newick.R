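#' Uncalibrated ultrametric topology
#'
#' Wraps a rooted ultrametric \code{phylo} tree whose branch lengths carry
#' relative (not absolute) time. Depths are normalized so that tips sit at
#' relative depth 0 and the root at depth 1; the super-taxon machinery only
#' ever uses these relative depths, so any overall scaling of the input tree
#' is irrelevant.
#'
#' @param tree An \code{ape} \code{phylo} object with branch lengths.
#' @param tol Relative tolerance on ultrametricity (max spread of root-to-tip
#'   path lengths after normalization).
#' @return An object of class \code{ultrametric_topology} with elements
#'   \code{tree} (depth-normalized \code{phylo}) and \code{depth} (named
#'   relative depth per tip and labeled internal node).
#' @export
ultrametric_topology <- function(tree, tol = 1e-9) {
  if (!inherits(tree, "phylo")) fb_stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) fb_stop("tree must have branch lengths")
  ntip <- length(tree$tip.label)

  if (ntip == 1L) {
    # degenerate single-tip tree: one path, trivially ultrametric
    depth <- c(0, 1)
    names(depth) <- c(tree$tip.label, "root")
    tree$edge.length <- tree$edge.length / sum(tree$edge.length)
    return(structure(list(tree = tree, depth = depth, n_tip = 1L),
                     class = "ultrametric_topology"))
  }

  dist_root <- ape::node.depth.edgelength(tree)  # distance from root
  H <- max(dist_root[seq_len(ntip)])
  spread <- (max(dist_root[seq_len(ntip)]) - min(dist_root[seq_len(ntip)])) / H
  if (spread > tol)
    fb_stop("tree is not ultrametric: relative tip-depth spread = ",
            format(spread), " exceeds tolerance ", format(tol))

  tree$edge.length <- tree$edge.length / H
  depth <- (H - dist_root) / H
  depth[seq_len(ntip)] <- 0  # snap residual numerical error at the tips
  node_names <- character(length(depth))
  node_names[seq_len(ntip)] <- tree$tip.label
  inner <- if (!is.null(tree$node.label)) tree$node.label else
    rep("", tree$Nnode)
  inner[!nzchar(inner)] <- paste0("node", seq_len(tree$Nnode))[!nzchar(inner)]
  node_names[ntip + seq_len(tree$Nnode)] <- inner
  names(depth) <- node_names

  structure(list(tree = tree, depth = depth, n_tip = ntip),
            class = "ultrametric_topology")
}

#' Read an ultrametric tree from a newick file
#'
#' Reads a single rooted newick tree with branch lengths, verifies
#' ultrametricity and normalizes depths so the root sits at relative depth 1.
#' Normalization is idempotent: reading an already-normalized tree changes
#' nothing.
#'
#' @param path Newick file with one tree.
#' @param tol Relative ultrametricity tolerance (default \code{1e-9}).
#' @return An [ultrametric_topology()].
#' @export
read_newick <- function(path, tol = 1e-9) {
  if (!file.exists(path)) fb_stop("file not found: ", path)
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) fb_stop(path, " contains more than one tree")
  if (is.null(tree)) fb_stop("could not parse a tree from ", path)
  ultrametric_topology(tree, tol = tol)
}

#' @export
print.ultrametric_topology <- function(x, ...) {
  cat(sprintf("<ultrametric_topology: %d tip(s), root depth 1>\n", x$n_tip))
  invisible(x)
}
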