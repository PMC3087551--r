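#' Simulate a rooted binary species tree
#'
#' Draws a pure-birth (Yule) tree with `n_taxa` leaves and rescales it so the
#' maximum root-to-tip path equals `height` expected substitutions per site.
#' Leaves are labelled `G01, G02, ...` and internal nodes `N<k>`; a branch is
#' identified throughout the package by the label of its child node.
#'
#' @param n_taxa number of leaves (>= 3).
#' @param seed integer seed; identical seeds give byte-identical trees.
#' @param height root-to-tip depth in expected substitutions/site. The
#'   default, 0.75, emulates a deep bacterial phylogeny in which distant
#'   family members retain roughly 20-30 percent identity.
#' @return an [ape::rphylo()]-style `phylo` object, rooted and binary, with
#'   tip and node labels set.
#' @export
simulate_species_tree <- function(n_taxa, seed, height = 0.75) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 3)
    stop("n_taxa must be a single integer >= 3")
  n_taxa <- as.integer(n_taxa)
  tree <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * (height / max(depths[seq_len(n_taxa)]))
  tree$tip.label <- sprintf("G%02d", seq_len(n_taxa))
  tree$node.label <- sprintf("N%d", n_taxa + seq_len(tree$Nnode))
  tree
}

# Label of every node (tips then internals), indexed by ape node number.
node_labels <- function(tree) {
  c(tree$tip.label,
    if (is.null(tree$node.label)) sprintf("N%d", ape::Ntip(tree) + seq_len(tree$Nnode))
    else tree$node.label)
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# parent[i] = ape number of the parent of node i (NA for root)
parent_map <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- rep(NA_integer_, n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

children_map <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# branch length leading into node i (NA for root)
branch_lengths_in <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  bl <- rep(NA_real_, n)
  bl[tree$edge[, 2]] <- tree$edge.length
  bl
}

# tips (ape numbers) descending from node
descendant_tips <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(node)
  ch <- children_map(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= nt) out <- c(out, v) else stack <- c(stack, ch[[v]])
  }
  sort(out)
}

node_number <- function(tree, label) {
  labs <- node_labels(tree)
  i <- match(label, labs)
  if (is.na(i)) stop("unknown branch/node id: ", label)
  i
}
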