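#' Build the genomes x families presence (copy-count) matrix
#'
#' @param assignments data.frame with columns genome, family, gene_id and
#'   optionally evidence ("RBH", "HMM", ...); one row per assigned gene.
#' @param genomes,families row/column universe (defaults: those observed).
#' @return list of class `presence_matrix`: `counts` (integer matrix),
#'   `provenance` (character matrix: "RBH", "HMM", "both" or "").
#' @export
build_presence_matrix <- function(assignments, genomes = NULL,
                                  families = NULL) {
  if (is.null(genomes)) genomes <- sort(unique(assignments$genome))
  if (is.null(families)) families <- sort(unique(assignments$family))
  if (anyDuplicated(genomes) || anyDuplicated(families))
    stop("genomes and families must be unique")
  counts <- matrix(0L, length(genomes), length(families),
                   dimnames = list(genomes, families))
  prov <- matrix("", length(genomes), length(families),
                 dimnames = list(genomes, families))
  if (nrow(assignments)) {
    bad <- setdiff(assignments$genome, genomes)
    if (length(bad)) stop("assignments reference unknown genomes: ",
                          paste(bad, collapse = ", "))
    ev <- if ("evidence" %in% names(assignments)) assignments$evidence
      else rep("RBH", nrow(assignments))
    for (i in seq_len(nrow(assignments))) {
      g <- assignments$genome[i]; f <- assignments$family[i]
      if (!f %in% families) next
      counts[g, f] <- counts[g, f] + 1L
      old <- prov[g, f]
      prov[g, f] <- if (old == "" || old == ev[i]) ev[i] else "both"
    }
  }
  structure(list(counts = counts, provenance = prov),
            class = "presence_matrix")
}

#' Dollo parsimony: single gain plus minimal losses for one family
#'
#' The gain is placed on the branch above the most recent common ancestor
#' of the present leaves; the losses are the maximal all-absent subtrees
#' below it. This placement is the unique loss-minimizing single-gain
#' reconstruction.
#'
#' @param presence named logical/integer vector over the tree's leaves
#'   (TRUE/count > 0 = family present).
#' @param tree rooted `phylo` with node labels (see
#'   [simulate_species_tree()]).
#' @return list: `gain` (branch id = node label), `losses` (branch ids),
#'   `n_losses`.
#' @export
dollo_infer <- function(presence, tree) {
  tips <- tree$tip.label
  pres <- tips[which(as.numeric(presence[tips]) > 0)]
  if (!length(pres)) stop("all-absent column: no gain placeable")
  labs <- node_labels(tree)
  gain_node <- if (length(pres) == 1) match(pres, tips)
    else ape::getMRCA(tree, pres)
  ch <- children_map(tree)
  nt <- ape::Ntip(tree)
  absent_tip <- setNames(!(tips %in% pres), tips)
  # all-absent status per node, computed on demand below the gain node
  all_absent <- function(node) {
    if (node <= nt) return(absent_tip[[tips[node]]])
    all(vapply(ch[[node]], all_absent, logical(1)))
  }
  losses <- character(0)
  walk <- function(node) {
    for (kid in ch[[node]]) {
      if (all_absent(kid)) losses <<- c(losses, labs[kid])
      else if (kid > nt) walk(kid)
    }
  }
  if (gain_node > nt) walk(gain_node)
  list(gain = labs[gain_node], losses = losses, n_losses = length(losses))
}

#' LCA reconciliation of a gene tree with a species tree
#'
#' Maps every gene-tree node to the last common ancestor of its leaves'
#' species; an internal gene-tree node mapping to the same species node as
#' one of its children is a duplication, charged to the species branch it
#' maps to. Implied losses are counted with the standard depth formula.
#'
#' @param gene_tree rooted `phylo` of gene copies.
#' @param species_tree rooted `phylo`.
#' @param leaf_map named character vector gene leaf -> species leaf
#'   (default: `<genome>|...` gene ids are mapped by their genome prefix).
#' @return list: `duplications` (species branch ids, one entry per event),
#'   `n_duplications`, `n_losses`, `node_map` (gene node -> species node
#'   label).
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map = NULL) {
  gt <- gene_tree; st <- species_tree
  if (!ape::is.rooted(gt) || !ape::is.rooted(st))
    stop("both trees must be rooted")
  if (is.null(leaf_map))
    leaf_map <- setNames(sub("\\|.*$", "", gt$tip.label), gt$tip.label)
  unmapped <- setdiff(gt$tip.label, names(leaf_map))
  if (length(unmapped))
    stop("unmapped gene leaves: ", paste(unmapped, collapse = ", "))
  bad <- setdiff(unname(leaf_map[gt$tip.label]), st$tip.label)
  if (length(bad))
    stop("species absent from species tree: ", paste(bad, collapse = ", "))
  s_labs <- node_labels(st)
  nt_s <- ape::Ntip(st)
  s_parent <- parent_map(st)
  s_depth <- rep(0L, nt_s + st$Nnode)
  for (node in rev(postorder_nodes(st))) # preorder
    if (!is.na(s_parent[node])) s_depth[node] <- s_depth[s_parent[node]] + 1L
  # ancestor lists for LCA
  anc_path <- function(node) {
    out <- node
    while (!is.na(s_parent[node])) { node <- s_parent[node]; out <- c(out, node) }
    out
  }
  lca2 <- function(a, b) {
    pa <- anc_path(a)
    pb <- anc_path(b)
    intersect(pa, pb)[1]
  }
  nt_g <- ape::Ntip(gt)
  ch_g <- children_map(gt)
  mapping <- rep(NA_integer_, nt_g + gt$Nnode)
  dup <- rep(FALSE, nt_g + gt$Nnode)
  for (node in postorder_nodes(gt)) {
    if (node <= nt_g) {
      mapping[node] <- match(leaf_map[[gt$tip.label[node]]], st$tip.label)
    } else {
      kids <- ch_g[[node]]
      m <- mapping[kids[1]]
      for (kid in kids[-1]) m <- lca2(m, mapping[kid])
      mapping[node] <- m
      dup[node] <- any(mapping[kids] == m)
    }
  }
  # implied losses: per gene edge parent->child, species-tree edges skipped
  # between the two mappings cost one loss each; below a duplication the
  # copy must also traverse the duplication's own species node.
  gp <- parent_map(gt)
  n_loss <- 0L
  for (node in seq_len(nt_g + gt$Nnode)) {
    p <- gp[node]
    if (is.na(p)) next
    dsteps <- s_depth[mapping[node]] - s_depth[mapping[p]]
    n_loss <- n_loss + if (dup[p]) dsteps else max(dsteps - 1L, 0L)
  }
  dup_nodes <- which(dup)
  list(duplications = s_labs[mapping[dup_nodes]],
       n_duplications = length(dup_nodes),
       n_losses = n_loss,
       node_map = setNames(s_labs[mapping], node_labels(gt)))
}
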