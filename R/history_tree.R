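#' True gene tree implied by a simulated family history
#'
#' Reconstructs the copy genealogy of one family directly from the planted
#' duplication/loss events: duplications become internal nodes on the
#' branch they occurred on, speciations follow the species tree, and
#' lineages with no surviving descendants are pruned. Useful as the exact
#' gene tree against which reconciliation-based inferences are scored.
#'
#' @param tree species tree the history was simulated on.
#' @param history one element of `$histories` from
#'   [simulate_family_histories()].
#' @return rooted `phylo` with tips `<genome>|<family>#<copy>`, or NULL
#'   when fewer than two copies survive.
#' @export
history_gene_tree <- function(tree, history) {
  labs <- node_labels(tree)
  ch <- children_map(tree)
  nt <- ape::Ntip(tree)
  ev <- history$events
  fam <- history$family
  # newick for the lineage of `copy` entering the branch above `node`
  lineage <- function(node, copy) {
    lab <- labs[node]
    state <- history$copies_at[[lab]]
    lost <- ev$copy[ev$type == "loss" & ev$branch == lab]
    if (copy %in% lost) return(NULL)
    dup_here <- ev[ev$type == "duplication" & ev$branch == lab, , drop = FALSE]
    below <- function(cp) {
      # subtree of cp from the bottom of this branch downward
      if (node <= nt) return(sprintf("%s|%s#%s", lab, fam, cp))
      kids <- Filter(Negate(is.null), lapply(ch[[node]], lineage, copy = cp))
      if (!length(kids)) return(NULL)
      if (length(kids) == 1) return(kids[[1]])
      sprintf("(%s)", paste(unlist(kids), collapse = ","))
    }
    parts <- below(copy)
    born <- dup_here$copy[dup_here$parent_copy == copy]
    for (nc in born) {
      sub <- below(nc)
      if (is.null(sub)) next
      parts <- if (is.null(parts)) sub
        else sprintf("(%s,%s)", parts, sub)
    }
    parts
  }
  root <- root_node(tree)
  gain_node <- node_number(tree, history$gain_branch)
  nwk <- if (gain_node == root) {
    kids <- Filter(Negate(is.null), lapply(ch[[root]], lineage, copy = "c1"))
    if (!length(kids)) NULL
    else if (length(kids) == 1) kids[[1]]
    else sprintf("(%s)", paste(unlist(kids), collapse = ","))
  } else lineage(gain_node, "c1")
  if (is.null(nwk) || !grepl(",", nwk)) return(NULL)
  if (!startsWith(nwk, "(")) nwk <- sprintf("(%s)", nwk)
  tr <- ape::read.tree(text = paste0(nwk, ";"))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}
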