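#' Simulate gene-family histories by per-branch duplication and loss
#'
#' Each family originates (one gene copy) at the top of its gain branch and
#' is then propagated tipward. Traversing a branch, every entering copy is
#' first lost with probability `1 - exp(-loss_rate)`; each surviving copy
#' then spawns one additional copy with probability `1 - exp(-dup_rate)`.
#' Copies born on a branch evolve independently from that branch onward.
#' Events are recorded against the branch (child-node label) they occur on.
#'
#' @param tree rooted species tree from [simulate_species_tree()].
#' @param n_families number of families (ignored when `gain_branches` is a
#'   named vector, whose names then define the families).
#' @param dup_rate,loss_rate per-branch event rates (>= 0).
#' @param gain_branches named character vector family -> branch id (node
#'   label). Default: every family gained at the root.
#' @param forced_duplications optional named list family -> branch ids on
#'   which the first entering copy duplicates deterministically (useful to
#'   plant a known event).
#' @param seed integer seed.
#' @return list with `histories` (per family: `events` data.frame,
#'   `copies_at` node-label -> copy ids, `leaf_counts`) and `truth`
#'   (gain/loss/duplication branches per family, leaf copy-count matrix).
#' @export
simulate_family_histories <- function(tree, n_families = 9,
                                      dup_rate = 0.05, loss_rate = 0.05,
                                      gain_branches = NULL,
                                      forced_duplications = NULL, seed = 1) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  labs <- node_labels(tree)
  if (is.null(gain_branches)) {
    fams <- sprintf("fam%02d", seq_len(n_families))
    gain_branches <- setNames(rep(labs[root_node(tree)], length(fams)), fams)
  }
  fams <- names(gain_branches)
  for (b in gain_branches) node_number(tree, b) # validates
  p_loss <- 1 - exp(-loss_rate)
  p_dup <- 1 - exp(-dup_rate)
  ch <- children_map(tree)
  nt <- ape::Ntip(tree)

  for (f in names(forced_duplications))
    for (b in forced_duplications[[f]]) node_number(tree, b)
  histories <- with_seed(seed, lapply(fams, function(fam) {
    gain_node <- node_number(tree, gain_branches[[fam]])
    forced <- forced_duplications[[fam]]
    if (is.null(forced)) forced <- character(0)
    events <- list()
    copies_at <- list()
    counter <- 0L
    new_copy <- function() { counter <<- counter + 1L; sprintf("c%d", counter) }
    # walk(node, entering): entering copies arrive at top of node's branch;
    # returns nothing, fills copies_at[[label]] with the state at the node.
    walk <- function(node, entering) {
      if (length(entering)) {
        lost <- entering[runif(length(entering)) < p_loss]
        kept <- setdiff(entering, lost)
        for (cp in lost)
          events[[length(events) + 1L]] <<- data.frame(
            branch = labs[node], type = "loss", copy = cp,
            parent_copy = NA_character_, stringsAsFactors = FALSE)
        born <- character(0)
        forced_here <- labs[node] %in% forced
        for (cp in kept) {
          force_this <- forced_here && cp == kept[1]
          if (force_this || runif(1) < p_dup) {
            nc <- new_copy()
            born <- c(born, nc)
            events[[length(events) + 1L]] <<- data.frame(
              branch = labs[node], type = "duplication", copy = nc,
              parent_copy = cp, stringsAsFactors = FALSE)
          }
        }
        state <- c(kept, born)
      } else state <- character(0)
      copies_at[[labs[node]]] <<- state
      if (node > nt) for (kid in ch[[node]]) walk(kid, state)
    }
    if (gain_node == root_node(tree)) {
      # gained above the root: one copy enters each root child's branch
      first <- new_copy()
      copies_at[[labs[gain_node]]] <- first
      for (kid in ch[[gain_node]]) walk(kid, first)
    } else {
      walk(gain_node, new_copy())
    }
    ev <- if (length(events)) do.call(rbind, events)
      else data.frame(branch = character(0), type = character(0),
                      copy = character(0), parent_copy = character(0),
                      stringsAsFactors = FALSE)
    leaf_counts <- vapply(tree$tip.label, function(tl)
      length(copies_at[[tl]]), integer(1))
    list(family = fam, gain_branch = gain_branches[[fam]], events = ev,
         copies_at = copies_at, leaf_counts = leaf_counts)
  }))
  names(histories) <- fams

  counts <- do.call(rbind, lapply(histories, `[[`, "leaf_counts"))
  rownames(counts) <- fams
  truth <- list(
    gains = as.list(gain_branches),
    losses = lapply(histories, function(h)
      h$events$branch[h$events$type == "loss"]),
    duplications = lapply(histories, function(h)
      h$events$branch[h$events$type == "duplication"]),
    leaf_counts = counts)
  list(histories = histories, truth = truth)
}
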