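#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken by
#' the lexicographically smallest pair of current node labels. Negative
#' branch-length estimates are clamped to zero with the deficit moved to
#' the sibling branch, so path lengths are preserved.
#'
#' @param D symmetric distance matrix with labelled rows/columns.
#' @return unrooted `phylo` object.
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 3) stop("need >= 3 taxa")
  # working copies; nodes carry newick fragments
  nwk <- setNames(as.list(labels), labels)
  d <- D
  dimnames(d) <- list(labels, labels)
  act <- labels
  while (length(act) > 2) {
    r <- length(act)
    dm <- d[act, act]
    net <- rowSums(dm)
    Q <- (r - 2) * dm - outer(net, net, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pairs <- cbind(act[cand[, 1]], act[cand[, 2]])
    pairs <- t(apply(pairs, 1, sort))
    o <- order(pairs[, 1], pairs[, 2])
    i <- pairs[o[1], 1]; j <- pairs[o[1], 2]
    li <- 0.5 * dm[i, j] + (net[i] - net[j]) / (2 * (r - 2))
    lj <- dm[i, j] - li
    # clamp negatives, moving the deficit to the sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    lj <- max(lj, 0)
    new_lab <- paste0("(", i, ",", j, ")")
    nwk[[new_lab]] <- sprintf("(%s:%.10g,%s:%.10g)", nwk[[i]], li,
                              nwk[[j]], lj)
    rest <- setdiff(act, c(i, j))
    newd <- setNames((d[rest, i] + d[rest, j] - d[i, j]) / 2, rest)
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_lab
    d[new_lab, rest] <- d[rest, new_lab] <- newd
    act <- c(rest, new_lab)
  }
  i <- act[1]; j <- act[2]
  len <- max(d[i, j], 0)
  nw <- sprintf("(%s:%.10g,%s:%.10g);", nwk[[i]], len / 2, nwk[[j]], len / 2)
  tr <- ape::read.tree(text = nw)
  ape::unroot(tr)
}

# leaf-set bipartitions of an unrooted tree as canonical keys
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  nt <- length(tips)
  ch <- children_map(tree)
  out <- character(0)
  for (node in (ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)) {
    dts <- tree$tip.label[descendant_tips(tree, node)]
    side <- sort(dts)
    if (length(side) <= 1 || length(side) >= nt - 1) next
    if (!(tips[1] %in% side)) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal bipartition of the
#' point-estimate tree the percentage of replicate trees containing it,
#' stored as internal node labels. With `n_reps = 0` the point tree is
#' returned with supports flagged as `NA`.
#'
#' @param aln a [protein_alignment()].
#' @param n_reps bootstrap replicates (the study-scale default is 1000).
#' @param seed integer seed.
#' @param correction distance correction passed to [distances()].
#' @return `phylo` with `node.label` giving percent support (root/trivial
#'   splits empty).
#' @export
nj_bootstrap <- function(aln, n_reps = 1000, seed = 1,
                         correction = "poisson") {
  point <- neighbor_joining(distances(aln, correction))
  X <- aln_codes(aln)
  L <- ncol(X)
  point_bips <- tree_bipartitions(point)
  counts <- setNames(rep(0, length(point_bips)), point_bips)
  if (n_reps > 0) {
    with_seed(seed, {
      for (b in seq_len(n_reps)) {
        cols <- sample.int(L, L, replace = TRUE)
        D <- suppressWarnings(dist_from_codes(X[, cols, drop = FALSE],
                                              correction))
        if (anyNA(D)) next
        dimnames(D) <- list(aln$ids, aln$ids)
        rb <- tree_bipartitions(neighbor_joining(D))
        hit <- point_bips %in% rb
        counts[hit] <- counts[hit] + 1
      }
    })
  }
  supp <- if (n_reps > 0) 100 * counts / n_reps else rep(NA_real_, length(counts))
  # attach as node labels
  nt <- ape::Ntip(point)
  labs <- rep("", point$Nnode)
  tips <- sort(point$tip.label)
  for (k in seq_len(point$Nnode)) {
    node <- nt + k
    side <- sort(point$tip.label[descendant_tips(point, node)])
    if (length(side) <= 1 || length(side) >= nt - 1) next
    if (!(tips[1] %in% side)) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(counts))
      labs[k] <- if (is.na(supp[key])) "NA" else sprintf("%.4g", supp[key])
  }
  point$node.label <- labs
  point
}

#' Root a tree on a named outgroup taxon
#' @param tree `phylo`.
#' @param outgroup tip label.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not in tree: ", outgroup)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Midpoint-root a tree
#'
#' Roots on the midpoint of the longest leaf-to-leaf path; used for gene
#' trees when no outgroup member is available.
#'
#' @param tree unrooted `phylo` with branch lengths.
#' @return rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  dm <- ape::dist.nodes(tree)
  nt <- ape::Ntip(tree)
  tipd <- dm[seq_len(nt), seq_len(nt)]
  ij <- which(tipd == max(tipd), arr.ind = TRUE)[1, ]
  i <- ij[1]; j <- ij[2]
  half <- tipd[i, j] / 2
  # walk the i -> j path; the midpoint lies on the first edge whose far end
  # is more than halfway along
  path <- ape::nodepath(tree, i, j)
  acc <- 0
  mid_edge <- NULL; pos_from_near <- 0
  for (s in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[s] & tree$edge[, 2] == path[s + 1]) |
                 (tree$edge[, 2] == path[s] & tree$edge[, 1] == path[s + 1]))
    len <- tree$edge.length[e]
    if (acc + len >= half - 1e-12) {
      mid_edge <- e; pos_from_near <- half - acc
      break
    }
    acc <- acc + len
  }
  if (is.null(mid_edge))
    return(ape::root(tree, outgroup = tree$tip.label[i], resolve.root = TRUE))
  child <- tree$edge[mid_edge, 2]
  og <- tree$tip.label[descendant_tips(tree, child)]
  if (length(og) == nt) og <- tree$tip.label[i]
  rooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  rooted
}
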