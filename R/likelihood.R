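#' Fixed-tree log-likelihood by Felsenstein pruning
#'
#' Scores an alignment on a given tree under a reversible amino-acid model
#' ([subs_model()], e.g. WAG), with among-site rate heterogeneity handled
#' by `k` discrete Gamma categories (equal probability, category-mean
#' rates). No topology search is performed. Gaps and unknown residues are
#' treated as missing data. For reversible models the value is invariant
#' under re-rooting.
#'
#' @param tree `phylo` whose tips match the alignment rows.
#' @param aln a [protein_alignment()].
#' @param model a [subs_model()]; its `alpha`/`k` control the Gamma.
#' @return total log-likelihood (natural log).
#' @export
loglik <- function(tree, aln, model) {
  if (!setequal(tree$tip.label, aln$ids))
    stop("tree tips and alignment rows differ")
  X <- aln_codes(aln)[tree$tip.label, , drop = FALSE]
  # site-pattern compression
  key <- apply(X, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.numeric(table(key)[key[first]])
  Xp <- X[, first, drop = FALSE]
  npat <- ncol(Xp)
  rates <- gamma_rates(model$alpha, model$k)
  tr <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  nt <- ape::Ntip(tr)
  ch <- children_map(tr)
  blin <- branch_lengths_in(tr)
  ord <- rev(postorder_nodes(tr))
  site_l <- matrix(0, length(rates), npat)
  for (ri in seq_along(rates)) {
    partial <- vector("list", nt + tr$Nnode)
    for (node in postorder_nodes(tr)) {
      if (node <= nt) {
        P <- matrix(1, 20, npat)
        codes <- Xp[node, ]
        obs <- codes > 0
        P[, obs] <- 0
        P[cbind(codes[obs], which(obs))] <- 1
        partial[[node]] <- P
      } else {
        P <- matrix(1, 20, npat)
        for (kid in ch[[node]]) {
          t <- blin[kid]
          if (is.na(t)) t <- 0
          Pm <- subs_prob(model, t * rates[ri])
          P <- P * (Pm %*% partial[[kid]])
        }
        partial[[node]] <- P
      }
    }
    root <- nt + 1L
    site_l[ri, ] <- colSums(model$freqs * partial[[root]])
  }
  lik <- colMeans(site_l)
  sum(w * log(lik))
}

postorder_nodes <- function(tree) {
  nt <- ape::Ntip(tree)
  ch <- children_map(tree)
  out <- integer(0)
  visit <- function(node) {
    if (node > nt) for (kid in ch[[node]]) visit(kid)
    out <<- c(out, node)
  }
  visit(nt + 1L)
  out
}

#' Discrete-Gamma category rates
#'
#' Mean rates of `k` equal-probability bins of a Gamma(shape = alpha,
#' mean 1) distribution. `alpha = NULL` disables rate heterogeneity.
#'
#' @param alpha Gamma shape (larger = more homogeneous).
#' @param k number of categories.
#' @return numeric vector of `k` rates averaging 1 (or the single rate 1).
#' @export
gamma_rates <- function(alpha, k = 4L) {
  if (is.null(alpha)) return(1)
  stopifnot(alpha > 0, k >= 1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  r <- k * (pgamma(b[-1], shape = alpha + 1, rate = alpha) -
              pgamma(b[-(k + 1)], shape = alpha + 1, rate = alpha))
  r / mean(r) * 1
}
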