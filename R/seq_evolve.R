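#' Build a reversible amino-acid substitution model
#'
#' The rate matrix is `Q = S diag(pi)` (off-diagonal), normalized so the
#' mean substitution rate at equilibrium is 1, i.e. branch lengths are
#' expected substitutions per site. `"poisson"` uses equal exchangeabilities
#' and (by default) uniform frequencies; `"wag"` uses the WAG empirical
#' exchangeabilities and frequencies.
#'
#' @param type `"poisson"` or `"wag"`.
#' @param freqs optional length-20 equilibrium frequencies (order ARNDCQEGHILKMFPSTWYV).
#' @param alpha optional Gamma shape for among-site rate variation.
#' @param k number of discrete Gamma categories.
#' @return object of class `subs_model` with `Q`, `freqs`, eigensystem and
#'   Gamma settings.
#' @export
subs_model <- function(type = c("poisson", "wag"), freqs = NULL,
                       alpha = NULL, k = 4L) {
  type <- match.arg(type)
  if (type == "poisson") {
    S <- matrix(1, 20, 20)
    if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  } else {
    S <- wag_exchangeabilities()
    if (is.null(freqs)) freqs <- wag_frequencies()
  }
  stopifnot(length(freqs) == 20, abs(sum(freqs) - 1) < 1e-8)
  diag(S) <- 0
  Q <- S %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  # eigendecomposition of the symmetrized matrix for fast expm
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(type = type, Q = Q, freqs = freqs,
                 evec = diag(1 / sp) %*% eig$vectors,
                 ivec = t(eig$vectors) %*% diag(sp),
                 eval = eig$values, alpha = alpha, k = as.integer(k)),
            class = "subs_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model a [subs_model()].
#' @param t branch length (expected substitutions/site).
#' @return 20 x 20 stochastic matrix.
#' @export
subs_prob <- function(model, t) {
  P <- model$evec %*% (exp(model$eval * t) * model$ivec)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Plant a multi-block motif into a random root sequence
#'
#' Writes the blocks of `pattern` (see [motif_pattern()]) into a random
#' background sequence at spacings drawn within the pattern's spacer bounds,
#' and returns the motif columns so they can be held invariant during
#' evolution. Alternative-residue positions take their first alternative;
#' wildcard positions keep the background residue.
#'
#' @param length sequence length.
#' @param pattern a [motif_pattern()].
#' @param seed integer seed.
#' @param freqs background residue frequencies.
#' @return list: `seq` (string), `invariant` (1-based motif columns).
#' @export
plant_motif_root <- function(length, pattern, seed, freqs = rep(1 / 20, 20)) {
  with_seed(seed, {
    res <- sample(AA, length, replace = TRUE, prob = freqs)
    blk_len <- vapply(pattern$blocks, length, integer(1))
    nb <- length(blk_len)
    smin <- pmax(pattern$spacer_min, 1L)
    # place blocks with spacers near the low end so short sequences fit
    need <- sum(blk_len) + sum(smin + 2L)
    if (need > length) stop("sequence too short for the motif pattern")
    pos <- integer(nb)
    cur <- 1L
    for (b in seq_len(nb)) {
      if (b > 1) cur <- cur + blk_len[b - 1] + smin[b - 1] + sample(0:2, 1)
      pos[b] <- cur
    }
    invariant <- integer(0)
    for (b in seq_len(nb)) {
      for (p in seq_len(blk_len[b])) {
        alt <- pattern$blocks[[b]][[p]]
        col <- pos[b] + p - 1L
        if (!is.null(alt) && !identical(alt, "*")) {
          res[col] <- alt[[1]]
          invariant <- c(invariant, col)
        }
      }
    }
    list(seq = paste(res, collapse = ""), invariant = invariant,
         block_starts = pos)
  })
}

#' Generate a random background protein sequence
#' @param length sequence length.
#' @param freqs residue frequencies.
#' @return protein string.
#' @export
random_protein <- function(length, freqs = rep(1 / 20, 20)) {
  paste(sample(AA, length, replace = TRUE, prob = freqs), collapse = "")
}

#' Evolve family sequences along the species tree
#'
#' Sites evolve independently under `model`; columns listed in
#' `invariant_cols` for a family are never substituted (planted motif
#' blocks). Copies follow the duplication/loss history: a copy born on a
#' branch starts from its parent copy's sequence at the top of that branch
#' and evolves the branch independently.
#'
#' @param tree species tree.
#' @param histories `$histories` from [simulate_family_histories()].
#' @param root_seqs named character vector, one root sequence per family.
#' @param model a [subs_model()].
#' @param invariant_cols optional named list family -> integer columns.
#' @param seed integer seed.
#' @return list: `genomes` (genome -> named vector of protein sequences,
#'   gene ids `<genome>|<family>#<copy>`), `meta` (gene_id, genome, family,
#'   copy data.frame).
#' @export
evolve_sequences <- function(tree, histories, root_seqs, model,
                             invariant_cols = NULL, seed = 1) {
  fams <- names(histories)
  if (!all(fams %in% names(root_seqs)))
    stop("missing root sequence for: ",
         paste(setdiff(fams, names(root_seqs)), collapse = ", "))
  if (any(!nzchar(root_seqs[fams]))) stop("empty root sequence")
  ch <- children_map(tree)
  labs <- node_labels(tree)
  nt <- ape::Ntip(tree)
  blin <- branch_lengths_in(tree)
  genomes <- setNames(vector("list", nt), tree$tip.label)
  meta <- list()

  evolve_one <- function(codes, t, inv_mask) {
    if (t <= 0) return(codes)
    P <- subs_prob(model, t)
    cum <- t(apply(P, 1, cumsum))
    u <- runif(length(codes))
    new <- codes
    for (i in seq_along(codes)) {
      if (inv_mask[i]) next
      new[i] <- findInterval(u[i], cum[codes[i] + 1L, ], left.open = TRUE)
    }
    new
  }

  with_seed(seed, {
    for (fam in fams) {
      h <- histories[[fam]]
      root_codes <- aa_encode(root_seqs[[fam]], allow_x = FALSE)
      inv <- rep(FALSE, length(root_codes))
      if (!is.null(invariant_cols[[fam]])) inv[invariant_cols[[fam]]] <- TRUE
      ev <- h$events
      gain_node <- node_number(tree, h$gain_branch)
      # seqs[[copy]] at current node
      walk <- function(node, seqs_in) {
        lab <- labs[node]
        state <- h$copies_at[[lab]]
        t <- blin[node]
        if (is.na(t)) t <- 0
        dup_here <- ev[ev$type == "duplication" & ev$branch == lab, , drop = FALSE]
        seqs <- list()
        for (cp in state) {
          src <- cp
          i <- match(cp, dup_here$copy)
          if (!is.na(i)) src <- dup_here$parent_copy[i]
          base <- seqs_in[[src]]
          if (is.null(base)) next
          seqs[[cp]] <- evolve_one(base, t, inv)
        }
        if (node <= nt) {
          for (cp in names(seqs)) {
            gid <- sprintf("%s|%s#%s", lab, fam, cp)
            genomes[[lab]][gid] <<- aa_decode(seqs[[cp]])
            meta[[length(meta) + 1L]] <<- data.frame(
              gene_id = gid, genome = lab, family = fam, copy = cp,
              stringsAsFactors = FALSE)
          }
        } else {
          for (kid in ch[[node]]) walk(kid, seqs)
        }
      }
      # the founding copy is always "c1" (first id issued by the history)
      founder <- setNames(list(root_codes), "c1")
      if (gain_node == root_node(tree)) {
        for (kid in ch[[gain_node]]) walk(kid, founder)
      } else {
        walk(gain_node, founder)
      }
    }
  })
  genomes <- lapply(genomes, function(g) if (is.null(g)) character(0) else g)
  meta <- if (length(meta)) do.call(rbind, meta)
    else data.frame(gene_id = character(0), genome = character(0),
                    family = character(0), copy = character(0))
  list(genomes = genomes, meta = meta)
}
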