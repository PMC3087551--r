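#' Default simulation settings
#'
#' The generator emulates the study design of the real analysis: a species
#' tree over a couple dozen bacteria, the nine Kdo2-lipid A pathway families
#' (plus fabZ, which travels with the lpxD-lpxC-fabZ-lpxA-lpxB cluster),
#' duplication/loss along branches, a planted metallophosphoesterase motif
#' in lpxH, conserved gene clusters, and occasional lpxC/fabZ fusions.
#'
#' @param n_taxa number of genomes.
#' @param seed master seed; stage seeds are derived from it.
#' @return a config list accepted by [simulate_dataset()].
#' @export
default_sim_config <- function(n_taxa = 20, seed = 1) {
  list(
    n_taxa = n_taxa,
    seed = seed,
    tree_height = 0.75,
    families = c("lpxA", "lpxC", "lpxD", "lpxH", "lpxB",
                 "lpxK", "waaA", "lpxL", "lpxM", "fabZ"),
    dup_rate = 0.05,
    loss_rate = 0.05,
    subs_model = "wag",
    root_len = 300,
    motif_family = "lpxH",
    clusters = list(
      list(families = c("lpxD", "lpxC", "fabZ", "lpxA", "lpxB"), gap = 1),
      list(families = c("waaA", "lpxK"), gap = 0)),
    fusion_pair = c("lpxC", "fabZ"),
    fusion_prob = 0.2,
    n_decoys = 15)
}

#' Simulate a full synthetic dataset with truth log
#'
#' Runs tree simulation, family histories, sequence evolution and genome
#' assembly under one config and consolidates every planted event into a
#' single truth log for parameter-recovery tests.
#'
#' @param config list as returned by [default_sim_config()].
#' @return list: `tree`, `histories`, `sequences`, `assembly`, `truth`,
#'   `config`. `truth` carries gains/losses/duplications per family, leaf
#'   copy counts, motif columns, planted clusters and fusions.
#' @export
simulate_dataset <- function(config = default_sim_config()) {
  cfg <- config
  tree <- simulate_species_tree(cfg$n_taxa, seed = cfg$seed,
                                height = cfg$tree_height)
  gains <- setNames(rep(node_labels(tree)[root_node(tree)],
                        length(cfg$families)), cfg$families)
  fh <- simulate_family_histories(tree, dup_rate = cfg$dup_rate,
                                  loss_rate = cfg$loss_rate,
                                  gain_branches = gains,
                                  seed = cfg$seed + 1L)
  model <- subs_model(if (is.null(cfg$subs_model)) "wag" else cfg$subs_model)
  root_seqs <- character(0)
  invariant <- list()
  motif_info <- NULL
  for (i in seq_along(cfg$families)) {
    fam <- cfg$families[i]
    if (identical(fam, cfg$motif_family)) {
      pm <- plant_motif_root(cfg$root_len, motif_pattern(),
                             seed = cfg$seed + 100L + i,
                             freqs = model$freqs)
      root_seqs[fam] <- pm$seq
      invariant[[fam]] <- pm$invariant
      motif_info <- list(family = fam, columns = pm$invariant,
                         block_starts = pm$block_starts)
    } else {
      root_seqs[fam] <- with_seed(cfg$seed + 100L + i,
                                  random_protein(cfg$root_len, model$freqs))
    }
  }
  seqs <- evolve_sequences(tree, fh$histories, root_seqs, model,
                           invariant_cols = invariant,
                           seed = cfg$seed + 2L)
  asm <- assemble_genomes(seqs, cluster_specs = cfg$clusters,
                          fusion_pair = cfg$fusion_pair,
                          fusion_prob = cfg$fusion_prob,
                          n_decoys = cfg$n_decoys,
                          seed = cfg$seed + 3L)
  truth <- c(fh$truth,
             list(motif = motif_info,
                  clusters = asm$truth$clusters,
                  fusions = asm$truth$fusions,
                  root_seqs = as.list(root_seqs)))
  list(tree = tree, histories = fh$histories, sequences = seqs,
       assembly = asm, truth = truth, config = cfg)
}
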