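# species trees, family histories, sequence evolution, genome assembly

test_that("species tree simulation gives rooted binary labelled trees", {
  tr3 <- simulate_species_tree(3, seed = 1)
  expect_s3_class(tr3, "phylo")
  expect_true(ape::is.rooted(tr3))
  expect_equal(ape::Ntip(tr3), 3)
  expect_equal(nrow(tr3$edge), 4) # smallest rooted binary case
  tr61 <- simulate_species_tree(61, seed = 7)
  expect_equal(ape::Ntip(tr61), 61)
  expect_equal(tr61$Nnode, 60) # 2n - 1 nodes total
  expect_true(all(tr61$edge.length >= 0))
  expect_false(anyDuplicated(tr61$tip.label) > 0)
  expect_error(simulate_species_tree(2, seed = 1), "n_taxa")
})

test_that("species tree simulation is deterministic given the seed", {
  a <- ape::write.tree(simulate_species_tree(15, seed = 9))
  b <- ape::write.tree(simulate_species_tree(15, seed = 9))
  c <- ape::write.tree(simulate_species_tree(15, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("family histories honor the no-event and forced-event limits", {
  tr <- simulate_species_tree(10, seed = 3)
  fh <- simulate_family_histories(tr, n_families = 4, dup_rate = 0,
                                  loss_rate = 0, seed = 5)
  expect_true(all(fh$truth$leaf_counts == 1))
  # forced duplication on an internal branch doubles all leaves below it
  labs <- lpxevo:::node_labels(tr)
  internal <- labs[(ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode)]
  b <- internal[1]
  fh2 <- simulate_family_histories(
    tr, dup_rate = 0, loss_rate = 0,
    gain_branches = c(famA = labs[lpxevo:::root_node(tr)]),
    forced_duplications = list(famA = b), seed = 5)
  below <- tr$tip.label[lpxevo:::descendant_tips(tr, lpxevo:::node_number(tr, b))]
  counts <- fh2$truth$leaf_counts["famA", ]
  expect_true(all(counts[below] == 2))
  expect_true(all(counts[setdiff(tr$tip.label, below)] == 1))
  expect_error(simulate_family_histories(tr, gain_branches = c(f = "nope"),
                                         seed = 1),
               "unknown branch")
})

test_that("mean leaf copy number matches an independent Monte-Carlo oracle", {
  tr <- simulate_species_tree(20, seed = 3)
  dup <- 0.05; loss <- 0.05
  n_fam <- 60 # many iid families to estimate the generator mean
  fh <- simulate_family_histories(tr, n_families = n_fam, dup_rate = dup,
                                  loss_rate = loss, seed = 3)
  gen_mean <- mean(fh$truth$leaf_counts)
  # oracle: per-leaf branching process along the root-to-leaf path,
  # 10,000 Monte-Carlo replicates, written independently of the generator
  p_loss <- 1 - exp(-loss); p_dup <- 1 - exp(-dup)
  pm <- lpxevo:::parent_map(tr)
  reps <- 10000
  leaf_means <- vapply(seq_len(ape::Ntip(tr)), function(tip) {
    path <- integer(0); v <- tip
    while (!is.na(pm[v])) { path <- c(path, v); v <- pm[v] }
    n <- rep(1L, reps)
    for (br in rev(path)) {
      n <- rbinom(reps, n, 1 - p_loss)
      n <- n + rbinom(reps, n, p_dup)
    }
    mean(n)
  }, numeric(1))
  oracle_mean <- mean(leaf_means)
  # sampling error of the generator mean (n_fam families x 20 leaves,
  # leaves within a family are correlated -> use per-family variance)
  fam_means <- rowMeans(fh$truth$leaf_counts)
  se <- sd(fam_means) / sqrt(n_fam)
  expect_lt(abs(gen_mean - oracle_mean), 4 * se + 0.02)
})

test_that("sequence evolution respects limits, invariants and rates", {
  tr <- simulate_species_tree(6, seed = 2)
  m <- subs_model("poisson")
  # zero-length branches: all leaf sequences identical to the root
  tr0 <- tr; tr0$edge.length[] <- 0
  fh <- simulate_family_histories(tr0, n_families = 1, dup_rate = 0,
                                  loss_rate = 0, seed = 4)
  root <- with_seed(8, random_protein(120))
  ev <- evolve_sequences(tr0, fh$histories, c(fam01 = root), m, seed = 9)
  expect_true(all(unlist(ev$genomes) == root))
  expect_error(evolve_sequences(tr0, fh$histories, c(fam01 = ""), m),
               "empty root")
  # motif-flagged columns are never substituted
  pat <- motif_pattern()
  pm <- plant_motif_root(200, pat, seed = 11)
  fh2 <- simulate_family_histories(tr, n_families = 1, dup_rate = 0.1,
                                   loss_rate = 0, seed = 5)
  ev2 <- evolve_sequences(tr, fh2$histories, c(fam01 = pm$seq), m,
                          invariant_cols = list(fam01 = pm$invariant),
                          seed = 10)
  rootc <- strsplit(pm$seq, "")[[1]]
  for (s in unlist(ev2$genomes)) {
    expect_equal(strsplit(s, "")[[1]][pm$invariant], rootc[pm$invariant])
    expect_length(scan_motif(s, pat), 1)
  }
})

test_that("per-site substitution fraction follows the closed form", {
  # two-taxon tree with branch length 1.0 to one tip
  tr <- ape::read.tree(text = "(G01:1.0,G02:0.0)N3;")
  tr$node.label <- "N3"
  m <- subs_model("poisson")
  L <- 4000
  root <- with_seed(21, random_protein(L))
  fh <- simulate_family_histories(tr, n_families = 1, dup_rate = 0,
                                  loss_rate = 0, seed = 2)
  ev <- evolve_sequences(tr, fh$histories, c(fam01 = root), m, seed = 22)
  evolved <- ev$genomes[["G01"]][[1]]
  p_obs <- mean(strsplit(evolved, "")[[1]] != strsplit(root, "")[[1]])
  # closed form: P(change | t) = (19/20) (1 - exp(-20 t / 19))
  p_exp <- (19 / 20) * (1 - exp(-20 * 1.0 / 19))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("copy-count conservation: every surviving copy is emitted once", {
  tr <- simulate_species_tree(12, seed = 6)
  fh <- simulate_family_histories(tr, n_families = 5, dup_rate = 0.15,
                                  loss_rate = 0.1, seed = 7)
  m <- subs_model("poisson")
  roots <- setNames(vapply(1:5, function(i)
    with_seed(30 + i, random_protein(80)), character(1)),
    names(fh$histories))
  ev <- evolve_sequences(tr, fh$histories, roots, m, seed = 8)
  emitted <- table(factor(ev$meta$family, rownames(fh$truth$leaf_counts)),
                   factor(ev$meta$genome, colnames(fh$truth$leaf_counts)))
  expect_true(all(emitted == fh$truth$leaf_counts))
})

test_that("genome assembly plants clusters, fusions and valid coordinates", {
  tr <- simulate_species_tree(8, seed = 2)
  fams <- c("lpxD", "lpxC", "fabZ", "lpxA", "lpxB")
  gains <- setNames(rep(lpxevo:::node_labels(tr)[lpxevo:::root_node(tr)], 5),
                    fams)
  fh <- simulate_family_histories(tr, dup_rate = 0, loss_rate = 0,
                                  gain_branches = gains, seed = 3)
  m <- subs_model("poisson")
  roots <- setNames(vapply(seq_along(fams), function(i)
    with_seed(40 + i, random_protein(100)), character(1)), fams)
  ev <- evolve_sequences(tr, fh$histories, roots, m, seed = 4)
  # no fusion: every input sequence appears as its own gene
  asm0 <- assemble_genomes(ev, cluster_specs = list(), fusion_prob = 0,
                           n_decoys = 3, seed = 5)
  fam_rows <- asm0$gene_table[asm0$gene_table$family_truth != "decoy", ]
  expect_equal(nrow(fam_rows), nrow(ev$meta))
  # gap-0 cluster: the five families are adjacent, in order
  asm1 <- assemble_genomes(ev, cluster_specs = list(
    list(families = fams, gap = 0)), fusion_prob = 0, n_decoys = 5, seed = 6)
  for (gm in tr$tip.label) {
    tab <- asm1$gene_table[asm1$gene_table$genome == gm, ]
    tab <- tab[order(tab$start), ]
    idx <- which(tab$family_truth %in% fams)
    expect_equal(diff(idx), rep(1L, 4))
    expect_equal(tab$family_truth[idx], fams)
  }
  # forced fusion in every genome
  asm2 <- assemble_genomes(ev, cluster_specs = list(),
                           fusion_pair = c("lpxC", "fabZ"), fusion_prob = 1,
                           n_decoys = 2, seed = 7)
  expect_equal(nrow(asm2$truth$fusions), ape::Ntip(tr))
  # coordinates: 0-based half-open, non-overlapping, ordered per contig
  for (gm in tr$tip.label) {
    tab <- asm2$gene_table[asm2$gene_table$genome == gm, ]
    tab <- tab[order(tab$start), ]
    expect_true(all(tab$end > tab$start))
    expect_true(all(diff(tab$start) > 0))
    expect_true(all(tab$start[-1] >= tab$end[-nrow(tab)]))
  }
})

test_that("identical seeds reproduce identical datasets", {
  cfg <- default_sim_config(n_taxa = 8, seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$assembly$gene_table, b$assembly$gene_table)
  expect_identical(a$assembly$proteomes, b$assembly$proteomes)
  expect_identical(a$truth$leaf_counts, b$truth$leaf_counts)
})
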