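# progressive alignment, distances, NJ, bootstrap, likelihood, concatenation

nw_oracle <- function(a, b, smat, open, ext) {
  # plain-R global affine alignment returning the aligned strings
  av <- lpxevo:::aa_encode(a) + 1L
  bv <- lpxevo:::aa_encode(b) + 1L
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  H <- matrix(NEG, n + 1, m + 1); E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (j in 2:(m + 1)) { E[1, j] <- -(open + (j - 1) * ext); H[1, j] <- E[1, j] }
  for (i in 2:(n + 1)) { F[i, 1] <- -(open + (i - 1) * ext); H[i, 1] <- F[i, 1] }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(H[i - 1, j - 1] + smat[av[i - 1], bv[j - 1]], E[i, j], F[i, j])
  }
  H[n + 1, m + 1]
}

test_that("aligning identical sequences is gap-free", {
  a <- progressive_align(c(x = "MKVLITGA", y = "MKVLITGA", z = "MKVLITGA"))
  expect_true(all(!grepl("-", a$seqs)))
  expect_equal(a$seqs[1], "MKVLITGA")
})

test_that("two-sequence alignment attains the global DP optimum", {
  sch <- scoring_scheme()
  sm <- sch$matrix[1:20, 1:20]
  set.seed(301)
  for (rep in 1:25) {
    a <- random_aa_string(sample(5:30, 1))
    b <- random_aa_string(sample(5:30, 1))
    aln <- progressive_align(c(x = a, y = b), sch)
    # score the returned alignment and compare with the NW oracle value
    ca <- strsplit(aln$seqs[1], "")[[1]]
    cb <- strsplit(aln$seqs[2], "")[[1]]
    sc <- 0; gap <- 0
    in_gap_a <- FALSE; in_gap_b <- FALSE
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        sc <- sc - (if (in_gap_a) 0 else sch$gap_open) - sch$gap_ext
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (cb[k] == "-") {
        sc <- sc - (if (in_gap_b) 0 else sch$gap_open) - sch$gap_ext
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        sc <- sc + sm[match(ca[k], lpxevo:::AA), match(cb[k], lpxevo:::AA)]
        in_gap_a <- in_gap_b <- FALSE
      }
    }
    expect_equal(sc, nw_oracle(a, b, sm, sch$gap_open, sch$gap_ext))
  }
  expect_error(progressive_align(c(x = "ACD")), ">= 2")
})

test_that("planted-motif columns end up aligned in shared columns", {
  sch <- scoring_scheme()
  pat <- motif_pattern()
  tr <- simulate_species_tree(10, seed = 31)
  pm <- plant_motif_root(220, pat, seed = 32)
  fh <- simulate_family_histories(tr, n_families = 1, dup_rate = 0,
                                  loss_rate = 0, seed = 33)
  ev <- evolve_sequences(tr, fh$histories, c(fam01 = pm$seq),
                         subs_model("poisson"),
                         invariant_cols = list(fam01 = pm$invariant),
                         seed = 34)
  seqs <- unlist(ev$genomes)
  aln <- progressive_align(seqs, sch)
  M <- lpxevo:::aln_matrix(aln)
  # residue-level: map each row's ungapped positions to columns; motif
  # residues should occupy a common column across >= 90% of rows
  colmap <- lapply(seq_len(nrow(M)), function(i) which(M[i, ] != "-"))
  shared <- 0; total <- 0
  for (p in pm$invariant) {
    cols <- vapply(seq_len(nrow(M)), function(i) colmap[[i]][p], numeric(1))
    total <- total + length(cols)
    shared <- shared + max(table(cols))
  }
  expect_gte(shared / total, 0.9)
})

test_that("p-distances and Poisson correction follow their definitions", {
  a100 <- strrep("A", 100)
  b <- paste0(strrep("A", 95), strrep("C", 5))
  aln <- protein_alignment(c("a", "b"), c(a100, b))
  D <- distances(aln, "none")
  expect_equal(D["a", "b"], 0.05)
  expect_equal(D["a", "a"], 0)
  Dp <- distances(aln, "poisson")
  expect_equal(Dp["a", "b"], -log(0.95))
  expect_identical(distances(protein_alignment(c("a", "b"),
                                               c(a100, a100)))["a", "b"], 0)
  expect_error(distances(protein_alignment(c("a", "b"), c("A-", "-A"))),
               "shares")
})

test_that("NJ solves the 3-taxon closed form and rejects asymmetry", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # three-point formulas: la = (dab + dac - dbc)/2 etc.
  cp <- cophenetic(tr)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(cp), unname(D), tolerance = 1e-9)
  Dbad <- D; Dbad[1, 2] <- 6
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("NJ exactly recovers 100 random additive 6-8 taxon trees", {
  set.seed(302)
  for (rep in 1:100) {
    n <- sample(6:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- cophenetic(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(cophenetic(nj)[rownames(D), colnames(D)] - D)), 1e-6)
  }
})

test_that("NJ on an ultrametric matrix matches single-linkage grouping", {
  set.seed(303)
  for (rep in 1:10) {
    tr <- ape::rcoal(6)
    D <- cophenetic(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
    # single-linkage oracle: hclust single on the same matrix
    hc <- stats::hclust(stats::as.dist(D), "single")
    hctr <- ape::as.phylo(hc)
    expect_equal(ape::dist.topo(ape::unroot(hctr), nj), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports behave at the limits and under seeds", {
  # every column supports the same split -> 100%
  seqs <- c(a = strrep("A", 30), b = strrep("A", 30),
            c = strrep("C", 30), d = strrep("C", 30))
  aln <- protein_alignment(names(seqs), seqs)
  tr <- nj_bootstrap(aln, n_reps = 50, seed = 4, correction = "none")
  supp <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(supp[!is.na(supp)] == 100))
  # n_reps = 0: point tree with supports flagged undefined
  tr0 <- nj_bootstrap(aln, n_reps = 0, seed = 4, correction = "none")
  expect_true(any(tr0$node.label == "NA"))
  # determinism
  set.seed(305)
  seqs2 <- setNames(replicate(5, random_aa_string(40)), letters[1:5])
  t1 <- nj_bootstrap(protein_alignment(names(seqs2), seqs2), 100, seed = 9,
                     correction = "none")
  t2 <- nj_bootstrap(protein_alignment(names(seqs2), seqs2), 100, seed = 9,
                     correction = "none")
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("clean long-branch simulations give full support for true splits", {
  ok <- 0
  for (rep in 1:10) {
    tr <- simulate_species_tree(6, seed = 400 + rep, height = 0.6)
    # stretch internal branches so splits are unambiguous
    internal <- tr$edge[, 2] > ape::Ntip(tr)
    tr$edge.length[internal] <- tr$edge.length[internal] + 0.4
    fh <- simulate_family_histories(tr, n_families = 1, dup_rate = 0,
                                    loss_rate = 0, seed = rep)
    root <- with_seed(500 + rep, random_protein(400))
    ev <- evolve_sequences(tr, fh$histories, c(fam01 = root),
                           subs_model("poisson"), seed = 600 + rep)
    seqs <- setNames(unlist(ev$genomes),
                     sub("\\|.*", "", names(unlist(ev$genomes))))
    names(seqs) <- sub("\\|.*", "", unlist(lapply(ev$genomes, names)))
    aln <- progressive_align(seqs)
    bt <- nj_bootstrap(aln, n_reps = 100, seed = 700 + rep)
    true_bips <- lpxevo:::tree_bipartitions(ape::unroot(tr))
    est_bips <- lpxevo:::tree_bipartitions(bt)
    supp <- suppressWarnings(as.numeric(bt$node.label))
    if (setequal(true_bips, est_bips) &&
        all(supp[!is.na(supp)] >= 95)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("pruning likelihood matches closed forms and enumeration", {
  m <- subs_model("poisson")
  # 2-leaf single column closed form
  tl <- ape::read.tree(text = "(a:0.4,b:0.6);")
  al <- protein_alignment(c("a", "b"), c("A", "C"))
  P <- subs_prob(m, 1.0)
  expect_equal(loglik(tl, al, m), log(0.05 * P[1, 5]), tolerance = 1e-9)
  al2 <- protein_alignment(c("a", "b"), c("A", "A"))
  expect_equal(loglik(tl, al2, m), log(0.05 * P[1, 1]), tolerance = 1e-9)
  # 4-leaf brute force over internal state assignments
  t4 <- ape::read.tree(text = "((a:0.2,b:0.3):0.15,(c:0.25,d:0.1):0.05);")
  set.seed(310)
  seqs <- setNames(replicate(4, random_aa_string(5)), letters[1:4])
  al4 <- protein_alignment(names(seqs), seqs)
  codes <- lapply(seqs, function(s) lpxevo:::aa_encode(s) + 1L)
  brute <- function() {
    Pab <- list(a = subs_prob(m, 0.2), b = subs_prob(m, 0.3),
                c = subs_prob(m, 0.25), d = subs_prob(m, 0.1))
    Pu <- subs_prob(m, 0.15); Pv <- subs_prob(m, 0.05)
    total <- 0
    for (site in 1:5) {
      s <- 0
      for (root in 1:20) for (u in 1:20) for (v in 1:20) {
        s <- s + 0.05 * Pu[root, u] * Pv[root, v] *
          Pab$a[u, codes$a[site]] * Pab$b[u, codes$b[site]] *
          Pab$c[v, codes$c[site]] * Pab$d[v, codes$d[site]]
      }
      total <- total + log(s)
    }
    total
  }
  expect_equal(loglik(t4, al4, m), brute(), tolerance = 1e-9)
})

test_that("likelihood is invariant under re-rooting and in the Gamma limit", {
  set.seed(311)
  tr <- ape::rtree(5)
  tr$tip.label <- letters[1:5]
  seqs <- setNames(replicate(5, random_aa_string(30)), letters[1:5])
  aln <- protein_alignment(names(seqs), seqs)
  m <- subs_model("wag")
  l1 <- loglik(tr, aln, m)
  rerooted <- ape::root(ape::unroot(tr), outgroup = "d", resolve.root = TRUE)
  expect_equal(loglik(rerooted, aln, m), l1, tolerance = 1e-8)
  # alpha -> large converges to the rate-homogeneous value
  mg <- subs_model("wag", alpha = 1e6, k = 4)
  expect_equal(loglik(tr, aln, mg), l1, tolerance = 1e-3)
  expect_error(loglik(tr, protein_alignment("a", "ACD"), m), "differ")
})

test_that("pruning agrees with an independent phylogenetics package", {
  skip_if_not_installed("phangorn")
  set.seed(312)
  tr <- ape::rtree(6)
  seqs <- setNames(replicate(6, random_aa_string(40)), tr$tip.label)
  aln <- protein_alignment(names(seqs), seqs)
  m <- subs_model("wag")
  M <- do.call(rbind, strsplit(seqs, ""))
  rownames(M) <- names(seqs)
  pd <- phangorn::phyDat(M, type = "AA")
  fit <- phangorn::pml(tr, pd, model = "WAG")
  expect_equal(loglik(tr, aln, m), fit$logLik, tolerance = 1e-6)
})

test_that("concatenation pads missing genes and picks the best-scoring copy", {
  g1 <- protein_alignment(c("G01|a#1", "G02|a#1"), c("AAAA", "AACA"))
  g2 <- protein_alignment(c("G01|b#1"), c("CCCCCC"))
  cat12 <- concatenate_alignments(list(geneA = g1, geneB = g2))
  expect_equal(nchar(cat12$seqs[1]), 10)
  expect_equal(cat12$seqs[cat12$ids == "G02"], "AACA------")
  expect_equal(cat12$col_source, c(rep("geneA", 4), rep("geneB", 6)))
  # duplicate copies: highest score wins
  g3 <- protein_alignment(c("G01|c#1", "G01|c#2", "G02|c#1"),
                          c("GGGG", "GGGC", "GGGA"))
  sc <- c("G01|c#1" = 10, "G01|c#2" = 50)
  cat3 <- concatenate_alignments(list(geneC = g3), scores = sc)
  expect_equal(cat3$seqs[cat3$ids == "G01"], "GGGC")
  # without scores the lexicographically first id is kept
  cat4 <- concatenate_alignments(list(geneC = g3))
  expect_equal(cat4$seqs[cat4$ids == "G01"], "GGGG")
})
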