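# profile HMM construction, forward/Viterbi scoring, calibration, search

test_that("match columns and emissions follow the seed alignment", {
  # two identical ungapped rows: model length = sequence length, each
  # match emission maximized at the observed residue
  aln <- c(a = "ACDEFG", b = "ACDEFG")
  h <- build_hmm(aln)
  expect_equal(h$m, 6)
  expect_equal(lpxevo:::AA[apply(h$match_emit, 1, which.max)],
               strsplit("ACDEFG", "")[[1]])
  # an all-gap column is not a match state
  aln2 <- c(a = "AC-EF", b = "AC-EF", c = "AC-EF")
  expect_equal(build_hmm(aln2)$m, 4)
  expect_error(build_hmm(c(a = "---", b = "---")), "match columns")
})

test_that("per-column modes equal an independent counting oracle", {
  set.seed(201)
  n <- 10; L <- 30
  rows <- replicate(n, random_aa_string(L))
  names(rows) <- sprintf("r%02d", 1:n)
  h <- build_hmm(rows, pseudocount_weight = 0.1)
  M <- do.call(rbind, strsplit(rows, ""))
  for (k in seq_len(L)) {
    tab <- table(factor(M[, k], levels = lpxevo:::AA))
    consensus <- names(tab)[which.max(tab)]
    expect_equal(lpxevo:::AA[which.max(h$match_emit[k, ])], consensus)
  }
})

test_that("all outgoing distributions are normalized", {
  set.seed(202)
  rows <- replicate(6, random_aa_string(25))
  rows[3] <- paste0(substr(rows[3], 1, 10), "----",
                    substr(rows[3], 15, 25))
  names(rows) <- sprintf("r%d", 1:6)
  h <- build_hmm(rows)
  expect_true(all(abs(rowSums(h$match_emit) - 1) < 1e-9))
  m <- h$m
  out_m <- h$exit + c(h$t_mm[-m], 0) + c(h$t_mi[-m], 0) + c(h$t_md[-m], 0)
  expect_true(all(abs(out_m - 1) < 1e-9))
  expect_true(all(abs(h$t_im[-m] + h$t_ii[-m] - 1) < 1e-9))
  expect_true(all(abs(h$t_dm[-m] + h$t_dd[-m] - 1) < 1e-9))
  expect_equal(sum(h$entry), 1)
})

test_that("a 1-state model scores a residue by its log-odds closed form", {
  h <- build_hmm(c(a = "A", b = "A"), pseudocount_weight = 0)
  expect_equal(forward_score(h, "A"), log2(1 / 0.05))
  h2 <- build_hmm(c(a = "A", b = "C"), pseudocount_weight = 0)
  expect_equal(forward_score(h2, "A"), log2(0.5 / 0.05))
})

test_that("forward probability equals exhaustive path enumeration on toys", {
  # oracle: hmm_enum_odds (helper) sums over all (start, state path, end)
  # combinations explicitly; <= 3 match states, <= 4 residues
  enum_odds <- hmm_enum_odds
  set.seed(203)
  for (rep in 1:6) {
    rows <- replicate(4, random_aa_string(3))
    rows[2] <- paste0(substr(rows[2], 1, 1), "-",
                      substr(rows[2], 3, 3)) # inject a deletion
    names(rows) <- sprintf("r%d", 1:4)
    h <- build_hmm(rows)
    for (L in 1:4) {
      s <- random_aa_string(L)
      codes <- lpxevo:::aa_encode(s)
      expect_equal(forward_score(h, s), log2(enum_odds(h, codes)),
                   tolerance = 1e-9)
    }
  }
})

test_that("forward never falls below Viterbi", {
  set.seed(204)
  rows <- replicate(5, random_aa_string(15))
  names(rows) <- sprintf("r%d", 1:5)
  h <- build_hmm(rows)
  for (rep in 1:20) {
    s <- random_aa_string(sample(5:40, 1))
    expect_gte(forward_score(h, s), viterbi_score(h, s) - 1e-9)
  }
})

test_that("growing the seed with an identical row never hurts its own score", {
  set.seed(205)
  base <- random_aa_string(20)
  rows <- c(x = base, y = base)
  h2 <- build_hmm(rows)
  h3 <- build_hmm(c(rows, z = base))
  expect_gte(forward_score(h3, base), forward_score(h2, base) - 1e-9)
})

test_that("calibration is deterministic, rejects degenerate scores, and
           anchors the tail", {
  set.seed(206)
  rows <- replicate(8, random_aa_string(25))
  names(rows) <- sprintf("r%d", 1:8)
  h <- build_hmm(rows)
  c1 <- calibrate_hmm(h, n_random = 600, len = 60, seed = 3)
  c2 <- calibrate_hmm(h, n_random = 600, len = 60, seed = 3)
  expect_identical(c1$calibration, c2$calibration)
  expect_error(calibrate_hmm(h, n_random = 100, len = 60, seed = 3), "500")
  # degenerate: a model whose scores cannot vary -> constant scores
  h1 <- build_hmm(c(a = "A", b = "A"), pseudocount_weight = 0)
  expect_error(suppressWarnings(calibrate_hmm(h1, n_random = 500, len = 1,
                                              seed = 1)),
               "degenerate")
  # E-value at the anchor quantile reproduces the tail fraction x trials
  held <- with_seed(99, {
    seqs <- lapply(1:2000, function(i) sample.int(20, 60, TRUE) - 1L)
    lpxevo:::.hmm_forward_many_cpp(c1, seqs)
  })
  e_at_q95 <- hmm_evalue(c1, unname(quantile(held, 0.95)))
  expect_gt(e_at_q95, 0.05 * 20000 / 3)
  expect_lt(e_at_q95, 0.05 * 20000 * 3)
})

test_that("hmm_search finds seed members and requires calibration", {
  set.seed(207)
  ancestor <- random_aa_string(60)
  m <- subs_model("poisson")
  P <- subs_prob(m, 0.3)
  cum <- t(apply(P, 1, cumsum))
  mutate <- function(s, cum) {
    codes <- lpxevo:::aa_encode(s) + 1L
    nc <- vapply(codes, function(x)
      findInterval(runif(1), cum[x, ], left.open = TRUE), integer(1))
    paste(lpxevo:::AA[nc + 1L], collapse = "")
  }
  rows <- vapply(1:8, function(i) mutate(ancestor, cum), character(1))
  names(rows) <- sprintf("r%d", 1:8)
  h <- build_hmm(progressive_align(rows))
  expect_error(hmm_search(h, rows), "not calibrated")
  h <- calibrate_hmm(h, n_random = 600, len = 60, seed = 5)
  prot <- c(rows[1], setNames(replicate(30, random_aa_string(60)),
                              sprintf("d%02d", 1:30)))
  hits <- hmm_search(h, prot)
  expect_true("r1" %in% hits$target)
  expect_lt(hits$evalue[hits$target == "r1"], 1e-4)
})

test_that("null searches stay within the calibrated false-hit budget", {
  set.seed(208)
  rows <- replicate(8, random_aa_string(20))
  names(rows) <- sprintf("r%d", 1:8)
  h <- calibrate_hmm(build_hmm(rows), n_random = 1000, len = 50, seed = 6)
  counts <- hmm_null_false_hits(h, n_searches = 40, seqs_per_search = 5000,
                                len = 50, cutoff = 0.01, seed = 7)
  # expected <= 0.01 * 5000/20000 = 0.0025 per search; 40 searches -> 0.1;
  # allow the 3-sigma-style slack of a unit count
  expect_lte(sum(counts), 2)
})

test_that("a remote homolog missed by pairwise search is found by the HMM", {
  # The pairwise stage uses one fixed reference; the profile pools the
  # family, including a few members along the remote lineage (the study
  # enriched its profiles with additional family sequences the same way).
  # The remote homolog sits at branch length 1.5 from the family ancestor
  # while the reference lies deep in another clade, so the single-query
  # search fails where the profile succeeds.
  sch <- cached_scheme()
  cfg <- search_config()
  m <- subs_model("poisson")
  mutate <- function(codes, cum) vapply(codes + 1L, function(x)
    findInterval(runif(1), cum[x, ], left.open = TRUE), integer(1))
  cumt <- function(t) t(apply(subs_prob(m, t), 1, cumsum))
  to_str <- function(x) paste(lpxevo:::AA[x + 1L], collapse = "")
  pat <- motif_pattern()
  res <- with_seed(209, {
    pm <- plant_motif_root(260, pat, seed = 303)
    anc <- lpxevo:::aa_encode(pm$seq)
    inv <- pm$invariant
    evolve <- function(codes, t) {
      out <- mutate(codes, cumt(t))
      out[inv] <- codes[inv]
      out
    }
    ref <- evolve(anc, 1.5)                       # reference, clade A
    seedA <- lapply(1:8, function(i) evolve(anc, 0.5))
    interm <- evolve(anc, 1.0)                    # remote lineage stem
    seedB <- lapply(1:3, function(i) evolve(interm, 0.15))
    seed_seqs <- vapply(c(seedA, seedB), to_str, character(1))
    names(seed_seqs) <- sprintf("m%02d", seq_along(seed_seqs))
    hmm <- calibrate_hmm(build_hmm(progressive_align(seed_seqs, sch)),
                         n_random = 800, len = 260, seed = 304)
    hits_sw <- 0; hits_hmm <- 0; compound <- 0
    for (i in 1:100) {
      remote <- evolve(interm, 0.5) # 1.5 subs/site from the ancestor
      prot <- c(setNames(to_str(remote), "remote"),
                setNames(replicate(10, random_aa_string(260)),
                         sprintf("d%02d", 1:10)))
      sw_hit <- "remote" %in% search_genome(to_str(ref), prot, cfg,
                                            sch)$target
      hmm_hit <- "remote" %in% hmm_search(hmm, prot)$target
      hits_sw <- hits_sw + sw_hit
      hits_hmm <- hits_hmm + hmm_hit
      compound <- compound + (!sw_hit && hmm_hit)
    }
    c(sw = hits_sw, hmm = hits_hmm, compound = compound)
  })
  expect_gte(res[["compound"]], 60)
  expect_gt(res[["hmm"]], res[["sw"]])
})

test_that("JSON round-trip preserves the model and its scores", {
  set.seed(210)
  rows <- replicate(5, random_aa_string(18))
  names(rows) <- sprintf("r%d", 1:5)
  h <- calibrate_hmm(build_hmm(rows), n_random = 600, len = 40, seed = 8)
  f <- tempfile(fileext = ".json")
  hmm_to_json(h, f)
  h2 <- hmm_from_json(f)
  s <- random_aa_string(30)
  expect_equal(forward_score(h2, s), forward_score(h, s), tolerance = 1e-12)
  expect_equal(h2$calibration$mu, h$calibration$mu)
})
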