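# Shared fixtures, memoized for the whole test session. Heavy objects (the
# calibrated scoring scheme, the 20-genome pipeline run) are built once and
# reused across files.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

cached_scheme <- function() {
  fixture("scheme", function() calibrate_scheme(scoring_scheme(), seed = 42))
}

# identity-style matrix used by several spec examples: +1 match, -1 mismatch
identity_scheme <- function(gap_open = 10, gap_ext = 1) {
  m <- matrix(-1, 20, 20)
  diag(m) <- 1
  scoring_scheme(m, gap_open = gap_open, gap_ext = gap_ext)
}

random_aa_string <- function(n) paste(sample(lpxevo:::AA, n, TRUE), collapse = "")

# Study-condition pipeline run: 20 genomes, the 9 pathway families (+fabZ),
# dup and loss rates 0.05, fixed seed. Bootstrap replicates are scaled to
# 200 to keep the suite quick; everything else is at the package defaults.
cached_pipeline <- function() {
  fixture("pipeline", function() {
    cfg <- run_config(n_taxa = 20, seed = 1)
    cfg$bootstrap_reps <- 200
    out <- file.path(tempdir(), "lpxevo-test-run")
    run_pipeline(cfg, out_dir = out)
  })
}

# plain-R affine-gap local alignment (Gotoh) oracle, written independently
# of the C++ kernel
sw_score_oracle <- function(a, b, smat, open, ext) {
  av <- lpxevo:::aa_encode(a) + 1L
  bv <- lpxevo:::aa_encode(b) + 1L
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + smat[av[i - 1], bv[j - 1]],
                   E[i, j], F[i, j])
  }
  max(H)
}

# exponential-time oracle: enumerate every local alignment path explicitly
sw_enum_oracle <- function(a, b, smat, open, ext) {
  av <- lpxevo:::aa_encode(a) + 1L
  bv <- lpxevo:::aa_encode(b) + 1L
  n <- length(av); m <- length(bv)
  best <- 0
  # extend(i, j, score, state): best completion starting after cell (i,j)
  extend <- function(i, j, score) {
    best <<- max(best, score)
    if (i <= n && j <= m)
      extend(i + 1, j + 1, score + smat[av[i], bv[j]])
    # gaps: consume k of a or k of b, then must resume with a match
    if (i <= n) for (k in 1:(n - i + 1)) {
      if (i + k <= n && j <= m)
        extend(i + k + 1, j + 1,
               score - open - k * ext + smat[av[i + k], bv[j]])
    }
    if (j <= m) for (k in 1:(m - j + 1)) {
      if (j + k <= m && i <= n)
        extend(i + 1, j + k + 1,
               score - open - k * ext + smat[av[i], bv[j + k]])
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    extend(i + 1, j + 1, smat[av[i], bv[j]])
  best
}
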