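#' Build a profile HMM from a seed alignment
#'
#' Columns whose residue occupancy (fraction of non-gap rows) is at least
#' `occupancy_threshold` become match states. Emissions are estimated with
#' a fixed-weight background (Laplace-style) pseudocount mixture,
#' `(count + w * bg) / (n + w)`; transitions likewise with weight 1 on each
#' outgoing edge. The topology is local (Plan-7 style): uniform entry
#' `B -> M_k = 1/m`, exit `M_k -> E = 1/(m - k + 1)` with the remaining
#' mass shared by the core M->M/I/D transitions, so every outgoing
#' distribution sums to one.
#'
#' @param aln a `protein_alignment` (see [progressive_align()]) or a named
#'   character vector of equal-length gapped sequences.
#' @param occupancy_threshold match-state occupancy threshold.
#' @param pseudocount_weight weight of the background mixture.
#' @param bg background residue frequencies.
#' @return object of class `profile_hmm`.
#' @export
build_hmm <- function(aln, occupancy_threshold = 0.5, pseudocount_weight = 1,
                      bg = rep(1 / 20, 20)) {
  seqs <- if (inherits(aln, "protein_alignment")) aln$seqs else aln
  if (length(seqs) < 2) stop("seed alignment needs >= 2 rows")
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  if (length(unique(nchar(seqs))) != 1) stop("ragged alignment")
  is_res <- M != "-" & M != "."
  occ <- colMeans(is_res)
  match_cols <- which(occ >= occupancy_threshold)
  m <- length(match_cols)
  if (m < 1) stop("alignment has no match columns (all-gap?)")
  nbg <- bg / sum(bg)
  w <- pseudocount_weight
  # match emissions
  emit <- matrix(0, m, 20, dimnames = list(NULL, AA))
  for (k in seq_len(m)) {
    col <- M[, match_cols[k]]
    cnt <- table(factor(col[col %in% AA], levels = AA))
    emit[k, ] <- (as.numeric(cnt) + w * nbg) / (sum(cnt) + w)
  }
  # transition counts from observed row paths over match columns
  nmm <- nmi <- nmd <- rep(0, m); nim <- nii <- rep(0, m)
  ndm <- ndd <- rep(0, m)
  state_of <- function(row) {
    # per match column: "M" residue, "D" gap; inserts are residues in
    # non-match columns between match columns
    sapply(seq_len(m), function(k) if (is_res[row, match_cols[k]]) "M" else "D")
  }
  ins_between <- function(row, k) {
    if (k >= m) return(0L)
    lo <- match_cols[k] + 1L; hi <- match_cols[k + 1L] - 1L
    if (lo > hi) return(0L)
    sum(is_res[row, setdiff(lo:hi, match_cols)])
  }
  for (r in seq_len(nrow(M))) {
    st <- state_of(r)
    for (k in seq_len(m - 1)) {
      ni <- ins_between(r, k)
      from <- st[k]; to <- st[k + 1]
      if (from == "M") {
        if (ni > 0) { nmi[k] <- nmi[k] + 1; nii[k] <- nii[k] + ni - 1
                      nim[k] <- nim[k] + (to == "M")
                      # insert cannot precede D in this topology; count to M
        } else if (to == "M") nmm[k] <- nmm[k] + 1
        else nmd[k] <- nmd[k] + 1
      } else {
        if (to == "M") ndm[k] <- ndm[k] + 1 else ndd[k] <- ndd[k] + 1
      }
    }
  }
  exit <- 1 / (m - seq_len(m) + 1)
  t_mm <- t_mi <- t_md <- t_im <- t_ii <- t_dm <- t_dd <- rep(0, m)
  for (k in seq_len(m - 1)) {
    core <- c(nmm[k], nmi[k], nmd[k]) + w / 3
    core <- core / sum(core) * (1 - exit[k])
    t_mm[k] <- core[1]; t_mi[k] <- core[2]; t_md[k] <- core[3]
    ins <- c(nim[k], nii[k]) + w / 2
    ins <- ins / sum(ins)
    t_im[k] <- ins[1]; t_ii[k] <- ins[2]
    del <- c(ndm[k], ndd[k]) + w / 2
    del <- del / sum(del)
    t_dm[k] <- del[1]; t_dd[k] <- del[2]
  }
  structure(list(
    match_emit = emit,
    match_odds = sweep(emit, 2, nbg, "/"),
    entry = rep(1 / m, m), exit = exit,
    t_mm = t_mm, t_mi = t_mi, t_md = t_md,
    t_im = t_im, t_ii = t_ii, t_dm = t_dm, t_dd = t_dd,
    m = m, bg = nbg, match_cols = match_cols,
    consensus = AA[apply(emit, 1, which.max)],
    calibration = NULL), class = "profile_hmm")
}

#' Forward log-odds score of a sequence against a profile HMM
#'
#' `log2 [ P(seq | hmm, local alignment) / P(seq | background) ]`, summing
#' over all alignments (any model sub-path against any subsequence, free
#' background flanks).
#'
#' @param hmm a [build_hmm()] model.
#' @param seq protein string.
#' @return score in bits (finite).
#' @export
forward_score <- function(hmm, seq) {
  v <- aa_encode(seq, allow_x = FALSE)
  if (!length(v)) stop("empty sequence")
  .hmm_forward_cpp(hmm, v)
}

#' @rdname forward_score
#' @details `viterbi_score` scores only the single best alignment path and
#'   is therefore never larger than the forward score.
#' @export
viterbi_score <- function(hmm, seq) {
  v <- aa_encode(seq, allow_x = FALSE)
  .hmm_viterbi_cpp(hmm, v)
}

#' Calibrate a profile HMM against random background sequences
#'
#' Scores `n_random` background sequences with the forward algorithm and
#' fits a Gumbel law to them. Because a forward score is the log2 of a sum
#' of likelihood ratios whose null expectation is finite, the null
#' distribution's right tail decays as `2^-score`; the Gumbel scale is
#' therefore fixed at `1 / ln 2` on theoretical grounds and only the
#' location is estimated, anchored so that the fitted survival matches the
#' empirical upper tail (fraction `tail_p`) of the calibration sample.
#' E-values then use the constant trial count:
#' `E(S) = n_trials * P_gumbel(score >= S)` with `n_trials` 20,000.
#'
#' @param hmm a [build_hmm()] model.
#' @param n_random number of calibration sequences (>= 500).
#' @param len calibration sequence length (constant query-length convention,
#'   320, by default).
#' @param bg background frequencies.
#' @param seed integer seed.
#' @param n_trials trial-count constant for E-values.
#' @param tail_p empirical tail fraction used to anchor the location.
#' @return the hmm with `calibration` (mu, beta, n, len, seed, n_trials).
#' @export
calibrate_hmm <- function(hmm, n_random = 1000, len = 320,
                          bg = hmm$bg, seed = 7, n_trials = 20000,
                          tail_p = 0.05) {
  if (n_random < 500) stop("n_random must be >= 500")
  scores <- with_seed(seed, {
    seqs <- lapply(seq_len(n_random), function(i)
      sample.int(20, len, replace = TRUE, prob = bg) - 1L)
    .hmm_forward_many_cpp(hmm, seqs)
  })
  if (length(unique(scores)) < 3 || sd(scores) < 1e-9)
    stop("degenerate score distribution: cannot calibrate")
  beta <- 1 / log(2)
  tau <- unname(quantile(scores, 1 - tail_p))
  # exponential-tail Gumbel: P(S >= tau) = tail_p  =>  mu = tau + beta ln p
  mu <- tau + beta * log(tail_p)
  hmm$calibration <- list(mu = mu, beta = beta, n = n_random,
                          len = len, seed = seed, n_trials = n_trials,
                          tail_p = tail_p, tau = tau)
  hmm
}

#' E-value of a forward score under the model's calibration
#' @param hmm calibrated model.
#' @param score forward score(s) in bits.
#' @return E-value(s).
#' @export
hmm_evalue <- function(hmm, score) {
  cal <- hmm$calibration
  if (is.null(cal)) stop("profile HMM is not calibrated")
  z <- (score - cal$mu) / cal$beta
  p <- -expm1(-exp(-z)) # P(S >= s)
  cal$n_trials * p
}

# score at which the E-value equals `e`
hmm_score_at_evalue <- function(hmm, e) {
  cal <- hmm$calibration
  if (is.null(cal)) stop("profile HMM is not calibrated")
  p <- e / cal$n_trials
  cal$mu - cal$beta * log(-log1p(-p))
}

#' Search a proteome with a calibrated profile HMM
#'
#' @param hmm calibrated model.
#' @param proteome named character vector of proteins.
#' @param cutoff E-value cutoff (default 0.01).
#' @return data.frame: target, bits, evalue, ranked by ascending E-value.
#' @export
hmm_search <- function(hmm, proteome, cutoff = 0.01) {
  if (is.null(hmm$calibration)) stop("profile HMM is not calibrated")
  enc <- lapply(unname(proteome), aa_encode, allow_x = FALSE)
  bits <- .hmm_forward_many_cpp(hmm, enc)
  ev <- hmm_evalue(hmm, bits)
  keep <- which(ev <= cutoff)
  out <- data.frame(target = names(proteome)[keep], bits = bits[keep],
                    evalue = ev[keep], stringsAsFactors = FALSE)
  out <- out[order(out$evalue, -out$bits, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count false detections in searches of pure-background proteomes
#'
#' Calibration audit: runs `n_searches` independent searches, each against
#' `seqs_per_search` random background sequences, and counts forward scores
#' reaching the score threshold that corresponds to `cutoff`. Under an
#' accurate calibration the expected count per search is
#' `cutoff * seqs_per_search / n_trials`.
#'
#' @param hmm calibrated model.
#' @param n_searches number of null searches.
#' @param seqs_per_search proteome size per search.
#' @param len null sequence length.
#' @param cutoff E-value cutoff.
#' @param seed integer seed.
#' @return integer vector of per-search false-detection counts.
#' @export
hmm_null_false_hits <- function(hmm, n_searches = 200,
                                seqs_per_search = 20000, len = 320,
                                cutoff = 0.01, seed = 11) {
  thr <- hmm_score_at_evalue(hmm, cutoff)
  with_seed(seed,
    .hmm_null_counts_cpp(hmm, n_searches, seqs_per_search, len, hmm$bg, thr))
}

#' Serialize / load a profile HMM as JSON
#'
#' Schema: fields `match_emit` (m x 20, row-major), `entry`, `exit`,
#' `t_mm`..`t_dd`, `bg`, `match_cols`, `consensus`, `calibration`.
#'
#' @param hmm model.
#' @param path JSON path.
#' @export
hmm_to_json <- function(hmm, path) {
  x <- unclass(hmm)
  x$match_emit <- unclass(x$match_emit)
  x$match_odds <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname hmm_to_json
#' @export
hmm_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$match_emit <- matrix(as.numeric(x$match_emit), nrow = x$m,
                         dimnames = list(NULL, AA))
  x$match_odds <- sweep(x$match_emit, 2, x$bg, "/")
  if (!is.null(x$calibration) && !length(x$calibration)) x$calibration <- NULL
  structure(x, class = "profile_hmm")
}
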