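#' Pairwise scoring scheme with Karlin-Altschul statistics
#'
#' Bundles the substitution matrix and affine gap penalties with the
#' Karlin-Altschul parameters lambda and K once calibrated. The matrix is
#' extended with an `X` row/column scored as the worst substitution so
#' ambiguous residues can never create signal.
#'
#' @param matrix `"BLOSUM62"` or a 20x20 numeric matrix (rows/cols ordered
#'   ARNDCQEGHILKMFPSTWYV).
#' @param gap_open,gap_ext gap penalties; a gap of length k costs
#'   `gap_open + k * gap_ext`.
#' @return object of class `scoring_scheme` (uncalibrated: lambda/K NULL).
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    m <- get(matrix, envir = env)
    m <- m[AA, AA]
  } else {
    m <- matrix
    stopifnot(is.matrix(m), nrow(m) == 20, ncol(m) == 20)
    dimnames(m) <- list(AA, AA)
  }
  worst <- min(m)
  full <- rbind(cbind(m, X = worst), X = worst)
  # sanity: expected score under uniform background must be negative
  if (mean(m) >= 0)
    stop("substitution matrix has non-negative expected score")
  structure(list(matrix = full, gap_open = gap_open, gap_ext = gap_ext,
                 lambda = NULL, K = NULL, calibration = NULL),
            class = "scoring_scheme")
}

# Maximum-likelihood Gumbel fit; returns list(mu, beta).
gumbel_fit <- function(x) {
  if (length(unique(x)) < 3 || sd(x) < 1e-9)
    stop("degenerate score distribution: cannot fit a Gumbel")
  beta0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(p) {
    mu <- p[1]; beta <- exp(p[2])
    z <- (x - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  list(mu = fit$par[1], beta = exp(fit$par[2]))
}

#' Calibrate lambda and K for a scoring scheme
#'
#' Aligns `n_pairs` random background sequence pairs of length `len` with
#' the scheme's gapped Smith-Waterman and fits a Gumbel distribution to the
#' scores by maximum likelihood. Under Karlin-Altschul statistics the score
#' of a length-m x length-n search follows a Gumbel with
#' `mu = ln(K m n) / lambda` and scale `1 / lambda`, which inverts to
#' `lambda = 1 / beta` and `K = exp(mu / beta) / (m n)`.
#'
#' @param scheme a [scoring_scheme()].
#' @param n_pairs number of shuffled pairs (>= 2000 recommended).
#' @param len sequence length for calibration (the constant average
#'   query length, 320, by default).
#' @param bg background residue frequencies.
#' @param seed integer seed.
#' @return the scheme with `lambda`, `K` and calibration metadata filled in.
#' @export
calibrate_scheme <- function(scheme, n_pairs = 2000, len = 320,
                             bg = rep(1 / 20, 20), seed = 42) {
  scores <- with_seed(seed, {
    vapply(seq_len(n_pairs), function(i) {
      a <- sample.int(20, len, replace = TRUE, prob = bg) - 1L
      b <- sample.int(20, len, replace = TRUE, prob = bg) - 1L
      .sw_scores_cpp(a, list(b), scheme$matrix, scheme$gap_open,
                     scheme$gap_ext)
    }, numeric(1))
  })
  fit <- gumbel_fit(scores)
  scheme$lambda <- 1 / fit$beta
  scheme$K <- exp(fit$mu / fit$beta) / (len * len)
  scheme$calibration <- list(n_pairs = n_pairs, len = len, seed = seed,
                             mu = fit$mu, beta = fit$beta)
  scheme
}

#' Search configuration with the constant-database-size convention
#'
#' The effective database length is held constant at
#' `avg_query_len * genome_size` (default 320 x 20,000 = 6,400,000) so
#' E-values are comparable across genomes of different sizes.
#'
#' @param cutoff E-value at and below which a hit is reported.
#' @param avg_query_len average query length constant (amino acids).
#' @param genome_size genome size constant (genes).
#' @return list of class `search_config` with `eff_db_len` filled in.
#' @export
search_config <- function(cutoff = 0.01, avg_query_len = 320,
                          genome_size = 20000) {
  structure(list(cutoff = cutoff, avg_query_len = avg_query_len,
                 genome_size = genome_size,
                 eff_db_len = avg_query_len * genome_size),
            class = "search_config")
}

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' `E = K * m * n_eff * exp(-lambda * S)` with `m` the query length and
#' `n_eff` the configured effective database length.
#'
#' @param raw_score raw Smith-Waterman score(s).
#' @param query_length query length m.
#' @param cfg a [search_config()].
#' @param scheme a calibrated [scoring_scheme()].
#' @return E-value(s), strictly decreasing in the score.
#' @export
evalue <- function(raw_score, query_length, cfg, scheme) {
  if (is.null(scheme$lambda) || is.null(scheme$K))
    stop("scoring scheme is not calibrated; run calibrate_scheme() first")
  scheme$K * query_length * cfg$eff_db_len * exp(-scheme$lambda * raw_score)
}
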