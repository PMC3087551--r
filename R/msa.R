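#' Protein alignment container
#' @param ids row ids.
#' @param seqs equal-length gapped sequences.
#' @param col_source optional per-column metadata (source gene for
#'   concatenations).
#' @return object of class `protein_alignment`.
#' @export
protein_alignment <- function(ids, seqs, col_source = NULL) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids))
  if (length(unique(nchar(seqs))) > 1) stop("rows differ in length")
  structure(list(ids = ids, seqs = unname(seqs), col_source = col_source),
            class = "protein_alignment")
}

aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

# fractional shared k-mer distance used for the guide tree
kmer_distance <- function(seqs, k = 3) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- sum(pmin(ci[names(cj)], cj)[!is.na(ci[names(cj)])])
    denom <- min(sum(ci), sum(cj))
    D[i, j] <- D[j, i] <- 1 - if (denom > 0) shared / denom else 0
  }
  D
}

# 20 x L residue-frequency profile of an alignment (gaps excluded)
aln_profile <- function(seqs) {
  M <- do.call(rbind, strsplit(seqs, ""))
  L <- ncol(M); n <- nrow(M)
  P <- matrix(0, 20, L)
  for (j in seq_len(L)) {
    cnt <- table(factor(M[, j][M[, j] %in% AA], levels = AA))
    P[, j] <- as.numeric(cnt) / n
  }
  P
}

# apply a column path (0 = new gap) to gapped sequences
apply_path <- function(seqs, cols) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(ifelse(cols == 0, "-", ch[pmax(cols, 1)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Progressive multiple alignment
#'
#' Builds a guide tree by average-linkage clustering of fractional shared
#' k-mer distances, then aligns profiles up the tree with affine-gap
#' profile-profile alignment under the scheme's substitution matrix.
#' Deterministic; for two sequences the result equals the pairwise global
#' (Needleman-Wunsch) alignment.
#'
#' @param seqs named character vector of >= 2 ungapped protein sequences.
#' @param scheme a [scoring_scheme()] (calibration not required).
#' @param k k-mer size for the guide distances.
#' @return a [protein_alignment()].
#' @export
progressive_align <- function(seqs, scheme = scoring_scheme(), k = 3) {
  if (length(seqs) < 2) stop("need >= 2 sequences to align")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("s%d", seq_along(seqs))
  if (length(seqs) == 2) {
    r <- .profile_align_cpp(aln_profile(seqs[1]), aln_profile(seqs[2]),
                            scheme$matrix[1:20, 1:20],
                            scheme$gap_open, scheme$gap_ext)
    return(protein_alignment(ids, c(apply_path(seqs[1], r$a_cols),
                                    apply_path(seqs[2], r$b_cols))))
  }
  D <- kmer_distance(seqs)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  groups <- as.list(seq_along(seqs))
  aligned <- as.list(unname(seqs))
  merged <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) list(rows = -x, seqs = aligned[[-x]])
      else merged[[x]]
    a <- pick(hc$merge[s, 1]); b <- pick(hc$merge[s, 2])
    r <- .profile_align_cpp(aln_profile(a$seqs), aln_profile(b$seqs),
                            scheme$matrix[1:20, 1:20],
                            scheme$gap_open, scheme$gap_ext)
    merged[[s]] <- list(rows = c(a$rows, b$rows),
                        seqs = c(apply_path(a$seqs, r$a_cols),
                                 apply_path(b$seqs, r$b_cols)))
  }
  fin <- merged[[nrow(hc$merge)]]
  ord <- order(fin$rows)
  protein_alignment(ids[fin$rows[ord]], fin$seqs[ord])
}

#' Pairwise distances from an alignment
#'
#' p-distance over mutually ungapped columns, optionally Poisson-corrected
#' (`-ln(1 - p)`). Pairs with `p >= 1` (or no shared columns when at least
#' one other pair has some) are set to `NA` and flagged with a warning.
#'
#' @param aln a [protein_alignment()].
#' @param correction `"none"` or `"poisson"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distances <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  X <- aln_codes(aln)
  D <- dist_from_codes(X, correction)
  dimnames(D) <- list(aln$ids, aln$ids)
  D
}

# integer code matrix: 1..20 residues, 0 gap/unknown
aln_codes <- function(aln) {
  M <- aln_matrix(aln)
  X <- matrix(match(M, AA, nomatch = 0L), nrow = nrow(M))
  rownames(X) <- aln$ids
  X
}

dist_from_codes <- function(X, correction = "none") {
  n <- nrow(X)
  if (n < 2) stop("need >= 2 rows")
  B <- (X > 0) * 1
  shared <- tcrossprod(B)
  matches <- matrix(0, n, n)
  for (r in seq_len(20)) {
    A <- (X == r) * 1
    matches <- matches + tcrossprod(A)
  }
  if (all(shared[upper.tri(shared)] == 0))
    stop("no pair of rows shares an ungapped column")
  p <- 1 - matches / shared
  p[shared == 0] <- NA
  d <- if (correction == "poisson") {
    out <- -log(1 - p)
    out[!is.na(p) & p >= 1] <- NA
    out
  } else p
  diag(d) <- 0
  if (anyNA(d)) warning("saturated or disjoint pairs set to NA")
  d
}

#' Concatenate per-gene alignments into one genome-level supermatrix
#'
#' One row per genome; a genome missing a gene gets a gap block of that
#' gene's width. When a genome carries several copies of a gene, one copy
#' is retained by `copy_policy` (default: the copy with the highest score
#' in `scores`, e.g. the family-HMM forward score; without scores, the
#' lexicographically first gene id).
#'
#' @param alignments named list gene -> [protein_alignment()] whose row ids
#'   are gene ids of the form `<genome>|...`.
#' @param scores optional named numeric vector gene_id -> score used to
#'   pick among duplicate copies.
#' @param genome_of function mapping a row id to its genome.
#' @return a [protein_alignment()] with `col_source` naming the gene of
#'   every column.
#' @export
concatenate_alignments <- function(alignments, scores = NULL,
                                   genome_of = function(id)
                                     sub("\\|.*$", "", id)) {
  genomes <- sort(unique(unlist(lapply(alignments, function(a)
    vapply(a$ids, genome_of, character(1))))))
  rows <- setNames(rep("", length(genomes)), genomes)
  col_source <- character(0)
  for (gene in names(alignments)) {
    a <- alignments[[gene]]
    width <- nchar(a$seqs[1])
    gm <- vapply(a$ids, genome_of, character(1))
    for (g in genomes) {
      idx <- which(gm == g)
      if (!length(idx)) {
        rows[g] <- paste0(rows[g], strrep("-", width))
      } else {
        if (length(idx) > 1) {
          ids <- a$ids[idx]
          if (!is.null(scores) && any(ids %in% names(scores))) {
            sc <- scores[ids]; sc[is.na(sc)] <- -Inf
            idx <- idx[which.max(sc)]
          } else idx <- idx[order(ids)][1]
        }
        rows[g] <- paste0(rows[g], a$seqs[idx[1]])
      }
    }
    col_source <- c(col_source, rep(gene, width))
  }
  protein_alignment(genomes, rows, col_source = col_source)
}
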