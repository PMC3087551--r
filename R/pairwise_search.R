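#' Optimal affine-gap local alignment of two proteins
#'
#' Exact Smith-Waterman under the scheme's matrix and affine gap costs.
#' Among co-optimal alignments the one with the smallest (query start,
#' target start), then smallest ends, is reported. A zero score yields
#' empty intervals.
#'
#' @param a,b protein strings (20-letter alphabet; `X` allowed and scored
#'   as the worst substitution).
#' @param scheme a [scoring_scheme()].
#' @return list of class `sw_hit`: `score`, `qstart`, `qend`, `tstart`,
#'   `tend` (0-based half-open).
#' @export
smith_waterman <- function(a, b, scheme) {
  av <- aa_encode(a); bv <- aa_encode(b)
  if (!length(av) || !length(bv)) stop("empty sequence")
  r <- .sw_align_cpp(av, bv, scheme$matrix, scheme$gap_open, scheme$gap_ext)
  structure(r, class = "sw_hit")
}

# encode a proteome once for batch scoring
encode_proteome <- function(proteome) lapply(proteome, aa_encode)

#' Search one query against a proteome
#'
#' Scores the query against every target, converts raw scores to
#' constant-database-size E-values, and returns hits at or below the
#' cutoff sorted by ascending E-value then descending score (ties broken
#' by target id). An empty data.frame means "no hit".
#'
#' @param query protein string.
#' @param proteome named character vector of target proteins (or a
#'   pre-encoded list from `encode_proteome`).
#' @param cfg a [search_config()].
#' @param scheme a calibrated [scoring_scheme()].
#' @param intervals also recover aligned intervals for each kept hit.
#' @return data.frame: target, raw, bits, evalue (+ intervals if requested).
#' @export
search_genome <- function(query, proteome, cfg, scheme, intervals = FALSE) {
  if (!length(proteome)) stop("empty proteome")
  qv <- aa_encode(query)
  enc <- if (is.list(proteome)) proteome else encode_proteome(proteome)
  raw <- .sw_scores_cpp(qv, unname(enc), scheme$matrix, scheme$gap_open,
                        scheme$gap_ext)
  ev <- evalue(raw, length(qv), cfg, scheme)
  bits <- (scheme$lambda * raw - log(scheme$K)) / log(2)
  keep <- which(ev <= cfg$cutoff)
  out <- data.frame(target = names(enc)[keep], raw = raw[keep],
                    bits = bits[keep], evalue = ev[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$evalue, -out$raw, out$target), , drop = FALSE]
  rownames(out) <- NULL
  if (intervals && nrow(out)) {
    iv <- t(vapply(out$target, function(tg) {
      r <- .sw_align_cpp(qv, enc[[tg]], scheme$matrix, scheme$gap_open,
                         scheme$gap_ext)
      c(r$qstart, r$qend, r$tstart, r$tend)
    }, numeric(4)))
    out$qstart <- iv[, 1]; out$qend <- iv[, 2]
    out$tstart <- iv[, 3]; out$tend <- iv[, 4]
  }
  out
}

#' Reciprocal-best-hit family assignment across proteomes
#'
#' For each family reference, searches every genome; every hit at or below
#' the E-value cutoff whose own top hit back in the reference genome is a
#' member of the family is assigned to the family. This keeps the top
#' ortholog and retains duplicate (paralog) candidates that still
#' reciprocate with the family, and records absence as no assignment.
#'
#' @param references named list family -> character vector of reference
#'   gene ids (members of `proteomes[[ref_genome]]`).
#' @param proteomes named list genome -> named protein vector.
#' @param ref_genome name of the reference genome in `proteomes`.
#' @param cfg a [search_config()].
#' @param scheme a calibrated [scoring_scheme()].
#' @return data.frame: family, genome, gene_id, raw, evalue, rank,
#'   top_hit (logical).
#' @export
reciprocal_best_hits <- function(references, proteomes, ref_genome,
                                 cfg, scheme) {
  if (!ref_genome %in% names(proteomes))
    stop("reference genome must be among the proteomes")
  enc <- lapply(proteomes, encode_proteome)
  ref_enc <- enc[[ref_genome]]
  out <- list()
  # cache reciprocal top hits: candidate gene -> its top hit in ref genome
  recip_cache <- new.env(parent = emptyenv())
  top_in_ref <- function(genome, gene) {
    key <- paste0(genome, "\r", gene)
    if (!is.null(recip_cache[[key]])) return(recip_cache[[key]])
    hits <- search_genome(proteomes[[genome]][[gene]], ref_enc, cfg, scheme)
    th <- if (nrow(hits)) hits$target[1] else NA_character_
    recip_cache[[key]] <- th
    th
  }
  for (fam in names(references)) {
    refs <- references[[fam]]
    qid <- refs[1]
    query <- proteomes[[ref_genome]][[qid]]
    if (is.null(query)) stop("reference gene not in reference proteome: ", qid)
    for (gm in names(proteomes)) {
      hits <- search_genome(query, enc[[gm]], cfg, scheme)
      if (!nrow(hits)) next
      for (i in seq_len(nrow(hits))) {
        g <- hits$target[i]
        if (gm == ref_genome && g %in% refs) {
          back <- g # a reference trivially reciprocates with itself
        } else {
          back <- top_in_ref(gm, g)
        }
        if (!is.na(back) && back %in% refs) {
          out[[length(out) + 1L]] <- data.frame(
            family = fam, genome = gm, gene_id = g, raw = hits$raw[i],
            evalue = hits$evalue[i], rank = i, top_hit = (i == 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), genome = character(0),
                      gene_id = character(0), raw = numeric(0),
                      evalue = numeric(0), rank = integer(0),
                      top_hit = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
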